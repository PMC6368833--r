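# Period-wise Poisson regressions of species richness on N deposition, and
# the trend of the deposition effect across periods: a space-for-time
# comparison repeated at each survey period.

#' Oligotrophic species richness at a site-period
#'
#' Number of recorded species with nutrient indicator value < 3; species
#' with a missing nutrient value are excluded from the count.
#'
#' @param survey a survey table.
#' @param indicators an indicator table.
#' @param site,period site identifier and period.
#' @return Integer count.
#' @export
oligotrophic_richness <- function(survey, indicators, site, period) {
  sp <- species_set(survey, site, period)
  v <- indicators$nutrients[match(sp, indicators$species_id)]
  sum(!is.na(v) & v < 3)
}

#' Poisson GLM of richness on N deposition for one survey period
#'
#' Log-link Poisson regression across sites using only the surveys of one
#' period. Two covariate sets are supported: `"fig_style"` (default) uses
#' elevation, precipitation, inclination, and the site's community-mean
#' moisture and light values alongside N deposition; `"gradients"` uses the
#' four environmental gradients (temperature, precipitation, N deposition,
#' inclination). Predictors are z-standardized; the N-deposition effect is
#' reported per SD of deposition, with the SD recorded so the coefficient
#' can be rescaled to natural units (`effect / ndep_sd` per kg N).
#'
#' @param survey a survey table.
#' @param indicators an indicator table.
#' @param covariates a site-covariate table.
#' @param period which survey period to use.
#' @param response `"oligotrophic"` (default) or `"total"` richness.
#' @param covariate_set `"fig_style"` or `"gradients"`.
#' @param period_years mapping from period to midpoint year for deposition
#'   interpolation.
#' @return A one-row tibble: `period`, `response`, `covariate_set`,
#'   `effect` (N-deposition coefficient on log richness, per SD), `q05`,
#'   `q95`, `ndep_sd`, `n_sites`.
#' @export
fit_period_glm <- function(survey, indicators, covariates, period,
                           response = c("oligotrophic", "total"),
                           covariate_set = c("fig_style", "gradients"),
                           period_years = c(`1` = 2005, `2` = 2010,
                                            `3` = 2015)) {
  response <- match.arg(response)
  covariate_set <- match.arg(covariate_set)
  covariates <- site_covariates(covariates)
  year <- period_years[[as.character(period)]]
  sites <- sort(unique(survey$site_id[survey$surveyor == "regular" &
                                        survey$period == period]))
  if (length(sites) < 8) stop("too few sites surveyed in period ", period)
  d <- dplyr::bind_rows(lapply(sites, function(s) {
    sp <- species_set(survey, s, period)
    rich <- if (response == "oligotrophic") {
      oligotrophic_richness(survey, indicators, s, period)
    } else {
      length(sp)
    }
    tibble::tibble(
      site_id = s, richness = rich,
      cm_moisture = community_mean(sp, indicators, "moisture")$value,
      cm_light = community_mean(sp, indicators, "light")$value
    )
  }))
  i <- match(d$site_id, covariates$site_id)
  ndep <- covariates$ndep2000[i] + (year - 2000) / 15 *
    (covariates$ndep2015[i] - covariates$ndep2000[i])
  ndep_sd <- stats::sd(ndep)
  d$z_ndep <- zscore(ndep)
  if (covariate_set == "fig_style") {
    d$z_elev <- zscore(covariates$elevation_m[i])
    d$z_precip <- zscore(covariates$precip_mm[i])
    d$z_incl <- zscore(covariates$inclination_deg[i])
    d$z_moist <- zscore(d$cm_moisture)
    d$z_light <- zscore(d$cm_light)
    form <- richness ~ z_ndep + z_elev + z_precip + z_incl + z_moist +
      z_light
  } else {
    d$z_temp <- zscore(covariates$temp_c[i])
    d$z_precip <- zscore(covariates$precip_mm[i])
    d$z_incl <- zscore(covariates$inclination_deg[i])
    form <- richness ~ z_ndep + z_temp + z_precip + z_incl
  }
  fit <- stats::glm(form, family = stats::poisson(), data = d)
  X <- stats::model.matrix(fit)
  kappa_x <- kappa(X, exact = TRUE)
  if (kappa_x > 1e4) {
    warning("predictor matrix is ill-conditioned (condition number ",
            format(kappa_x, digits = 3), ")")
  }
  cf <- summary(fit)$coefficients
  tibble::tibble(
    period = period, response = response, covariate_set = covariate_set,
    effect = cf["z_ndep", 1],
    q05 = cf["z_ndep", 1] - Z90 * cf["z_ndep", 2],
    q95 = cf["z_ndep", 1] + Z90 * cf["z_ndep", 2],
    ndep_sd = ndep_sd, n_sites = nrow(d)
  )
}

#' Deposition-effect GLMs for every period
#'
#' @inheritParams fit_period_glm
#' @return A tibble with one [fit_period_glm()] row per period present in
#'   the survey table.
#' @export
period_effects <- function(survey, indicators, covariates,
                           response = "oligotrophic",
                           covariate_set = "fig_style",
                           period_years = c(`1` = 2005, `2` = 2010,
                                            `3` = 2015)) {
  periods <- sort(unique(survey$period[survey$surveyor == "regular"]))
  dplyr::bind_rows(lapply(periods, function(p) {
    fit_period_glm(survey, indicators, covariates, p, response,
                   covariate_set, period_years)
  }))
}

#' Trend of the deposition effect across periods
#'
#' Ordinary linear regression of the period-wise N-deposition effect on the
#' period index.
#'
#' @param effects output of [period_effects()] (>= 3 periods).
#' @return A [model_summary()] tibble with terms `(Intercept)` and
#'   `slope_per_period`.
#' @export
effect_trend <- function(effects) {
  if (nrow(effects) < 3) stop("need effects from at least 3 periods")
  fit <- stats::lm(effect ~ period, data = effects)
  cf <- summary(fit)$coefficients
  model_summary(c("(Intercept)", "slope_per_period"), cf[, 1], cf[, 2],
                backend = "OLS, normal-approximation intervals")
}
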