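# Per-species colonization and local-survival models along the N-deposition
# gradient.
#
# For every (species, site, transition): a species present at t either
# survives to t+1 or disappears; a species from the site's pool that is
# absent at t either colonizes by t+1 or stays absent. Both processes are
# modelled with the logistic mixed model
#   logit P(outcome) = b0 + b1 N + b2 V + b3 N x V + u_species + v_site,
# where N is the site's N deposition at the transition midpoint and V the
# species' nutrient indicator value. The crossover deposition rate is the N
# at which V has no effect on the logit (b2 + b3 N = 0), i.e. where
# oligotrophic (V < 3) and eutrophic (V > 3) species have equal predicted
# probabilities.

#' Transition observations for the colonization or survival process
#'
#' Survival rows cover every (species, site, transition) with the species
#' present at the start; colonization rows cover species in the candidate
#' pool absent at the start. The outcome is presence at the next survey.
#' N deposition is attached per transition by linear interpolation of the
#' site's 2000 and 2015 values to the transition midpoint year.
#'
#' @param survey a survey table (3 surveys per site; sites with fewer are
#'   skipped with a warning).
#' @param covariates a site-covariate table.
#' @param indicators an indicator table; species without a nutrient value
#'   are excluded (count reported via a message).
#' @param process `"colonization"` or `"survival"`.
#' @param pool candidate pool for colonization: `"site"` (default, the
#'   site's total community) or `"regional"` (every species in the survey
#'   table).
#' @param period_years mapping from period index to midpoint year, used for
#'   deposition interpolation.
#' @param ndep_year `"interpolate"` (default), or `"2000"` / `"2015"` to
#'   attach a fixed-year deposition value.
#' @return A tibble with `species_id`, `site_id`, `transition`, `state_t`,
#'   `outcome` (0/1), `ndep`, `nutrient_value`.
#' @export
build_transitions <- function(survey, covariates, indicators,
                              process = c("colonization", "survival"),
                              pool = c("site", "regional"),
                              period_years = c(`1` = 2005, `2` = 2010,
                                               `3` = 2015),
                              ndep_year = c("interpolate", "2000", "2015")) {
  process <- match.arg(process)
  pool <- match.arg(pool)
  ndep_year <- match.arg(ndep_year)
  covariates <- site_covariates(covariates)
  nut <- stats::setNames(indicators$nutrients, indicators$species_id)
  regional_pool <- sort(unique(survey$species_id[survey$surveyor ==
                                                   "regular"]))
  ndep_at <- function(site, year) {
    i <- match(site, covariates$site_id)
    if (is.na(i)) stop("site missing from covariates: ", site)
    switch(ndep_year,
           `2000` = covariates$ndep2000[i],
           `2015` = covariates$ndep2015[i],
           interpolate = covariates$ndep2000[i] +
             (year - 2000) / 15 *
             (covariates$ndep2015[i] - covariates$ndep2000[i]))
  }

  sites <- sort(unique(survey$site_id[survey$surveyor == "regular"]))
  rows <- list()
  n_dropped <- 0L
  for (s in sites) {
    periods <- site_periods(survey, s)
    if (length(periods) < 3) {
      warning("site '", s, "' has fewer than 3 surveys; skipped")
      next
    }
    sets <- lapply(periods, function(p) species_set(survey, s, p))
    site_pool <- if (pool == "site") total_community(survey, s) else
      regional_pool
    for (i in seq_len(length(periods) - 1)) {
      midpoint <- (period_years[[as.character(periods[i])]] +
                     period_years[[as.character(periods[i + 1])]]) / 2
      candidates <- if (process == "survival") sets[[i]] else
        setdiff(site_pool, sets[[i]])
      if (length(candidates) == 0) next
      v <- nut[candidates]
      keep <- !is.na(v)
      n_dropped <- n_dropped + sum(!keep)
      candidates <- candidates[keep]
      if (length(candidates) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        species_id = candidates,
        site_id = s,
        transition = paste0(periods[i], "->", periods[i + 1]),
        state_t = if (process == "survival") "present" else "absent",
        outcome = as.integer(candidates %in% sets[[i + 1]]),
        ndep = ndep_at(s, midpoint),
        nutrient_value = unname(v[keep])
      )
    }
  }
  if (n_dropped > 0) {
    message(n_dropped, " candidate records excluded: no nutrient value")
  }
  dplyr::bind_rows(rows)
}

#' Fit the logistic mixed model for one process
#'
#' Predictors are centered for numerical stability: deposition at its
#' sample mean, nutrient value at 3 (the scale midpoint separating
#' oligotrophic from eutrophic species). Random intercepts for species and
#' site. Coefficients are reported on the centered scale; the centering
#' constants travel with the result so derived quantities (the crossover)
#' can be mapped back to the natural deposition scale.
#'
#' @param rows output of [build_transitions()].
#' @param process `"colonization"` or `"survival"` (recorded in the output).
#' @return A [model_summary()] tibble with terms `(Intercept)`, `ndep_c`,
#'   `nut_c`, `ndep_c:nut_c`, plus attributes `vcov` (fixed-effect
#'   covariance), `ndep_center`, `nut_center`, `process`, `fit`.
#' @export
fit_process <- function(rows, process = c("colonization", "survival")) {
  process <- match.arg(process)
  if (length(unique(rows$species_id)) < 2 ||
      length(unique(rows$site_id)) < 2) {
    stop("need at least 2 species and 2 sites")
  }
  if (length(unique(rows$outcome)) < 2) {
    stop("outcome is constant; model not identifiable (separation)")
  }
  d <- rows
  ndep_center <- mean(d$ndep)
  d$ndep_c <- d$ndep - ndep_center
  d$nut_c <- d$nutrient_value - 3
  fit <- glmmTMB::glmmTMB(
    outcome ~ ndep_c * nut_c + (1 | species_id) + (1 | site_id),
    family = stats::binomial(), data = d
  )
  st <- fixef_stats(fit)
  out <- model_summary(names(st$estimate), st$estimate, st$se,
                       backend = "glmmTMB ML, normal-approximation intervals")
  attr(out, "vcov") <- st$vcov
  attr(out, "ndep_center") <- ndep_center
  attr(out, "nut_center") <- 3
  attr(out, "process") <- process
  attr(out, "fit") <- fit
  out
}

#' Crossover deposition rate from a fitted process model
#'
#' The deposition rate at which the nutrient value has no effect on the
#' logit, so the oligotrophic and eutrophic prediction curves intersect.
#' On the centered scale this is `-b2/b3`; the result is mapped back to
#' kg N ha-1 yr-1. Uncertainty comes from draws of the fixed effects from
#' their estimated multivariate normal; draws with a numerically zero
#' interaction are excluded and their fraction reported.
#'
#' @param fit output of [fit_process()].
#' @param n_draws number of coefficient draws (default 4000).
#' @param seed seed for the draws.
#' @return A one-row tibble: `process`, `n_star` (median of draws), `q05`,
#'   `q95`, `frac_degenerate`, `unstable` (`TRUE` when the interaction's
#'   90% interval includes 0, or when more than half the draws are
#'   degenerate, in which case the estimates are `NA`).
#' @export
crossover <- function(fit, n_draws = 4000, seed = 1) {
  V <- attr(fit, "vcov")
  center <- attr(fit, "ndep_center")
  if (is.null(V) || is.null(center)) {
    stop("'fit' must come from fit_process()")
  }
  b <- stats::setNames(fit$estimate, fit$term)
  inter <- summary_row(fit, "ndep_c:nut_c")
  unstable <- inter$q05 <= 0 && inter$q95 >= 0
  draws <- with_local_seed(seed, MASS::mvrnorm(n_draws, mu = b, Sigma = V))
  b2 <- draws[, "nut_c"]
  b3 <- draws[, "ndep_c:nut_c"]
  ok <- abs(b3) > 1e-12
  frac_degenerate <- 1 - mean(ok)
  if (frac_degenerate > 0.5) {
    return(tibble::tibble(process = attr(fit, "process"), n_star = NA_real_,
                          q05 = NA_real_, q95 = NA_real_,
                          frac_degenerate = frac_degenerate,
                          unstable = TRUE))
  }
  n_star_draws <- center - b2[ok] / b3[ok]
  qs <- stats::quantile(n_star_draws, c(0.05, 0.5, 0.95), names = FALSE)
  tibble::tibble(process = attr(fit, "process"),
                 n_star = qs[2], q05 = qs[1], q95 = qs[3],
                 frac_degenerate = frac_degenerate, unstable = unstable)
}

#' Predicted probability curves for oligotrophic and eutrophic groups
#'
#' Fixed-effects predictions along a deposition grid at two representative
#' nutrient values (defaults: 2 for oligotrophic, 4 for eutrophic), for
#' plotting and for locating the crossover by curve intersection.
#'
#' @param fit output of [fit_process()].
#' @param ndep_grid deposition values (natural scale).
#' @param v_olig,v_eut nutrient values representing the two groups.
#' @return A tibble with `ndep`, `p_olig`, `p_eut`.
#' @export
process_curves <- function(fit, ndep_grid = seq(0, 60, by = 0.1),
                           v_olig = 2, v_eut = 4) {
  b <- stats::setNames(fit$estimate, fit$term)
  center <- attr(fit, "ndep_center")
  pred <- function(v) {
    nc <- ndep_grid - center
    vc <- v - attr(fit, "nut_center")
    stats::plogis(b[["(Intercept)"]] + b[["ndep_c"]] * nc +
                    b[["nut_c"]] * vc + b[["ndep_c:nut_c"]] * nc * vc)
  }
  tibble::tibble(ndep = ndep_grid, p_olig = pred(v_olig),
                 p_eut = pred(v_eut))
}

#' Summaries of the N-deposition gradient
#'
#' @param covariates a site-covariate table.
#' @param threshold deposition threshold of interest, kg N ha-1 yr-1
#'   (default 12.5).
#' @return A one-row tibble: mean and SD of deposition in 2000 and 2015,
#'   mean and SD of the per-site change, the fraction of sites below
#'   `threshold` in 2015, the fraction below 10 in 2000, and the fraction
#'   of those low-deposition sites lying above 1000 m.
#' @export
deposition_summary <- function(covariates, threshold = 12.5) {
  covariates <- site_covariates(covariates)
  change <- covariates$ndep2015 - covariates$ndep2000
  low2000 <- covariates$ndep2000 < 10
  tibble::tibble(
    n_sites = nrow(covariates),
    mean_2000 = mean(covariates$ndep2000),
    sd_2000 = stats::sd(covariates$ndep2000),
    mean_2015 = mean(covariates$ndep2015),
    sd_2015 = stats::sd(covariates$ndep2015),
    mean_change = mean(change),
    sd_change = stats::sd(change),
    threshold = threshold,
    frac_below_threshold_2015 = mean(covariates$ndep2015 < threshold),
    frac_below_10_2000 = mean(low2000),
    frac_low2000_above_1000m = if (any(low2000))
      mean(covariates$elevation_m[low2000] > 1000) else NA_real_
  )
}
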