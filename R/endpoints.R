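# Biodiversity endpoints per survey (species richness and community-mean
# indicator values) and their site-level linear trends.

#' Community mean of an indicator value over a species set
#'
#' Arithmetic mean of the requested indicator dimension over the species in
#' `species`; species with a missing value on that dimension are excluded.
#'
#' @param species character vector of species ids.
#' @param indicators an indicator table.
#' @param dimension one of `"temperature"`, `"moisture"`, `"nutrients"`,
#'   `"light"`.
#' @return A one-row tibble with `value` (the CM, in `[1, 5]`) and `n_used`
#'   (species contributing a non-missing value).
#' @export
community_mean <- function(species, indicators, dimension) {
  dimension <- match.arg(dimension, INDICATOR_DIMENSIONS)
  vals <- indicators[[dimension]][match(unique(species),
                                        indicators$species_id)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("community mean undefined: no species with a non-missing '",
         dimension, "' value")
  }
  tibble::tibble(value = mean(vals), n_used = length(vals))
}

#' Endpoint series: richness and the four CMs per site and survey period
#'
#' @param survey a survey table (regular surveys only are used).
#' @param indicators an indicator table.
#' @return A tibble with one row per site-period: `site_id`, `period`,
#'   `richness`, `cm_temperature`, `cm_moisture`, `cm_nutrients`,
#'   `cm_light`, and `n_temperature` .. `n_light` (species used per CM).
#' @export
endpoint_series <- function(survey, indicators) {
  reg <- survey[survey$surveyor == "regular", ]
  grid <- unique(reg[c("site_id", "period")])
  grid <- grid[order(grid$site_id, grid$period), ]
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    sp <- species_set(reg, grid$site_id[i], grid$period[i])
    row <- tibble::tibble(site_id = grid$site_id[i],
                          period = grid$period[i],
                          richness = length(sp))
    for (dim in INDICATOR_DIMENSIONS) {
      cm <- community_mean(sp, indicators, dim)
      row[[paste0("cm_", dim)]] <- cm$value
      row[[paste0("n_", dim)]] <- cm$n_used
    }
    row
  }))
}

#' Per-period averages of the endpoints across sites
#'
#' @param series output of [endpoint_series()].
#' @return A tibble with one row per period and the across-site mean of each
#'   endpoint.
#' @export
endpoint_period_means <- function(series) {
  dplyr::summarise(
    dplyr::group_by(series, .data$period),
    dplyr::across(dplyr::all_of(c("richness", paste0("cm_",
                                                     INDICATOR_DIMENSIONS))),
                  mean),
    .groups = "drop"
  )
}

#' Linear temporal trend of a biodiversity endpoint
#'
#' Random-intercept random-slope model of the endpoint on time in decades:
#' `y_ij = a_i + b_i t_ij + e_ij` with site-level intercepts and slopes
#' drawn from a common (correlated) bivariate normal. Identity link with
#' normal errors for community means; log link with Poisson errors for
#' species richness. The reported trend is the population-level slope per
#' decade.
#'
#' Degenerate fits (non-convergence or an undefined standard error, as on
#' noise-free data) trigger a recorded fallback, first to a
#' random-intercept-only model and then to an ordinary regression.
#'
#' @param series output of [endpoint_series()].
#' @param endpoint `"richness"` or one of the `cm_*` column names.
#' @param period_years named numeric mapping from period index to calendar
#'   midpoint year; the default places three 5-year periods at 2005, 2010,
#'   2015.
#' @return A one-row [model_summary()] tibble (`term = "trend_per_decade"`)
#'   whose `backend` attribute records the model actually used.
#' @export
trend_model <- function(series, endpoint,
                        period_years = c(`1` = 2005, `2` = 2010,
                                         `3` = 2015)) {
  if (!endpoint %in% names(series)) stop("unknown endpoint: ", endpoint)
  if (length(unique(series$period)) < 2) stop("need at least 2 periods")
  if (length(unique(series$site_id)) < 5) stop("need at least 5 sites")
  years <- period_years[as.character(series$period)]
  if (anyNA(years)) stop("period_years does not cover all periods")
  d <- tibble::tibble(site_id = series$site_id,
                      t = (years - min(years)) / 10,
                      y = series[[endpoint]])
  fam <- if (endpoint == "richness") stats::poisson() else stats::gaussian()

  # REML for the gaussian models (standard for LMM variance components);
  # ML for Poisson richness
  reml <- endpoint != "richness"
  try_fit <- function(formula, label) {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(formula, family = fam, data = d,
                                        REML = reml)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    st <- tryCatch(fixef_stats(fit), error = function(e) NULL)
    if (is.null(st) || !is.finite(st$se[["t"]])) return(NULL)
    list(st = st, label = label)
  }

  res <- try_fit(y ~ t + (t | site_id), "glmmTMB random intercept + slope")
  if (is.null(res)) {
    res <- try_fit(y ~ t + (1 | site_id),
                   "glmmTMB random intercept (slope-variance fallback)")
  }
  if (is.null(res)) {
    fit <- stats::glm(y ~ t, family = fam, data = d)
    cf <- summary(fit)$coefficients
    res <- list(st = list(estimate = c(t = cf["t", 1]),
                          se = c(t = cf["t", 2])),
                label = "fixed-effects GLM (degenerate-variance fallback)")
  }
  # t reference with between-site degrees of freedom: with few time points
  # per site the population slope is effectively estimated from n_sites
  # site-level slopes, and normal quantiles are anticonservative
  out <- model_summary("trend_per_decade", res$st$estimate[["t"]],
                       res$st$se[["t"]], backend = res$label,
                       df = length(unique(d$site_id)) - 2)
  out$endpoint <- endpoint
  out[c("endpoint", setdiff(names(out), "endpoint"))]
}

#' Trends for all five endpoints
#'
#' @inheritParams trend_model
#' @return A tibble with one row per endpoint, Table-shaped: endpoint,
#'   trend per decade, 90% interval, probability the trend is positive.
#' @export
trend_table <- function(series, period_years = c(`1` = 2005, `2` = 2010,
                                                 `3` = 2015)) {
  eps <- c("richness", paste0("cm_", INDICATOR_DIMENSIONS))
  dplyr::bind_rows(lapply(eps, function(e) {
    trend_model(series, e, period_years)
  }))
}
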