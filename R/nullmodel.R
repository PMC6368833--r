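# Randomization null model for the traits of colonizing and disappearing
# species.
#
# For each site, the species that colonized (absent -> present across a
# transition) or disappeared (present -> absent) are compared against
# random draws of the same number of species from the site's total
# community (the union of all its surveys). The statistic is
#   standardized-CM = CM(focal set) - mean over draws of CM(random set),
# a deviation from random assembly on each indicator dimension. Draws are
# uniform without replacement and include the focal species, since they are
# part of the total community.

#' Colonized, disappeared, and pool species sets for a site
#'
#' Colonized species were absent at some survey and present at the next;
#' disappeared species were present and then absent; both are unions over
#' all consecutive transitions, so a species that flickers can appear in
#' both sets. The pool is the site's total community.
#'
#' @param survey a survey table.
#' @param site site identifier; the site must have at least 3 surveys
#'   (sites with fewer are an error here; batch callers skip them).
#' @return A list with character vectors `colonized`, `disappeared`, `pool`.
#' @export
focal_sets <- function(survey, site) {
  periods <- site_periods(survey, site)
  if (length(periods) < 3) {
    stop("site '", site, "' has fewer than 3 surveys")
  }
  sets <- lapply(periods, function(p) species_set(survey, site, p))
  colonized <- character()
  disappeared <- character()
  for (i in seq_len(length(sets) - 1)) {
    colonized <- union(colonized, setdiff(sets[[i + 1]], sets[[i]]))
    disappeared <- union(disappeared, setdiff(sets[[i]], sets[[i + 1]]))
  }
  list(colonized = sort(colonized), disappeared = sort(disappeared),
       pool = total_community(survey, site))
}

#' Standardized community mean of a focal set against random draws
#'
#' @param focal character vector of focal species (must be a subset of
#'   `pool`).
#' @param pool character vector: the site's total community.
#' @param indicators an indicator table.
#' @param dimension indicator dimension.
#' @param n_draws number of random subsets (default 1000).
#' @param seed integer seed making the draws reproducible.
#' @param include_focal if `TRUE` (default) draws are taken from the full
#'   pool, focal species included; `FALSE` draws from `pool \\ focal`.
#' @return A one-row tibble with `n_species` (focal species with a
#'   non-missing value), `cm_observed`, `null_mean`, `null_sd`,
#'   `standardized = cm_observed - null_mean`, `n_draws`; or `NULL` with a
#'   message when no focal species carries a value on this dimension.
#' @export
standardized_cm <- function(focal, pool, indicators, dimension,
                            n_draws = 1000, seed = 1,
                            include_focal = TRUE) {
  dimension <- match.arg(dimension, INDICATOR_DIMENSIONS)
  focal <- unique(as.character(focal))
  pool <- unique(as.character(pool))
  if (length(setdiff(focal, pool)) > 0) {
    stop("focal species must be a subset of the pool")
  }
  if (length(focal) == 0) {
    message("empty focal set; standardized CM skipped")
    return(NULL)
  }
  val_of <- function(sp) {
    v <- indicators[[dimension]][match(sp, indicators$species_id)]
    v[!is.na(v)]
  }
  focal_vals <- val_of(focal)
  draw_pool <- if (include_focal) pool else setdiff(pool, focal)
  pool_vals <- val_of(draw_pool)
  k <- length(focal_vals)
  if (k == 0) {
    message("no focal species with a non-missing '", dimension,
            "' value; skipped")
    return(NULL)
  }
  if (length(pool_vals) < k) {
    stop("pool has fewer species with '", dimension,
         "' values than the focal set")
  }
  cm_observed <- mean(focal_vals)
  null_cms <- with_local_seed(seed, {
    vapply(seq_len(n_draws),
           function(i) mean(sample(pool_vals, k, replace = FALSE)),
           numeric(1))
  })
  null_mean <- mean(null_cms)
  tibble::tibble(
    n_species = k,
    cm_observed = cm_observed,
    null_mean = null_mean,
    null_sd = stats::sd(null_cms),
    standardized = cm_observed - null_mean,
    n_draws = n_draws
  )
}

#' Standardized CMs for every site, direction, and indicator dimension
#'
#' Each (site, direction, dimension) combination draws from its own seed
#' substream of `seed`, so results do not depend on iteration order. Sites
#' with fewer than 3 surveys are skipped with a warning; empty focal sets
#' are skipped silently (they carry no information).
#'
#' @param survey a survey table.
#' @param indicators an indicator table.
#' @param n_draws random draws per statistic (default 1000).
#' @param seed master seed.
#' @param include_focal see [standardized_cm()].
#' @return A tibble with columns `site_id`, `direction` (`"colonized"` /
#'   `"disappeared"`), `dimension`, and the [standardized_cm()] fields.
#' @export
standardized_cm_table <- function(survey, indicators, n_draws = 1000,
                                  seed = 1, include_focal = TRUE) {
  sites <- sort(unique(survey$site_id[survey$surveyor == "regular"]))
  rows <- list()
  for (s in sites) {
    if (length(site_periods(survey, s)) < 3) {
      warning("site '", s, "' has fewer than 3 surveys; skipped")
      next
    }
    fs <- focal_sets(survey, s)
    for (direction in c("colonized", "disappeared")) {
      focal <- fs[[direction]]
      if (length(focal) == 0) next
      for (dim in INDICATOR_DIMENSIONS) {
        rec <- suppressMessages(standardized_cm(
          focal, fs$pool, indicators, dim, n_draws = n_draws,
          seed = substream_seed(seed, s, direction, dim),
          include_focal = include_focal
        ))
        if (is.null(rec)) next
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(site_id = s, direction = direction,
                         dimension = dim), rec)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Table-3 pairing of indicator dimensions with environmental gradients
DEFAULT_PAIRING <- c(temperature = "temp_c", moisture = "precip_mm",
                     nutrients = "ndep", light = "inclination_deg")

#' Regression of standardized CMs along their paired gradients
#'
#' For each direction and indicator dimension, fits the ordinary linear
#' model `standardized ~ gradient`, with the gradient centered at a
#' reference point and scaled by its SD. The intercept is the expected
#' deviation from random at the reference ("difference from random"); the
#' slope is the change per gradient SD ("change along gradient"). Intervals
#' are 90% (t-based).
#'
#' @param stats output of [standardized_cm_table()].
#' @param covariates a site-covariate table.
#' @param pairing named character vector mapping dimension to the covariate
#'   column carrying its gradient (`"ndep"` means the N-deposition value
#'   selected by `ndep_year`). The default pairs temperature with mean
#'   annual temperature, moisture with precipitation, nutrients with N
#'   deposition, light with inclination.
#' @param ndep_reference reference point for the N-deposition gradient, in
#'   kg N ha-1 yr-1 (default 10; other gradients are referenced at their
#'   sample mean).
#' @param ndep_year `"midpoint"` (default), `"2000"` or `"2015"`.
#' @return A tibble with one row per (direction, dimension): gradient name,
#'   reference and SD used, `n_sites`, and estimate / `q05` / `q95` for
#'   `diff` (intercept) and `slope`.
#' @export
gradient_regression <- function(stats, covariates,
                                pairing = DEFAULT_PAIRING,
                                ndep_reference = 10,
                                ndep_year = c("midpoint", "2000", "2015")) {
  ndep_year <- match.arg(ndep_year)
  covariates <- site_covariates(covariates)
  covariates$ndep <- switch(
    ndep_year,
    midpoint = (covariates$ndep2000 + covariates$ndep2015) / 2,
    `2000` = covariates$ndep2000,
    `2015` = covariates$ndep2015
  )
  out <- list()
  for (direction in sort(unique(stats$direction))) {
    for (dim in INDICATOR_DIMENSIONS) {
      d <- stats[stats$direction == direction & stats$dimension == dim, ]
      if (nrow(d) == 0) next
      if (nrow(d) < 5) {
        stop("need >= 5 sites with standardized CMs for '", dim, "'")
      }
      gname <- pairing[[dim]]
      g <- covariates[[gname]][match(d$site_id, covariates$site_id)]
      if (anyNA(g)) stop("missing gradient values for some sites")
      gsd <- stats::sd(g)
      if (!is.finite(gsd) || gsd == 0) {
        stop("gradient '", gname, "' is constant; slope undefined")
      }
      ref <- if (gname == "ndep") ndep_reference else mean(g)
      fit <- stats::lm(d$standardized ~ I((g - ref) / gsd))
      cf <- summary(fit)$coefficients
      tq <- stats::qt(0.95, df = fit$df.residual)
      out[[length(out) + 1]] <- tibble::tibble(
        direction = direction, dimension = dim, gradient = gname,
        reference = ref, gradient_sd = gsd, n_sites = nrow(d),
        diff_estimate = cf[1, 1],
        diff_q05 = cf[1, 1] - tq * cf[1, 2],
        diff_q95 = cf[1, 1] + tq * cf[1, 2],
        slope_estimate = cf[2, 1],
        slope_q05 = cf[2, 1] - tq * cf[2, 2],
        slope_q95 = cf[2, 1] + tq * cf[2, 2]
      )
    }
  }
  dplyr::bind_rows(out)
}
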