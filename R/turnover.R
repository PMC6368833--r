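# Species exchange ratio (SER), surveyor pseudo-turnover, and the binomial
# mixed model for turnover along environmental gradients.
#
# Turnover between two surveys is the proportion of species that differ:
#   SER = (gains + losses) / richness of the union of both surveys.
# The union denominator is the species-exchange-ratio convention; the main
# alternative in the literature (mean richness of the two surveys) gives
# systematically larger values and is NOT what this package computes.

#' Species exchange ratio between two species sets
#'
#' @param set_a,set_b character vectors of species present in the first and
#'   second survey. Their union must be non-empty.
#' @return A one-row tibble with `n_gained` (`|B \\ A|`), `n_lost`
#'   (`|A \\ B|`), `n_union` and `ser = (n_gained + n_lost) / n_union`.
#' @export
ser <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  n_union <- length(union(set_a, set_b))
  if (n_union == 0) stop("SER is undefined for two empty species sets")
  n_lost <- length(setdiff(set_a, set_b))
  n_gained <- length(setdiff(set_b, set_a))
  tibble::tibble(n_gained = n_gained, n_lost = n_lost, n_union = n_union,
                 ser = (n_gained + n_lost) / n_union)
}

#' Temporal turnover records for every consecutive survey transition
#'
#' @param survey a survey table; sites with a single period are skipped with
#'   a warning. Only regular surveys are used.
#' @return A tibble with one row per site per consecutive transition:
#'   `site_id`, `transition` (e.g. `"1->2"`), `period_from`, `n_gained`,
#'   `n_lost`, `n_union`, `ser`.
#' @export
temporal_turnover <- function(survey) {
  sites <- sort(unique(survey$site_id[survey$surveyor == "regular"]))
  rows <- lapply(sites, function(s) {
    periods <- site_periods(survey, s)
    if (length(periods) < 2) {
      warning("site '", s, "' has fewer than 2 surveys; skipped")
      return(NULL)
    }
    dplyr::bind_rows(lapply(seq_len(length(periods) - 1), function(i) {
      rec <- ser(species_set(survey, s, periods[i]),
                 species_set(survey, s, periods[i + 1]))
      dplyr::bind_cols(
        tibble::tibble(site_id = s,
                       transition = paste0(periods[i], "->", periods[i + 1]),
                       period_from = periods[i]),
        rec
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Mean and SD of turnover per transition
#'
#' @param records output of [temporal_turnover()] or [pseudo_turnover()].
#' @return A tibble with `transition`, `n_sites`, `mean_ser`, `sd_ser`.
#' @export
turnover_summary <- function(records) {
  dplyr::summarise(dplyr::group_by(records, .data$transition),
                   n_sites = dplyr::n(),
                   mean_ser = mean(.data$ser),
                   sd_ser = stats::sd(.data$ser),
                   .groups = "drop")
}

#' Pseudo-turnover between regular and replicate surveys
#'
#' The SER between two same-year surveys of the same site by different
#' surveyors: an observation-error baseline against which temporal turnover
#' can be judged.
#'
#' @param survey a survey table containing replicate records.
#' @return A tibble as from [temporal_turnover()] with
#'   `transition = "replicate"` and a `period` column; zero rows (with a
#'   message) when no replicate surveys exist.
#' @export
pseudo_turnover <- function(survey) {
  reps <- unique(survey[survey$surveyor == "replicate",
                        c("site_id", "period")])
  if (nrow(reps) == 0) {
    message("no replicate surveys found; pseudo-turnover not computable")
    return(tibble::tibble(site_id = character(), transition = character(),
                          period = integer(), n_gained = integer(),
                          n_lost = integer(), n_union = integer(),
                          ser = double()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(reps)), function(i) {
    s <- reps$site_id[i]
    p <- reps$period[i]
    rec <- ser(species_set(survey, s, p, "regular"),
               species_set(survey, s, p, "replicate"))
    dplyr::bind_cols(tibble::tibble(site_id = s, transition = "replicate",
                                    period = p), rec)
  }))
}

#' Binomial mixed model of turnover along environmental gradients
#'
#' Fits a logit-link binomial GLMM with the number of differing species as
#' successes out of the union richness, with fixed effects for the
#' transition (0 = first, 1 = second), the union richness per 10 species,
#' and the four z-standardized gradients (mean annual temperature, annual
#' precipitation, N deposition, inclination), and a random intercept per
#' site.
#'
#' @param records output of [temporal_turnover()]; at least two sites.
#' @param covariates a site-covariate table.
#' @param ndep_year which deposition value represents the N gradient:
#'   `"midpoint"` (default; mean of the 2000 and 2015 values), `"2000"` or
#'   `"2015"`.
#' @return A [model_summary()] tibble with one row per fixed effect. The
#'   `backend` attribute records the estimation route.
#' @export
turnover_model <- function(records, covariates,
                           ndep_year = c("midpoint", "2000", "2015")) {
  ndep_year <- match.arg(ndep_year)
  if (length(unique(records$site_id)) < 2) {
    stop("turnover model needs records from at least 2 sites")
  }
  covariates <- site_covariates(covariates)
  ndep <- switch(ndep_year,
                 midpoint = (covariates$ndep2000 + covariates$ndep2015) / 2,
                 `2000` = covariates$ndep2000,
                 `2015` = covariates$ndep2015)
  covs <- tibble::tibble(
    site_id = covariates$site_id,
    z_temp = zscore(covariates$temp_c),
    z_precip = zscore(covariates$precip_mm),
    z_ndep = zscore(ndep),
    z_incl = zscore(covariates$inclination_deg)
  )
  d <- dplyr::inner_join(records, covs, by = "site_id")
  if (nrow(d) < nrow(records)) {
    warning(nrow(records) - nrow(d),
            " turnover records dropped: site missing from covariates")
  }
  d$period2 <- as.numeric(d$period_from > min(d$period_from))
  d$rich10 <- d$n_union / 10
  d$n_diff <- d$n_gained + d$n_lost
  d$n_same <- d$n_union - d$n_diff
  fit <- glmmTMB::glmmTMB(
    cbind(n_diff, n_same) ~ period2 + rich10 + z_temp + z_precip +
      z_ndep + z_incl + (1 | site_id),
    family = stats::binomial(), data = d
  )
  st <- fixef_stats(fit)
  out <- model_summary(names(st$estimate), st$estimate, st$se,
                       backend = "glmmTMB ML, normal-approximation intervals")
  attr(out, "fit") <- fit
  out
}
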