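test_that("oligotrophic richness counts species below the nutrient
           midpoint", {
  sv <- make_survey(list(X = list(`1` = c("a", "b", "c", "d"))))
  ind <- make_indicators(c("a", "b", "c", "d"), nutrients = c(1, 2, 3, 4))
  expect_equal(oligotrophic_richness(sv, ind, "X", 1), 2)
  ind_high <- make_indicators(c("a", "b", "c", "d"),
                              nutrients = c(3, 4, 5, 3))
  expect_equal(oligotrophic_richness(sv, ind_high, "X", 1), 0)
})

test_that("oligotrophic + eutrophic + midpoint + missing partitions the
           richness", {
  sim <- generate(synthetic_config(n_sites = 8, pool_size = 60,
                                   baseline_occupancy = 0.3,
                                   n_replicate_sites = 0), seed = 41)
  ind <- sim$indicators
  for (s in unique(sim$survey$site_id)[1:4]) {
    sp <- species_set(sim$survey, s, 1)
    v <- ind$nutrients[match(sp, ind$species_id)]
    oligo <- oligotrophic_richness(sim$survey, ind, s, 1)
    expect_equal(oligo + sum(!is.na(v) & v > 3) + sum(!is.na(v) & v == 3) +
                   sum(is.na(v)), length(sp))
  }
})

test_that("period GLM recovers a known deposition slope on simulated
           counts", {
  # direct Poisson simulation on the model's own scale: log richness falls
  # by 0.02 per kg N
  set.seed(55)
  n <- 400
  covs <- make_covariates(sprintf("s%03d", 1:n))
  covs$ndep2000 <- stats::runif(n, 5, 35)
  covs$ndep2015 <- covs$ndep2000 - 2.5
  ndep_p1 <- covs$ndep2000 + 7.5 / 15 * (covs$ndep2015 - covs$ndep2000)
  lam <- exp(log(20) - 0.02 * (ndep_p1 - mean(ndep_p1)))
  rich <- stats::rpois(n, lam)
  # survey with `rich` oligotrophic species per site drawn from a pool of
  # low-nutrient species, plus one fixed eutrophic species
  pool <- sprintf("olig%03d", 1:300)
  ind <- make_indicators(c(pool, "eut1"),
                         nutrients = c(rep(2, 300), 5),
                         moisture = c(rep(c(2, 3, 4), 100), 3),
                         light = c(rep(c(3, 4), 150), 4))
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(site_id = covs$site_id[i], period = 1L,
                   surveyor = "regular",
                   species_id = c(sample(pool, max(rich[i], 1)), "eut1"))
  })
  sv <- survey_table(dplyr::bind_rows(rows))
  # period 1 sits at calendar 2005, matching the deposition used above
  eff <- fit_period_glm(sv, ind, covs, period = 1,
                        response = "oligotrophic",
                        covariate_set = "fig_style",
                        period_years = c(`1` = 2005))
  slope_per_kg <- eff$effect / eff$ndep_sd
  expect_lt(eff$q05 / eff$ndep_sd, -0.02 + 0.01)
  expect_gt(eff$q95 / eff$ndep_sd, -0.02 - 0.01)
  expect_lt(abs(slope_per_kg + 0.02), 0.006)
})

test_that("permuting deposition across sites removes the effect", {
  sim <- generate(synthetic_config(n_sites = 60, pool_size = 200,
                                   baseline_occupancy = 0.2,
                                   n_replicate_sites = 0), seed = 66)
  covs <- sim$covariates
  set.seed(67)
  perm <- sample(nrow(covs))
  covs$ndep2000 <- covs$ndep2000[perm]
  covs$ndep2015 <- covs$ndep2015[perm]
  eff <- fit_period_glm(sim$survey, sim$indicators, covs, period = 1)
  expect_lt(eff$q05, 0)
  expect_gt(eff$q95, 0)
})

test_that("duplicating every observation leaves coefficients unchanged and
           narrows intervals", {
  sim <- generate(synthetic_config(n_sites = 40, pool_size = 150,
                                   baseline_occupancy = 0.25,
                                   n_replicate_sites = 0), seed = 68)
  eff <- fit_period_glm(sim$survey, sim$indicators, sim$covariates, 1)
  # duplicate each site under a new id with identical covariates
  sv2 <- sim$survey
  sv2$site_id <- paste0(sv2$site_id, "_dup")
  both <- survey_table(dplyr::bind_rows(tibble::as_tibble(sim$survey),
                                        tibble::as_tibble(sv2)))
  cv2 <- sim$covariates
  cv2$site_id <- paste0(cv2$site_id, "_dup")
  cvboth <- site_covariates(dplyr::bind_rows(
    tibble::as_tibble(sim$covariates), tibble::as_tibble(cv2)))
  eff2 <- fit_period_glm(both, sim$indicators, cvboth, 1)
  # compare on the natural (per kg N) scale: duplication changes the n-1
  # denominator of the SD used for standardization
  expect_equal(eff2$effect / eff2$ndep_sd, eff$effect / eff$ndep_sd,
               tolerance = 1e-6)
  expect_lt((eff2$q95 - eff2$q05) / eff2$ndep_sd,
            (eff$q95 - eff$q05) / eff$ndep_sd)
})

test_that("effect trend reproduces an exact line and needs 3 periods", {
  eff <- tibble::tibble(period = 1:3, effect = c(-0.1, -0.2, -0.3))
  tr <- suppressWarnings(effect_trend(eff))
  slope <- tr[tr$term == "slope_per_period", ]
  expect_equal(slope$estimate, -0.1, tolerance = 1e-9)
  expect_error(effect_trend(eff[1:2, ]), "3 periods")
  eff_flat <- tibble::tibble(period = 1:3, effect = rep(-0.15, 3))
  expect_equal(suppressWarnings(effect_trend(eff_flat))$estimate[2], 0,
               tolerance = 1e-12)
})
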