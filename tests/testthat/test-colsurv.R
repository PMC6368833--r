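test_that("transition rows enumerate survival and colonization
           candidates", {
  sv <- make_survey(list(X = list(`1` = c("a", "b"), `2` = "a",
                                  `3` = c("a", "b"))))
  ind <- make_indicators(c("a", "b"), nutrients = c(2, 4))
  covs <- make_covariates("X", ndep2000 = 20, ndep2015 = 14)
  surv <- build_transitions(sv, covs, ind, "survival")
  expect_equal(nrow(surv), 3)
  expect_equal(surv$outcome[surv$species_id == "a" &
                              surv$transition == "1->2"], 1L)
  expect_equal(surv$outcome[surv$species_id == "b" &
                              surv$transition == "1->2"], 0L)
  expect_equal(surv$outcome[surv$species_id == "a" &
                              surv$transition == "2->3"], 1L)
  col <- build_transitions(sv, covs, ind, "colonization")
  expect_equal(nrow(col), 1)
  expect_equal(col$species_id, "b")
  expect_equal(col$transition, "2->3")
  expect_equal(col$outcome, 1L)
  # deposition interpolated to the transition midpoints (2007.5, 2012.5)
  expect_equal(sort(unique(surv$ndep)),
               sort(20 + c(7.5, 12.5) / 15 * (14 - 20)))
})

test_that("survival and colonization rows partition the site pool at every
           transition", {
  sim <- generate(synthetic_config(n_sites = 10, pool_size = 80,
                                   baseline_occupancy = 0.25,
                                   trait_missing = 0,
                                   n_replicate_sites = 0), seed = 14)
  surv <- build_transitions(sim$survey, sim$covariates, sim$indicators,
                            "survival")
  col <- build_transitions(sim$survey, sim$covariates, sim$indicators,
                           "colonization")
  key <- function(d) paste(d$species_id, d$site_id, d$transition)
  expect_length(intersect(key(surv), key(col)), 0)
  for (s in unique(sim$survey$site_id)) {
    pool <- total_community(sim$survey, s)
    n_expected <- 2 * length(pool)
    expect_equal(sum(surv$site_id == s) + sum(col$site_id == s),
                 n_expected)
  }
})

test_that("species without a nutrient value are excluded with a count", {
  sv <- make_survey(list(X = list(`1` = c("a", "b"), `2` = c("a", "b"),
                                  `3` = c("a", "b"))))
  ind <- indicator_table(tibble::tibble(
    species_id = c("a", "b"), temperature = c(3, 3), moisture = c(3, 3),
    nutrients = c(2, NA), light = c(3, 3)))
  covs <- make_covariates("X", ndep2000 = 20, ndep2015 = 14)
  expect_message(rows <- build_transitions(sv, covs, ind, "survival"),
                 "excluded")
  expect_equal(unique(rows$species_id), "a")
})

test_that("crossover algebra, affine-recoding invariance, and the grid
           oracle agree", {
  # hand-made fit: b2 = 1.0, b3 = -0.08 on an uncentered scale gives
  # n_star = 12.5 exactly
  terms <- c("(Intercept)", "ndep_c", "nut_c", "ndep_c:nut_c")
  est <- c(-1, 0.01, 1.0, -0.08)
  fake <- model_summary(terms, est, se = rep(1e-8, 4))
  V_tiny <- diag(1e-16, 4)
  dimnames(V_tiny) <- list(terms, terms)
  attr(fake, "vcov") <- V_tiny
  attr(fake, "ndep_center") <- 0
  attr(fake, "nut_center") <- 3
  attr(fake, "process") <- "survival"
  cx <- crossover(fake, n_draws = 500, seed = 1)
  expect_equal(cx$n_star, 12.5, tolerance = 1e-4)
  expect_false(cx$unstable)

  # recentering deposition by c shifts b2 to b2 + c*b3 and leaves the
  # natural-scale crossover invariant
  c_shift <- 15
  est2 <- c(est[1] + c_shift * est[2], est[2],
            est[3] + c_shift * est[4], est[4])
  fake2 <- model_summary(terms, est2, se = rep(1e-8, 4))
  attr(fake2, "vcov") <- attr(fake, "vcov")
  attr(fake2, "ndep_center") <- c_shift
  attr(fake2, "nut_center") <- 3
  attr(fake2, "process") <- "survival"
  cx2 <- crossover(fake2, n_draws = 500, seed = 1)
  expect_equal(cx2$n_star, cx$n_star, tolerance = 1e-4)

  # brute-force intersection of the two group curves over a fine grid
  curves <- process_curves(fake, ndep_grid = seq(0, 60, by = 0.01))
  grid_star <- curves$ndep[which.min(abs(curves$p_olig - curves$p_eut))]
  expect_equal(grid_star, cx$n_star, tolerance = 0.01 + 1e-4)

  # zero interaction: crossover undefined
  est0 <- c(-1, 0.01, 1.0, 0)
  fake0 <- model_summary(terms, est0, se = c(1e-8, 1e-8, 1e-8, 1e-8))
  V0 <- diag(1e-30, 4)
  dimnames(V0) <- list(terms, terms)
  attr(fake0, "vcov") <- V0
  attr(fake0, "ndep_center") <- 0
  attr(fake0, "nut_center") <- 3
  attr(fake0, "process") <- "survival"
  cx0 <- crossover(fake0, n_draws = 200, seed = 1)
  expect_true(is.na(cx0$n_star))
  expect_true(cx0$unstable)
})

test_that("permuting outcomes destroys the nutrient-deposition
           interaction", {
  sim <- generate(synthetic_config(n_sites = 40, pool_size = 120,
                                   baseline_occupancy = 0.25,
                                   n_replicate_sites = 0), seed = 77)
  rows <- suppressMessages(build_transitions(
    sim$survey, sim$covariates, sim$indicators, "survival"))
  set.seed(78)
  rows$outcome <- sample(rows$outcome)
  fit <- fit_process(rows, "survival")
  inter <- fit[fit$term == "ndep_c:nut_c", ]
  expect_lt(inter$q05, 0)
  expect_gt(inter$q95, 0)
})

test_that("deposition summaries reduce to column arithmetic", {
  covs <- make_covariates(c("a", "b"), ndep2000 = c(12, 22),
                          ndep2015 = c(10, 20),
                          elevation = c(1400, 700))
  ds <- deposition_summary(covs, threshold = 12.5)
  expect_equal(ds$frac_below_threshold_2015, 0.5)
  expect_equal(ds$mean_change, -2)
  expect_equal(ds$mean_2000, 17)
  expect_equal(ds$frac_below_10_2000, 0)
  covs2 <- make_covariates(c("a", "b"), ndep2000 = c(8, 22),
                           ndep2015 = c(7, 20),
                           elevation = c(1400, 700))
  ds2 <- deposition_summary(covs2)
  expect_equal(ds2$frac_below_10_2000, 0.5)
  expect_equal(ds2$frac_low2000_above_1000m, 1)
})
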