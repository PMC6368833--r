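test_that("focal sets enumerate colonizations and disappearances", {
  sv <- make_survey(list(X = list(`1` = c("a", "b"), `2` = c("a", "b"),
                                  `3` = c("a", "b"))))
  fs <- focal_sets(sv, "X")
  expect_equal(fs$colonized, character(0))
  expect_equal(fs$disappeared, character(0))
  expect_setequal(fs$pool, c("a", "b"))

  # a species can flicker into both sets
  sv2 <- make_survey(list(X = list(`1` = c("a", "b"), `2` = c("b", "c"),
                                   `3` = c("a", "b"))))
  fs2 <- focal_sets(sv2, "X")
  expect_setequal(fs2$colonized, c("a", "c"))
  expect_setequal(fs2$disappeared, c("a", "c"))
  expect_setequal(fs2$pool, c("a", "b", "c"))

  sv3 <- make_survey(list(X = list(`1` = "a", `2` = c("a", "b"),
                                   `3` = c("a", "b", "c"))))
  fs3 <- focal_sets(sv3, "X")
  expect_setequal(fs3$colonized, c("b", "c"))
  expect_equal(fs3$disappeared, character(0))

  sv4 <- make_survey(list(X = list(`1` = "a", `2` = "a")))
  expect_error(focal_sets(sv4, "X"), "fewer than 3")
})

test_that("standardized CM agrees with exhaustive subset enumeration", {
  ind <- make_indicators(paste0("p", 1:4), nutrients = c(1, 2, 3, 4))
  pool <- paste0("p", 1:4)
  res <- standardized_cm(c("p1", "p2"), pool, ind, "nutrients",
                         n_draws = 1000, seed = 5)
  expect_equal(res$cm_observed, 1.5)
  # exact null mean over all C(4,2) = 6 subsets is 2.5
  exact <- mean(apply(utils::combn(c(1, 2, 3, 4), 2), 2, mean))
  expect_equal(exact, 2.5)
  expect_lt(abs(res$null_mean - exact), 3 * res$null_sd / sqrt(1000))
  expect_equal(res$standardized, res$cm_observed - res$null_mean)
})

test_that("degenerate focal sets behave exactly", {
  ind <- make_indicators(paste0("p", 1:6), nutrients = c(1, 1, 2, 3, 5, 5))
  pool <- paste0("p", 1:6)
  # focal = pool: every draw is the whole pool, standardized is exactly 0
  res <- standardized_cm(pool, pool, ind, "nutrients", n_draws = 50,
                         seed = 2)
  expect_identical(res$standardized, 0)
  expect_identical(res$null_sd, 0)
  # size-1 focal holding the pool maximum: null mean converges on the pool
  # mean, so standardized converges on max - mean
  res1 <- standardized_cm("p5", pool, ind, "nutrients", n_draws = 2000,
                          seed = 3)
  closed_form <- 5 - mean(c(1, 1, 2, 3, 5, 5))
  expect_lt(abs(res1$standardized - closed_form),
            4 * res1$null_sd / sqrt(2000))
  expect_error(standardized_cm("zz", pool, ind, "nutrients"), "subset")
  expect_message(
    expect_null(standardized_cm(character(), pool, ind, "nutrients")),
    "empty")
})

test_that("null mean converges on the pool mean (Monte-Carlo consistency)", {
  set.seed(17)
  for (i in 1:10) {
    n_pool <- sample(8:40, 1)
    vals <- sample(1:5, n_pool, replace = TRUE)
    if (length(unique(vals)) == 1) vals[1] <- vals[1] %% 5 + 1
    ind <- make_indicators(paste0("q", seq_len(n_pool)), nutrients = vals)
    k <- sample(seq_len(min(6, n_pool - 1)), 1)
    res <- standardized_cm(paste0("q", 1:k), paste0("q", seq_len(n_pool)),
                           ind, "nutrients", n_draws = 1000, seed = i)
    expect_lt(abs(res$null_mean - mean(vals)),
              4 * res$null_sd / sqrt(1000) + 1e-12)
    # standardized bounded by the range of pool values
    expect_lte(abs(res$standardized), diff(range(vals)))
  }
})

test_that("standardized CM table uses order-invariant seed substreams", {
  sim <- generate(synthetic_config(n_sites = 6, pool_size = 40,
                                   n_replicate_sites = 0), seed = 8)
  tab <- standardized_cm_table(sim$survey, sim$indicators, n_draws = 200,
                               seed = 99)
  expect_true(all(tab$n_draws == 200))
  # recomputing one cell directly with its substream seed reproduces it
  row <- tab[5, ]
  fs <- focal_sets(sim$survey, row$site_id)
  direct <- standardized_cm(fs[[row$direction]], fs$pool, sim$indicators,
                            row$dimension, n_draws = 200,
                            seed = substream_seed(99, row$site_id,
                                                  row$direction,
                                                  row$dimension))
  expect_equal(direct$standardized, row$standardized)
  # missing-value handling: n_species counts only valued species
  expect_true(all(tab$n_species >= 1))
})

test_that("trait-biased colonization at low deposition yields a negative
           difference from random and a positive gradient slope", {
  # colonization favours low-nutrient species only at low N: the V-effect
  # -0.6 + 0.03 N is negative below 20 kg and positive above
  cfg <- synthetic_config(
    n_sites = 150, pool_size = 300, baseline_occupancy = 0.15,
    niche_strength = 0, detection = 1, trait_missing = 0,
    colonization = c(x0 = -3.2, x_N = 0, x_V = -0.6, x_NV = 0.03),
    survival = c(x0 = 2.2, x_N = 0, x_V = 0, x_NV = 0),
    n_replicate_sites = 0)
  sim <- generate(cfg, seed = 330)
  tab <- standardized_cm_table(sim$survey, sim$indicators, n_draws = 400,
                               seed = 331)
  reg <- gradient_regression(tab, sim$covariates, ndep_reference = 10)
  nut <- reg[reg$direction == "colonized" & reg$dimension == "nutrients", ]
  expect_lt(nut$diff_estimate, 0)
  expect_lt(nut$diff_q95, 0)
  expect_gt(nut$slope_estimate, 0)
  expect_gt(nut$slope_q05, 0)
})

test_that("gradient regression recovers exact zero and known linear
           structure", {
  covs <- make_covariates(sprintf("s%02d", 1:20))
  stats0 <- tidyr::expand_grid(site_id = covs$site_id,
                               direction = c("colonized", "disappeared"),
                               dimension = c("temperature", "moisture",
                                             "nutrients", "light"))
  stats0$standardized <- 0
  reg <- gradient_regression(stats0, covs)
  expect_equal(nrow(reg), 8)
  expect_true(all(abs(reg$diff_estimate) < 1e-12))
  expect_true(all(abs(reg$slope_estimate) < 1e-12))
  # an exact linear relation in the N gradient is recovered exactly
  ndep_mid <- (covs$ndep2000 + covs$ndep2015) / 2
  stats1 <- tibble::tibble(site_id = covs$site_id,
                           direction = "colonized",
                           dimension = "nutrients",
                           standardized = -0.08 + 0.01 * (ndep_mid - 10))
  reg1 <- suppressWarnings(gradient_regression(stats1, covs,
                                               ndep_reference = 10))
  expect_equal(reg1$diff_estimate, -0.08, tolerance = 1e-9)
  expect_equal(reg1$slope_estimate / reg1$gradient_sd, 0.01,
               tolerance = 1e-9)
  expect_error(gradient_regression(stats1[1:3, ], covs), ">= 5 sites")
})
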