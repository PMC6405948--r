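test_that("SAI arithmetic matches both variants at the pinned points", {
  expect_equal(sai(25, 30, 20), 0.5)
  expect_equal(sai(25, 30, 20, variant = "as_printed"), 1.0)
  expect_equal(sai(30, 30, 20), 1.0)               # perfect surrogate
  expect_equal(sai(20, 30, 20), 0.0)               # random-equivalent
  expect_equal(sai(20, 30, 20, variant = "as_printed"), 0.0)
  expect_true(is.infinite(sai(30, 30, 20, variant = "as_printed")))
  expect_lt(sai(10, 30, 20), 0)                    # worse than random
  expect_warning(out <- sai(5, 10, 10), regexp = "unmeasurable")
  expect_true(is.nan(out))
  expect_error(sai(5, 10, 12), class = "saiplan_data_error")
})

test_that("the random baseline hits forced values exactly", {
  occ <- occ_from_matrix(diag(4)) # each plot exactly one distinct species
  expect_equal(random_baseline(occ, target = paste0("s", 1:4), k = 1,
                               n_random = 50, seed = 1), 1)
  expect_equal(random_baseline(occ, target = paste0("s", 1:4), k = 4,
                               n_random = 20, seed = 1), 4)
  expect_equal(random_baseline(occ, target = paste0("s", 1:4), k = 0,
                               n_random = 20, seed = 1), 0)
  expect_error(random_baseline(occ, target = paste0("s", 1:4), k = 9,
                               n_random = 5, seed = 1),
               class = "saiplan_data_error")
})

test_that("the random baseline matches the exhaustive enumeration oracle", {
  withr::with_seed(41, {
    m <- matrix(rbinom(10 * 5, 1, 0.4), 10, 5)
  })
  m[, colSums(m) == 0] <- 1 # keep every species representable
  occ <- occ_from_matrix(m)
  exact <- expected_k_representation(m, 3) # all C(10,3) = 120 subsets
  draws <- vapply(1:20, function(i) {
    random_baseline(occ, target = paste0("s", 1:5), k = 3,
                    n_random = 400, seed = i)
  }, numeric(1))
  mc_se <- sd(draws)
  expect_lt(abs(mean(draws) - exact), 3 * mc_se / sqrt(20) + 1e-9)
  expect_lt(abs(draws[1] - exact), 4 * mc_se)
})

test_that("surrogacy configs validate their fields", {
  expect_error(sai_config(q_values = c(0, 10)),
               class = "saiplan_config_error")
  expect_error(sai_config(n_models = 0), class = "saiplan_config_error")
  land <- small_landscape(seed = 50)
  cfg <- sai_config(q_values = 20, n_models = 2, n_random = 50,
                    surrogate_variables = "not_there", seed = 1)
  expect_error(evaluate_surrogate(land$occurrence, land$covariates, cfg),
               class = "saiplan_config_error")
  cfg$surrogate_variables <- character()
  expect_error(evaluate_surrogate(land$occurrence, land$covariates, cfg),
               class = "saiplan_config_error")
})

test_that("evaluated curves respect the SAI bounds and are reproducible", {
  land <- small_landscape(seed = 51)
  cfg <- sai_config(q_values = c(20, 50), n_models = 8, n_random = 200,
                    surrogate_variables = "soil_carbon", seed = 13)
  a <- evaluate_surrogate(land$occurrence, land$covariates, cfg)
  b <- evaluate_surrogate(land$occurrence, land$covariates, cfg)
  expect_identical(tidy(a), tidy(b))
  vals <- unlist(a$sai_values)
  expect_true(all(vals <= 1 + 1e-12))
  expect_true(all(a$S_mean <= a$O))
  expect_true(all(a$R_mean <= a$O))
  expect_true(all(a$ci_low <= a$ci_high))
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("a surrogate equal to the optimal score is near-perfect at generous q", {
  land <- small_landscape(seed = 52)
  sel <- greedy_richness_selection(land$occurrence)
  cov <- dplyr::mutate(land$covariates,
                       oracle_score = importance_scores(sel)$score)
  cfg <- sai_config(q_values = 50, n_models = 10, n_random = 300,
                    surrogate_variables = "oracle_score", seed = 14)
  cv <- evaluate_surrogate(land$occurrence, cov, cfg)
  expect_gte(cv$sai_mean, 0.8)
})

test_that("a pure-noise surrogate scores near zero", {
  land <- small_landscape(seed = 53)
  cov <- withr::with_seed(54, dplyr::mutate(land$covariates,
                                            junk = rnorm(nrow(land$covariates))))
  cfg <- sai_config(q_values = 30, n_models = 20, n_random = 300,
                    surrogate_variables = "junk", seed = 15)
  cv <- evaluate_surrogate(land$occurrence, cov, cfg)
  expect_lt(abs(cv$sai_mean), 0.25)
  expect_true(cv$ci_low <= 0 && cv$ci_high >= 0)
})

test_that("paired comparisons share draws: duplicated sets are identical", {
  land <- small_landscape(seed = 55)
  cfg <- sai_config(q_values = c(20, 40), n_models = 4, n_random = 100,
                    seed = 16)
  cmp <- compare_surrogates(
    land$occurrence, land$covariates,
    list(one = "soil_carbon", two = "soil_carbon"), cfg
  )
  expect_identical(tidy(cmp$curves$one), tidy(cmp$curves$two))
  expect_true(all(cmp$differences$mean_diff == 0))
  expect_true(all(cmp$differences$ci_low == 0 & cmp$differences$ci_high == 0))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("an informative surrogate beats noise in a paired comparison", {
  land <- small_landscape(seed = 56, n_plots = 80, soc_effect = 2.5)
  cov <- withr::with_seed(57, dplyr::mutate(land$covariates,
                                            junk = rnorm(80)))
  cfg <- sai_config(q_values = c(25, 50), n_models = 10, n_random = 300,
                    seed = 17)
  cmp <- compare_surrogates(land$occurrence, cov,
                            list(carbon = "soil_carbon", noise = "junk"),
                            cfg)
  diffs <- cmp$differences
  expect_true(all(diffs$mean_diff > 0))
})

test_that("more calibration data never systematically hurts an informative surrogate", {
  land <- small_landscape(seed = 58, n_plots = 80, soc_effect = 2.5)
  cfg <- sai_config(q_values = c(5, 60), n_models = 12, n_random = 300,
                    surrogate_variables = "soil_carbon", seed = 18)
  cv <- evaluate_surrogate(land$occurrence, land$covariates, cfg)
  se <- sd(cv$sai_values[[1]] - cv$sai_values[[2]]) / sqrt(12)
  expect_gte(cv$sai_mean[cv$q == 60],
             cv$sai_mean[cv$q == 5] - 3 * se - 0.05)
})
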