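test_that("default configuration matches the emulated plot network", {
  cfg <- default_config()
  expect_equal(cfg$n_plots, 145L)
  expect_equal(cfg$n_species, 470L)
  expect_equal(cfg$n_threatened, 37L)
  expect_gt(cfg$soc_effect, 0)
  expect_identical(default_config(), default_config())
})

test_that("invalid configurations are rejected as configuration errors", {
  expect_error(landscape_config(n_plots = 0), class = "saiplan_config_error")
  expect_error(landscape_config(n_threatened = 50, n_species = 40),
               class = "saiplan_config_error")
  expect_error(landscape_config(baseline_prevalence_range = c(0.5, 1.2)),
               class = "saiplan_config_error")
  expect_error(landscape_config(collinear_pairs = 99),
               class = "saiplan_config_error")
})

test_that("identical seeds reproduce identical landscapes", {
  a <- small_landscape(seed = 42)
  b <- small_landscape(seed = 42)
  expect_identical(a$occurrence, b$occurrence)
  expect_identical(a$covariates, b$covariates)
  c <- small_landscape(seed = 43)
  expect_false(identical(a$occurrence, c$occurrence))
})

test_that("landscape structure honours the configuration", {
  land <- small_landscape(seed = 5, collinear_pairs = 2)
  expect_equal(nrow(land$occurrence), 60)
  expect_lte(ncol(land$occurrence) - 1L, 80) # dropped species allowed
  expect_equal(length(land$threatened), 10)
  expect_true(all(unlist(land$occurrence[-1]) %in% 0:1))
  # no species is left occupying zero plots
  expect_true(all(colSums(land$occurrence[-1]) >= 1))
  # soil carbon positive and right-skewed; collinear twins present
  sc <- land$covariates$soil_carbon
  expect_true(all(sc > 0))
  expect_gt(mean(sc), median(sc))
  expect_gt(cor(land$covariates$soil_age, land$covariates$soil_age_alt),
            0.95)
})

test_that("species absent everywhere after resampling are dropped loudly", {
  expect_warning(
    suppressMessages(simulate_landscape(landscape_config(
      n_plots = 2, n_species = 40, n_threatened = 30,
      threatened_prevalence_range = c(0.001, 0.001),
      baseline_prevalence_range = c(0.001, 0.002),
      collinear_pairs = 0, seed = 99
    ))),
    regexp = "Dropped"
  )
})

test_that("with no soil-carbon effect prevalences track their baselines", {
  land <- suppressMessages(simulate_landscape(landscape_config(
    n_plots = 200, n_species = 100, n_threatened = 20, soc_effect = 0,
    threatened_prevalence_range = c(0.10, 0.30),
    baseline_prevalence_range = c(0.10, 0.40), seed = 21
  )))
  base <- land$truth$baselines[colnames(land$occurrence[-1])]
  obs <- colSums(land$occurrence[-1])
  lo <- qbinom(0.005, 200, base)
  hi <- qbinom(0.995, 200, base)
  inside <- mean(obs >= lo & obs <= hi)
  expect_gte(inside, 0.95) # each species held to its binomial 99% band
})

test_that("zero effect leaves soil carbon uncorrelated with threat counts", {
  rs <- vapply(1:50, function(i) {
    land <- suppressMessages(simulate_landscape(landscape_config(
      n_plots = 60, n_species = 25, n_threatened = 6, soc_effect = 0,
      collinear_pairs = 0, n_covariates = 2, seed = 1000 + i
    )))
    thr <- intersect(land$threatened, names(land$occurrence))
    counts <- rowSums(land$occurrence[thr])
    suppressWarnings(cor(land$covariates$soil_carbon, counts))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
  expect_lt(mean(abs(rs) >= 0.2, na.rm = TRUE), 0.4)
})

test_that("a positive effect concentrates threatened species on carbon-rich plots", {
  hits <- vapply(1:50, function(i) {
    land <- suppressMessages(simulate_landscape(landscape_config(
      n_plots = 80, n_species = 30, n_threatened = 10, soc_effect = 2,
      collinear_pairs = 0, n_covariates = 2, seed = 2000 + i
    )))
    thr <- intersect(land$threatened, names(land$occurrence))
    counts <- rowSums(land$occurrence[thr])
    sc <- land$covariates$soil_carbon
    qs <- quantile(sc, c(0.25, 0.75))
    mean(counts[sc >= qs[2]]) > mean(counts[sc <= qs[1]])
  }, logical(1))
  expect_gte(sum(hits), 48)
})

test_that("the generating effect sign is recoverable by logistic regression", {
  land <- suppressMessages(simulate_landscape(landscape_config(seed = 31)))
  thr <- intersect(land$threatened, names(land$occurrence))
  z <- as.numeric(scale(land$covariates$soil_carbon))
  pooled <- tidyr::pivot_longer(
    dplyr::mutate(land$occurrence[c("plot_id", thr)], z_soc = z),
    cols = dplyr::all_of(thr), values_to = "present"
  )
  fit <- glm(present ~ z_soc, family = binomial(), data = pooled)
  expect_gt(coef(fit)[["z_soc"]], 0)
  expect_lt(summary(fit)$coefficients["z_soc", "Pr(>|z|)"], 0.01)
})
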