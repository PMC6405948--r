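test_that("the worked chain {A,B}, {B,C}, {C} selects plots 1 then 2", {
  occ <- occ_from_matrix(rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1)),
                         species_ids = c("A", "B", "C"))
  sel <- greedy_richness_selection(occ, target = c("A", "B", "C"))
  expect_equal(sel$steps$plot_id, c("p1", "p2"))
  expect_equal(sel$steps$gain, c(2, 1))
  expect_equal(sel$steps$represented, c(2, 3))
  expect_false("p3" %in% sel$steps$plot_id)
})

test_that("a dominating plot is the whole selection", {
  occ <- occ_from_matrix(rbind(c(1, 1, 1), c(1, 0, 0)),
                         species_ids = c("A", "B", "C"))
  sel <- greedy_richness_selection(occ, target = c("A", "B", "C"))
  expect_equal(sel$steps$plot_id, "p1")
  expect_equal(sel$steps$gain, 3)
})

test_that("species in no plot are unrepresentable, not an error", {
  occ <- occ_from_matrix(rbind(c(1, 0), c(1, 0)), species_ids = c("A", "B"))
  sel <- greedy_richness_selection(occ, target = c("A", "B"))
  expect_equal(sel$unrepresentable, "B")
  expect_equal(max(sel$steps$represented), 1)

  none <- greedy_richness_selection(occ, target = "B")
  expect_equal(nrow(none$steps), 0)
  expect_equal(none$unrepresentable, "B")
  expect_equal(importance_scores(none)$score, c(0, 0))
})

test_that("empty or unknown targets are errors", {
  occ <- occ_from_matrix(rbind(c(1, 0), c(0, 1)))
  expect_error(greedy_richness_selection(occ, target = character()),
               class = "saiplan_data_error")
  expect_error(greedy_richness_selection(occ, target = "nope"),
               class = "saiplan_data_error")
})

test_that("importance scores normalize gains to [0, 1] with max 1", {
  occ <- occ_from_matrix(rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1)),
                         species_ids = c("A", "B", "C"))
  sel <- greedy_richness_selection(occ, target = c("A", "B", "C"))
  sc <- importance_scores(sel)
  expect_equal(sc$score, c(1, 0.5, 0))
  # identical plots: first by input order is selected, alone, scoring 1
  same <- occ_from_matrix(rbind(c(1, 1), c(1, 1), c(1, 1)))
  sc2 <- importance_scores(greedy_richness_selection(same,
                                                     target = c("s1", "s2")))
  expect_equal(sc2$score, c(1, 0, 0))
})

test_that("site budgets truncate the selection", {
  occ <- occ_from_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 1)))
  sel <- greedy_richness_selection(occ, target = paste0("s", 1:4),
                                   site_budget = 1)
  expect_equal(nrow(sel$steps), 1)
  expect_equal(sel$steps$represented, 2)
})

test_that("greedy matches brute force on 200 random small instances", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n_plots <- sample(2:12, 1)
      n_sp <- sample(2:10, 1)
      m <- matrix(rbinom(n_plots * n_sp, 1, runif(1, 0.15, 0.6)),
                  n_plots, n_sp)
      occ <- occ_from_matrix(m)
      target <- colnames(occ)[-1]
      sel <- greedy_richness_selection(occ, target = target)

      # first pick equals the brute-force richest plot
      rich <- rowSums(m)
      if (nrow(sel$steps) > 0) {
        expect_equal(match(sel$steps$plot_id[1], occ$plot_id),
                     which.max(rich))
      }
      # full representation achieved whenever it is achievable at all
      achievable <- sum(colSums(m) > 0)
      got <- if (nrow(sel$steps) > 0) max(sel$steps$represented) else 0
      expect_equal(got, achievable)
      # marginal gains are nonincreasing; coverage is nondecreasing
      expect_true(all(diff(sel$steps$gain) <= 0))
      expect_true(all(diff(sel$steps$represented) > 0))
      # greedy never does worse than the best exhaustive set of its size
      if (nrow(sel$steps) > 0 && n_plots <= 8) {
        k <- nrow(sel$steps)
        expect_equal(max(sel$steps$represented),
                     best_k_representation(m, min(k, n_plots)))
      }
    }
  })
})
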