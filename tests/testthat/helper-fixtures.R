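# Shared fixture builders and independent oracles.

# Occurrence tibble from a plain 0/1 matrix (plots x species).
occ_from_matrix <- function(m, plot_ids = NULL, species_ids = NULL,
                            threatened = character()) {
  plot_ids <- plot_ids %||% sprintf("p%d", seq_len(nrow(m)))
  species_ids <- species_ids %||% sprintf("s%d", seq_len(ncol(m)))
  colnames(m) <- species_ids
  out <- dplyr::bind_cols(tibble::tibble(plot_id = plot_ids),
                          tibble::as_tibble(m))
  attr(out, "threatened") <- threatened
  out
}

# A small but structured landscape for integration-style tests.
small_landscape <- function(seed = 11, n_plots = 60, n_species = 80,
                            n_threatened = 10, soc_effect = 2, ...) {
  suppressMessages(simulate_landscape(landscape_config(
    n_plots = n_plots, n_species = n_species, n_threatened = n_threatened,
    soc_effect = soc_effect, seed = seed, ...
  )))
}

# Columns with an exactly prescribed sample correlation matrix: map
# centered orthonormal columns through the Cholesky factor of `rho`.
exact_correlation_columns <- function(n, rho, seed = 1) {
  p <- nrow(rho)
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    m <- scale(m, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(m)) # orthonormal, still column-centered
    x <- q %*% chol(rho)
    colnames(x) <- letters[seq_len(p)]
    tibble::as_tibble(x)
  })
}

# Brute-force VIF oracle via the inverse correlation matrix.
vif_oracle <- function(x) {
  x <- as.matrix(x)
  diag(solve(stats::cor(x)))
}

# Exhaustive best-k species representation (oracle for greedy + baseline).
best_k_representation <- function(m, k) {
  combos <- utils::combn(nrow(m), k, simplify = FALSE)
  max(vapply(combos, function(idx) {
    sum(colSums(m[idx, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# Exact expected representation of a uniform k-subset, by enumeration.
expected_k_representation <- function(m, k) {
  combos <- utils::combn(nrow(m), k, simplify = FALSE)
  mean(vapply(combos, function(idx) {
    sum(colSums(m[idx, , drop = FALSE]) > 0)
  }, numeric(1)))
}

`%||%` <- rlang::`%||%`
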