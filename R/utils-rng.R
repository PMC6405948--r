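#' Derive a named substream seed from a master seed
#'
#' Stage-level randomness is organised as named substreams derived from one
#' master seed, so that changing how many draws one stage consumes (or
#' switching a stage off) never perturbs another stage's stream. The
#' substream seed is a deterministic hash of the stream name mixed with the
#' master seed, reduced modulo 2^31 - 1 so it is always a valid R seed.
#'
#' @param seed Master seed (single integer-valued number).
#' @param name Substream name (single string).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "covariates")
#' substream_seed(1, "occurrence")
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 2166136261 %% m
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h + (as.double(seed) %% m) * 48271) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate code under a named substream of `seed`, restoring RNG state after.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# Drop identifier columns (plot_id) and check the rest is numeric.
drop_plot_id <- function(data) {
  data <- as_tibble(data)
  data[setdiff(names(data), "plot_id")]
}
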