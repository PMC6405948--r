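#' Variance inflation factors
#'
#' For each variable `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the
#' coefficient of determination of an ordinary least-squares regression
#' (with intercept) of variable `j` on all the others. An exact linear
#' dependence yields an `Inf` sentinel rather than an error; a constant
#' column is an error naming it.
#'
#' @param data All-numeric covariate tibble; a `plot_id` column, if
#'   present, is ignored. Needs at least two variables and more rows than
#'   variables.
#' @return A tibble with columns `variable` and `vif` (dimensionless,
#'   >= 1).
#' @export
#' @examples
#' compute_vif(tibble::tibble(a = c(1, 2, 4, 3, 5), b = c(5, 3, 1, 4, 2)))
compute_vif <- function(data) {
  x <- drop_plot_id(data)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("All covariate columns must be numeric; see encode_covariates().",
          class = "saiplan_format_error")
  }
  if (ncol(x) < 2L) {
    abort("VIF needs at least two variables.", class = "saiplan_data_error")
  }
  if (nrow(x) <= ncol(x)) {
    abort("VIF needs more rows than variables.", class = "saiplan_data_error")
  }
  const <- names(x)[vapply(x, function(v) var(v) == 0, logical(1))]
  if (length(const) > 0L) {
    abort(sprintf("Constant column(s): %s", paste(const, collapse = ", ")),
          class = "saiplan_data_error")
  }
  vifs <- vapply(names(x), function(v) {
    df <- as.data.frame(x)
    names(df) <- make.names(names(df)) # formula-safe aliases
    vv <- make.names(names(x))[match(v, names(x))]
    fit <- lm(reformulate(setdiff(names(df), vv), response = vv), data = df)
    # exact dependence triggers a "perfect fit" nag; the Inf sentinel is
    # the documented outcome, not a problem
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(variable = names(x), vif = unname(vifs))
}

#' Iterative VIF reduction of a covariate set
#'
#' Repeatedly computes VIFs and removes the single worst variable (the
#' argmax; ties broken alphabetically) whenever the maximum VIF is at or
#' above `threshold`, stopping when all remaining VIFs fall below the
#' threshold or a single variable is left. The default threshold of 3
#' follows the convention of retaining only variables with VIF below 3.
#'
#' @param data All-numeric covariate tibble (`plot_id` ignored).
#' @param threshold Retention threshold; variables are kept only while all
#'   VIFs are strictly below it.
#' @return An object of class `vif_reduction` with elements `retained`
#'   (character), `dropped` (tibble: `variable`, `vif` at removal,
#'   `iteration`), `final_vifs` (tibble) and `threshold`. `tidy()` returns
#'   the per-variable trajectory, `glance()` a one-row summary.
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(50))
#' d$b <- d$a + rnorm(50, sd = 0.05) # nearly collinear pair
#' d$c <- rnorm(50)
#' reduce_collinearity(d, threshold = 3)
reduce_collinearity <- function(data, threshold = 3) {
  x <- drop_plot_id(data)
  dropped <- tibble(variable = character(), vif = numeric(),
                    iteration = integer())
  iter <- 0L
  repeat {
    if (ncol(x) == 1L) {
      final <- tibble(variable = names(x), vif = 1)
      break
    }
    vifs <- compute_vif(x)
    mx <- max(vifs$vif)
    if (mx < threshold) {
      final <- vifs
      break
    }
    iter <- iter + 1L
    worst <- sort(vifs$variable[vifs$vif == mx])[1]
    dropped <- dplyr::bind_rows(
      dropped,
      tibble(variable = worst, vif = mx, iteration = iter)
    )
    x <- x[setdiff(names(x), worst)]
  }
  structure(
    list(retained = final$variable, dropped = dropped, final_vifs = final,
         threshold = threshold),
    class = "vif_reduction"
  )
}

#' @export
print.vif_reduction <- function(x, ...) {
  cat(sprintf("<vif_reduction> threshold %g: retained %d, dropped %d\n",
              x$threshold, length(x$retained), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) {
    cat("dropped:", paste(x$dropped$variable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.vif_reduction <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$final_vifs, status = "retained",
                  iteration = NA_integer_),
    dplyr::mutate(x$dropped, status = "dropped")
  )
}

#' @export
glance.vif_reduction <- function(x, ...) {
  tibble(
    n_retained = length(x$retained),
    n_dropped = nrow(x$dropped),
    max_final_vif = max(x$final_vifs$vif),
    threshold = x$threshold
  )
}
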