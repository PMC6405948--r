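#' Random-forest ensemble for threatened-species presence
#'
#' Fits `n_runs` random-forest classifiers of plot-level presence/absence
#' on the covariates, each on an independent uniform split of the plots
#' into a training fraction (default 70%) and a held-out test set.
#' Variable importance is the mean decrease in the Gini index, recorded
#' raw and standardized within each run by dividing by the most important
#' variable (so every run's maximum is exactly 1). Training accuracy is
#' the out-of-bag accuracy on the training partition; test accuracy the
#' proportion of held-out plots classified correctly by majority vote.
#'
#' Hyperparameters are pinned rather than left to drift: 500 trees,
#' `floor(sqrt(p))` candidate variables per split, unlimited depth.
#'
#' @param covariates All-numeric covariate tibble (`plot_id` ignored).
#' @param presence Logical or 0/1 vector, one element per plot.
#' @param n_runs Number of resampled model fits.
#' @param train_fraction Fraction of plots used for training each run.
#' @param ntree Trees per forest.
#' @param seed Master seed; each run's split and fit use named substreams.
#' @return An object of class `importance_ensemble`: `importance` (tibble:
#'   `run`, `variable`, `gini`, `standardized`), `accuracy` (tibble:
#'   `run`, `train_accuracy`, `test_accuracy`) and the settings used.
#'   `tidy()` returns the per-run importances, `glance()` accuracy
#'   summaries (mean, SD and SE across runs).
#' @export
fit_presence_ensemble <- function(covariates, presence, n_runs = 20,
                                  train_fraction = 0.7, ntree = 500,
                                  seed = 1) {
  x <- drop_plot_id(covariates)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("Covariates must be all numeric; see encode_covariates().",
          class = "saiplan_format_error")
  }
  y <- as.integer(as.logical(presence))
  if (length(y) != nrow(x)) {
    abort("`presence` must have one element per plot.",
          class = "saiplan_data_error")
  }
  if (length(unique(y)) < 2L) {
    abort("degenerate response: presence vector holds a single class.",
          class = "saiplan_data_error")
  }
  n <- nrow(x)
  n_train <- round(train_fraction * n)
  if (n_train < 2L || n_train >= n) {
    abort("`train_fraction` leaves too few plots for train or test.",
          class = "saiplan_data_error")
  }
  mtry <- max(1L, floor(sqrt(ncol(x))))
  xdf <- as.data.frame(x)

  imp <- vector("list", n_runs)
  acc <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    idx <- with_substream(seed, paste0("split_run", run), {
      repeat {
        cand <- sample.int(n, n_train)
        if (length(unique(y[cand])) == 2L) break
        inform(sprintf("Run %d: single-class training split, resplitting.",
                       run))
      }
      cand
    })
    fit <- with_substream(seed, paste0("fit_run", run), {
      randomForest::randomForest(
        x = xdf[idx, , drop = FALSE],
        y = factor(y[idx], levels = c(0L, 1L)),
        ntree = ntree, mtry = mtry
      )
    })
    gini <- fit$importance[, "MeanDecreaseGini"]
    train_pred <- predict(fit) # out-of-bag votes on the training plots
    test_pred <- predict(fit, newdata = xdf[-idx, , drop = FALSE])
    imp[[run]] <- tibble(
      run = run, variable = names(x), gini = unname(gini),
      standardized = unname(gini) / max(gini)
    )
    acc[[run]] <- tibble(
      run = run,
      train_accuracy = mean(as.integer(as.character(train_pred)) == y[idx],
                            na.rm = TRUE),
      test_accuracy = mean(as.integer(as.character(test_pred)) == y[-idx])
    )
  }

  structure(
    list(
      importance = dplyr::bind_rows(imp),
      accuracy = dplyr::bind_rows(acc),
      n_runs = n_runs, train_fraction = train_fraction,
      ntree = ntree, mtry = mtry, seed = seed
    ),
    class = "importance_ensemble"
  )
}

#' Summarize standardized importances across runs
#'
#' Ranks variables by median standardized Gini importance across the
#' ensemble's runs (ties broken alphabetically), with quartiles for a
#' boxplot-style display.
#'
#' @param ensemble An `importance_ensemble`.
#' @return Tibble: `variable`, `median`, `q25`, `q75`, `rank`.
#' @export
summarize_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "importance_ensemble"))
  out <- ensemble$importance |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      median = median(.data$standardized),
      q25 = unname(quantile(.data$standardized, 0.25)),
      q75 = unname(quantile(.data$standardized, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$median), .data$variable)
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
print.importance_ensemble <- function(x, ...) {
  cat(sprintf(
    "<importance_ensemble> %d runs, train fraction %.2f, %d trees, mtry %d\n",
    x$n_runs, x$train_fraction, x$ntree, x$mtry))
  print(head(summarize_importance(x), 5))
  invisible(x)
}

#' @export
tidy.importance_ensemble <- function(x, ...) x$importance

#' @export
glance.importance_ensemble <- function(x, ...) {
  tibble(
    n_runs = x$n_runs,
    train_accuracy_mean = mean(x$accuracy$train_accuracy),
    train_accuracy_sd = sd(x$accuracy$train_accuracy),
    train_accuracy_se = sd(x$accuracy$train_accuracy) / sqrt(x$n_runs),
    test_accuracy_mean = mean(x$accuracy$test_accuracy),
    test_accuracy_sd = sd(x$accuracy$test_accuracy),
    test_accuracy_se = sd(x$accuracy$test_accuracy) / sqrt(x$n_runs),
    top_variable = summarize_importance(x)$variable[1]
  )
}

#' Boxplot of standardized variable importances
#'
#' @param object An `importance_ensemble`.
#' @param ... Unused.
#' @return A ggplot: one box per variable, ordered by median standardized
#'   mean-decrease-in-Gini importance.
#' @export
autoplot.importance_ensemble <- function(object, ...) {
  ord <- rev(summarize_importance(object)$variable)
  dat <- dplyr::mutate(object$importance,
                       variable = factor(.data$variable, levels = ord))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$variable,
                                    y = .data$standardized)) +
    ggplot2::geom_boxplot() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Standardized mean decrease in Gini") +
    ggplot2::theme_minimal()
}
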