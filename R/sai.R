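#' Species Accumulation Index
#'
#' Compares the number of target species represented in surrogate-selected
#' sites (`S`) with the optimum achievable in the same number of sites
#' (`O`) and the mean over random site sets (`R`). Positive values mean
#' better-than-random surrogacy; 1 is optimal; values at or above 0.2 are
#' conventionally read as a good or reliable surrogate.
#'
#' Two variants are available. `"range_consistent"` (the default) is
#' `(S - R) / (O - R)`, which actually realizes the stated range from
#' `-Inf` to 1 with 1 attained iff `S = O`. `"as_printed"` is
#' `(S - R) / (O - S)`, which returns an `Inf` sentinel when `S = O`.
#' When `O = R` surrogacy is unmeasurable and `NaN` is returned with a
#' warning.
#'
#' @param s,o,r Species counts for the surrogate, optimal and random
#'   selections (`s` may be a vector; `o`, `r` scalars or vectors of the
#'   same length).
#' @param variant `"range_consistent"` or `"as_printed"`.
#' @return Numeric vector of SAI values.
#' @export
#' @examples
#' sai(25, 30, 20)                        # 0.5
#' sai(25, 30, 20, variant = "as_printed") # 1.0
sai <- function(s, o, r, variant = c("range_consistent", "as_printed")) {
  variant <- match.arg(variant)
  if (any(o < r)) {
    abort("SAI requires O >= R.", class = "saiplan_data_error")
  }
  undef <- o == r
  if (any(undef)) {
    warn("O equals R: surrogacy unmeasurable, returning NaN.")
  }
  out <- if (variant == "range_consistent") {
    (s - r) / (o - r)
  } else {
    ifelse(s == o & s > r, Inf, (s - r) / (o - s))
  }
  out[undef] <- NaN
  out
}

#' Random-baseline species representation
#'
#' Mean number of unique target species represented by uniform
#' without-replacement draws of `k` plots.
#'
#' @param occurrence Occurrence tibble.
#' @param target Target species ids (default: attached threatened set).
#' @param k Number of plots per draw (`k = 0` returns 0).
#' @param n_random Number of random draws.
#' @param seed Seed for the draws.
#' @return A single number: the mean species count across draws.
#' @export
random_baseline <- function(occurrence, target = NULL, k, n_random = 1000,
                            seed = 1) {
  m <- occurrence_cells(occurrence)
  target <- target %||% threatened_species(occurrence)
  if (length(target) == 0L) {
    abort("Target species set is empty.", class = "saiplan_data_error")
  }
  tm <- m[, target, drop = FALSE]
  if (k > nrow(tm)) {
    abort("`k` exceeds the number of plots.", class = "saiplan_data_error")
  }
  if (k == 0L) return(0)
  counts <- with_substream(seed, "random_baseline", {
    vapply(seq_len(n_random), function(i) {
      idx <- sample.int(nrow(tm), k)
      sum(colSums(tm[idx, , drop = FALSE]) > 0L)
    }, numeric(1))
  })
  mean(counts)
}

#' Configuration for a surrogacy evaluation
#'
#' @param q_values Percentages of plots assumed to have species data when
#'   calibrating the surrogate (default 5, 10, ..., 60).
#' @param n_models Surrogate model repetitions per q (default 100).
#' @param n_random Random draws for the baseline `R` (default 1000).
#' @param surrogate_variables Covariate names the surrogate may use (e.g.
#'   soil carbon alone; abiotic variables with or without soil carbon).
#' @param site_budget Number of sites at which `S`, `O` and `R` are
#'   compared; `NULL` (default) uses the size of the full-data greedy
#'   selection, i.e. the smallest set representing every representable
#'   target species.
#' @param variant SAI variant, see [sai()].
#' @param ntree Trees per surrogate regression forest.
#' @param seed Master seed; subset draws and forest fits use named
#'   substreams so paired comparisons can share them.
#' @return A list of class `sai_config`.
#' @export
sai_config <- function(q_values = seq(5, 60, by = 5),
                       n_models = 100,
                       n_random = 1000,
                       surrogate_variables = character(),
                       site_budget = NULL,
                       variant = c("range_consistent", "as_printed"),
                       ntree = 500,
                       seed = 1) {
  variant <- match.arg(variant)
  if (any(q_values <= 0) || any(q_values >= 100)) {
    abort("`q_values` must lie in (0, 100).", class = "saiplan_config_error")
  }
  if (n_models < 1 || n_random < 1) {
    abort("`n_models` and `n_random` must be positive.",
          class = "saiplan_config_error")
  }
  structure(
    list(q_values = as.double(q_values), n_models = as.integer(n_models),
         n_random = as.integer(n_random),
         surrogate_variables = as.character(surrogate_variables),
         site_budget = site_budget, variant = variant,
         ntree = as.integer(ntree), seed = as.integer(seed)),
    class = "sai_config"
  )
}

# Align a covariate tibble to the occurrence plot order; error on mismatch.
align_covariates <- function(occurrence, covariates) {
  covariates <- as_tibble(covariates)
  plots <- as.character(as_tibble(occurrence)[[1]])
  if (!setequal(covariates$plot_id, plots)) {
    abort("Occurrence and covariate tables cover different plots.",
          class = "saiplan_data_error")
  }
  covariates[match(plots, covariates$plot_id), , drop = FALSE]
}

#' Evaluate a surrogate variable set with the SAI
#'
#' Mimics the planning situation in which species data exist for only q%
#' of the planning plots. For each q and each of `n_models` repetitions:
#' draw a uniform subset of `ceiling(q% * n_plots)` plots; run the greedy
#' richness selection within the subset and score its plots (see
#' [importance_scores()]); fit a random-forest regression of those scores
#' on the subset's surrogate covariates (`ntree` trees, `p/3` candidate
#' variables per split); predict scores for all plots, with calibration
#' plots taking their out-of-bag predictions so a surrogate is credited
#' only for what its covariates generalize, never for memorizing the
#' calibration scores; select the top
#' `site_budget` plots by predicted score (ties by plot order); and count
#' the unique target species represented (`S`). `O` is the representation
#' of the full-data greedy selection at the same budget, `R` the random
#' baseline from [random_baseline()]; each repetition's SAI uses its own
#' `S` with the shared `O` and `R`.
#'
#' Subsets containing no target-species occurrence cannot calibrate a
#' selection and are redrawn (with a message); persistent failure is an
#' error.
#'
#' @param occurrence Occurrence tibble.
#' @param covariates Covariate tibble (`plot_id` plus numeric columns).
#' @param config An [sai_config()]; `surrogate_variables` must be present
#'   in `covariates`.
#' @param target Target species ids (default: attached threatened set).
#' @return An object of class `sai_curve`: a tibble with one row per q
#'   (`q`, `S_mean`, `O`, `R_mean`, `sai_mean`, `ci_low`, `ci_high`, 95%
#'   percentile interval across repetitions) carrying the per-repetition
#'   SAI values in the `sai_values` list column; the configuration and
#'   the 0.2 reliability threshold are stored as attributes.
#' @export
evaluate_surrogate <- function(occurrence, covariates, config,
                               target = NULL) {
  stopifnot(inherits(config, "sai_config"))
  target <- target %||% threatened_species(occurrence)
  if (length(target) == 0L) {
    abort("Target species set is empty.", class = "saiplan_data_error")
  }
  covariates <- align_covariates(occurrence, covariates)
  vars <- config$surrogate_variables
  if (length(vars) == 0L) {
    abort("`surrogate_variables` is empty.", class = "saiplan_config_error")
  }
  missing <- setdiff(vars, names(covariates))
  if (length(missing) > 0L) {
    abort(sprintf("Surrogate variables absent from covariates: %s",
                  paste(missing, collapse = ", ")),
          class = "saiplan_config_error")
  }
  xall <- as.data.frame(covariates[vars])
  if (!all(vapply(xall, is.numeric, logical(1)))) {
    abort("Surrogate variables must be numeric; see encode_covariates().",
          class = "saiplan_format_error")
  }

  m <- occurrence_cells(occurrence)
  tm <- m[, target, drop = FALSE]
  n <- nrow(m)

  full_sel <- greedy_richness_selection(occurrence, target = target)
  budget <- min(config$site_budget %||% nrow(full_sel$steps), n)
  if (budget < 1L) {
    abort("Site budget is zero: no target species occurs in any plot.",
          class = "saiplan_data_error")
  }
  o_val <- if (budget >= nrow(full_sel$steps)) {
    max(full_sel$steps$represented)
  } else {
    full_sel$steps$represented[budget]
  }
  r_mean <- random_baseline(occurrence, target = target, k = budget,
                            n_random = config$n_random,
                            seed = substream_seed(config$seed, "baseline"))

  mtry <- max(1L, floor(length(vars) / 3))
  occ_tbl <- as_tibble(occurrence)

  rows <- purrr::map(config$q_values, function(q) {
    m_sub <- ceiling(q / 100 * n)
    s_vals <- numeric(config$n_models)
    for (rep in seq_len(config$n_models)) {
      idx <- NULL
      for (attempt in 0:config$n_models) {
        cand <- with_substream(
          config$seed, sprintf("subset_q%g_rep%d_try%d", q, rep, attempt),
          sample.int(n, m_sub)
        )
        if (sum(tm[cand, , drop = FALSE]) > 0L) {
          idx <- cand
          break
        }
        inform(sprintf(
          "q=%g rep %d: subset holds no target species, redrawing.", q, rep))
      }
      if (is.null(idx)) {
        abort("Too many subset redraws without target species.",
              class = "saiplan_data_error")
      }
      sub_occ <- occ_tbl[idx, , drop = FALSE]
      sub_sel <- greedy_richness_selection(sub_occ, target = target)
      scores <- importance_scores(sub_sel)$score
      if (length(scores) < 2L || sd(scores) == 0) {
        pred <- rep(scores[1], n) # constant calibration scores
      } else {
        fit <- with_substream(
          config$seed, sprintf("rf_q%g_rep%d", q, rep),
          # scores are legitimately few-valued (gain ratios); silence the
          # regression-on-few-unique-values nag
          suppressWarnings(randomForest::randomForest(
            x = xall[idx, , drop = FALSE], y = scores,
            ntree = config$ntree, mtry = mtry
          ))
        )
        pred <- predict(fit, xall)
        # calibration plots take their out-of-bag predictions: in-sample
        # predictions memorize the training scores, which would let even
        # an uninformative covariate "rediscover" the subset's best plots
        # and inflate the surrogate's apparent efficiency
        pred[idx] <- fit$predicted
      }
      top <- order(-pred)[seq_len(budget)] # stable: ties by plot order
      s_vals[rep] <- sum(colSums(tm[top, , drop = FALSE]) > 0L)
    }
    sai_vals <- sai(s_vals, o_val, r_mean, variant = config$variant)
    tibble(
      q = q,
      S_mean = mean(s_vals),
      O = o_val,
      R_mean = r_mean,
      sai_mean = mean(sai_vals),
      ci_low = unname(quantile(sai_vals, 0.025)),
      ci_high = unname(quantile(sai_vals, 0.975)),
      sai_values = list(sai_vals)
    )
  })

  curve <- dplyr::bind_rows(rows)
  structure(curve,
            class = c("sai_curve", class(curve)),
            config = config,
            site_budget = budget,
            reliability_threshold = 0.2,
            surrogate = paste(vars, collapse = "+"))
}

#' Paired comparison of surrogate variable sets
#'
#' Runs [evaluate_surrogate()] for each named variable set on identical
#' subset draws and forest-fit seeds (shared substreams from the config
#' seed), so per-q differences between sets are paired and
#' variance-reduced. Duplicated sets therefore yield bitwise-identical
#' curves and exactly zero differences.
#'
#' @param occurrence,covariates,target As in [evaluate_surrogate()].
#' @param variable_sets Named list of character vectors of covariate
#'   names (at least two sets).
#' @param config An [sai_config()]; its `surrogate_variables` field is
#'   ignored in favour of each set.
#' @return An object of class `sai_comparison`: `curves` (named list of
#'   `sai_curve`) and `differences` (tibble: `set_a`, `set_b`, `q`,
#'   `mean_diff`, `ci_low`, `ci_high` from the paired per-repetition
#'   differences).
#' @export
compare_surrogates <- function(occurrence, covariates, variable_sets,
                               config, target = NULL) {
  if (length(variable_sets) < 2L || is.null(names(variable_sets)) ||
      any(names(variable_sets) == "")) {
    abort("`variable_sets` must be a named list of at least two sets.",
          class = "saiplan_config_error")
  }
  curves <- purrr::map(variable_sets, function(vars) {
    cfg <- config
    cfg$surrogate_variables <- vars
    evaluate_surrogate(occurrence, covariates, cfg, target = target)
  })
  sets <- names(variable_sets)
  pairs <- utils::combn(sets, 2, simplify = FALSE)
  differences <- purrr::map_dfr(pairs, function(pr) {
    a <- curves[[pr[1]]]
    b <- curves[[pr[2]]]
    purrr::map_dfr(seq_len(nrow(a)), function(i) {
      d <- a$sai_values[[i]] - b$sai_values[[i]]
      tibble(set_a = pr[1], set_b = pr[2], q = a$q[i],
             mean_diff = mean(d),
             ci_low = unname(quantile(d, 0.025)),
             ci_high = unname(quantile(d, 0.975)))
    })
  })
  structure(list(curves = curves, differences = differences),
            class = "sai_comparison")
}

#' @export
tidy.sai_curve <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "config") <- NULL
  out$sai_values <- NULL
  out
}

#' @export
glance.sai_curve <- function(x, ...) {
  tibble(
    surrogate = attr(x, "surrogate"),
    site_budget = attr(x, "site_budget"),
    sai_grand_mean = mean(x$sai_mean),
    min_sai = min(x$sai_mean),
    max_sai = max(x$sai_mean)
  )
}

#' @export
print.sai_curve <- function(x, ...) {
  cat(sprintf("<sai_curve> surrogate: %s (site budget %d)\n",
              attr(x, "surrogate"), attr(x, "site_budget")))
  print(tidy(x))
  invisible(x)
}

#' @export
print.sai_comparison <- function(x, ...) {
  cat(sprintf("<sai_comparison> %d surrogate sets\n", length(x$curves)))
  print(x$differences)
  invisible(x)
}

#' SAI curve with 95% intervals and the 0.2 reliability line
#'
#' @param object An `sai_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sai_curve <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, y = .data$sai_mean)) +
    ggplot2::geom_hline(yintercept = attr(object, "reliability_threshold"),
                        linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 1) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "q (% of plots with species data)",
                  y = "Species Accumulation Index") +
    ggplot2::theme_minimal()
}

#' Multi-set SAI comparison figure
#'
#' @param object An `sai_comparison`.
#' @param ... Unused.
#' @return A ggplot with one colour per surrogate set, 95% intervals, and
#'   the 0.2 reliability reference line.
#' @export
autoplot.sai_comparison <- function(object, ...) {
  dat <- purrr::imap_dfr(object$curves, function(cv, nm) {
    dplyr::mutate(tidy(cv), surrogate = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, y = .data$sai_mean,
                                    colour = .data$surrogate)) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 1, position = ggplot2::position_dodge(2)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(2)) +
    ggplot2::labs(x = "q (% of plots with species data)",
                  y = "Species Accumulation Index", colour = NULL) +
    ggplot2::theme_minimal()
}
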