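#' Compare soil carbon across threatened-species count groups
#'
#' Groups plots by their number of threatened species (0, 1, 2, ...) and
#' tests whether mean soil carbon differs across groups with a one-way
#' ANOVA followed by Tukey's HSD for all pairwise contrasts (studentized
#' range, pooled within-group variance). Count groups with fewer than two
#' plots cannot support a within-group variance estimate and are merged
#' into the larger of their adjacent count categories, with a warning.
#'
#' @param data A data frame with one row per plot.
#' @param soil_carbon Column name (string) of the soil carbon values.
#' @param count Column name (string) of the per-plot threatened-species
#'   counts.
#' @return An object of class `group_test`: `groups` (tibble: `group`,
#'   `n`, `mean`), `anova_F`, `anova_p`, `pairwise` (tibble: `group_i`,
#'   `group_j`, `diff`, `p_adj`) and `merges` (any merged labels).
#'   `tidy()` returns the pairwise table, `glance()` the ANOVA row.
#' @export
#' @examples
#' d <- data.frame(soil_carbon = rnorm(60, 60, 10),
#'                 threatened_count = rep(0:2, each = 20))
#' soil_carbon_group_test(d)
soil_carbon_group_test <- function(data, soil_carbon = "soil_carbon",
                                   count = "threatened_count") {
  data <- as.data.frame(data)
  for (nm in c(soil_carbon, count)) {
    if (!nm %in% names(data)) {
      abort(sprintf("Column '%s' not found.", nm),
            class = "saiplan_data_error")
    }
  }
  sc <- as.numeric(data[[soil_carbon]])
  grp <- as.integer(data[[count]])
  if (any(is.na(sc)) || any(is.na(grp))) {
    abort("Missing values in soil carbon or counts.",
          class = "saiplan_data_error")
  }

  merges <- tibble(from = integer(), to = integer())
  repeat {
    tab <- table(grp)
    labels <- as.integer(names(tab))
    small <- labels[tab < 2L]
    if (length(small) == 0L || length(labels) < 2L) break
    g <- small[1]
    others <- setdiff(labels, g)
    dist <- abs(others - g)
    nearest <- others[dist == min(dist)]
    # among equally near neighbours take the better-populated one
    to <- nearest[which.max(tab[as.character(nearest)])]
    warn(sprintf(
      "Merging threatened-count group %d (n=%d) into adjacent group %d.",
      g, as.integer(tab[as.character(g)]), to))
    merges <- dplyr::bind_rows(merges, tibble(from = g, to = to))
    grp[grp == g] <- to
  }

  if (length(unique(grp)) < 2L) {
    abort("All plots fall in one threatened-count group; nothing to test.",
          class = "saiplan_data_error")
  }

  f <- factor(grp)
  fit <- aov(sc ~ f)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$f
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  pairwise <- tibble(
    group_i = as.integer(pairs[, 2]),
    group_j = as.integer(pairs[, 1]),
    diff = unname(tuk[, "diff"]),
    p_adj = unname(tuk[, "p adj"])
  )

  groups <- tibble(group = as.integer(levels(f))) |>
    dplyr::mutate(
      n = as.integer(table(f)),
      mean = as.numeric(tapply(sc, f, mean))
    )

  structure(
    list(
      groups = groups,
      anova_F = an[["F value"]][1],
      anova_p = an[["Pr(>F)"]][1],
      pairwise = pairwise,
      merges = merges
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %d groups, ANOVA F = %.3f, p = %.4g\n",
              nrow(x$groups), x$anova_F, x$anova_p))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.group_test <- function(x, ...) x$pairwise

#' @export
glance.group_test <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), anova_F = x$anova_F,
         anova_p = x$anova_p, n_merged = nrow(x$merges))
}

#' Boxplot of soil carbon by threatened-species count
#'
#' @param data Plot-level data frame.
#' @param soil_carbon,count Column names as in [soil_carbon_group_test()].
#' @return A ggplot.
#' @export
plot_soil_carbon_groups <- function(data, soil_carbon = "soil_carbon",
                                    count = "threatened_count") {
  ggplot2::ggplot(
    as.data.frame(data),
    ggplot2::aes(x = factor(.data[[count]]), y = .data[[soil_carbon]])
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Threatened species per plot",
                  y = "Soil organic carbon (Mg C ha⁻¹)") +
    ggplot2::theme_minimal()
}
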