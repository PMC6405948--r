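# Occurrence tibble -> integer matrix (plots x species), rownames plot ids.
occurrence_cells <- function(occurrence) {
  occurrence <- as_tibble(occurrence)
  m <- as.matrix(occurrence[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(occurrence[[1]])
  m
}

#' Greedy richness selection of complementary plots
#'
#' The Rebelo-Siegfried species-richness algorithm: repeatedly select the
#' plot holding the largest number of target species not yet represented
#' by previously selected plots (ties broken by input plot order), until
#' no plot adds a new target species or the site budget is exhausted.
#' Target species present in no plot are reported as unrepresentable, not
#' an error.
#'
#' @param occurrence Occurrence tibble (`plot_id` plus 0/1 species
#'   columns).
#' @param target Character vector of target species ids; defaults to the
#'   threatened species attached to `occurrence` (see
#'   [threatened_species()]). Must be a nonempty subset of the species
#'   columns.
#' @param site_budget Maximum number of plots to select (default:
#'   unlimited, i.e. stop at full representation).
#' @return An object of class `selection_result`: `steps` (tibble: `step`,
#'   `plot_id`, `gain`, `represented` cumulative), plus the target set,
#'   unrepresentable species, and the plot ids of the input. `tidy()`
#'   returns the step table, `glance()` a one-row summary.
#' @export
#' @examples
#' occ <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
#'                       A = c(1, 0, 0), B = c(1, 1, 0), C = c(0, 1, 1))
#' greedy_richness_selection(occ, target = c("A", "B", "C"))
greedy_richness_selection <- function(occurrence, target = NULL,
                                      site_budget = Inf) {
  m <- occurrence_cells(occurrence)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    abort("Occurrence matrix is empty.", class = "saiplan_data_error")
  }
  target <- target %||% threatened_species(occurrence)
  if (length(target) == 0L) {
    abort("Target species set is empty.", class = "saiplan_data_error")
  }
  missing <- setdiff(target, colnames(m))
  if (length(missing) > 0L) {
    abort(sprintf("Target species absent from occurrence columns: %s",
                  paste(head(missing, 5L), collapse = ", ")),
          class = "saiplan_data_error")
  }
  tm <- m[, target, drop = FALSE]
  unrepresentable <- target[colSums(tm) == 0L]

  uncovered <- colnames(tm)[colSums(tm) > 0L]
  steps <- list()
  k <- 0L
  while (length(uncovered) > 0L && k < site_budget) {
    gains <- rowSums(tm[, uncovered, drop = FALSE])
    best <- which.max(gains) # first maximum = input plot order tie-break
    if (gains[best] == 0L) break
    k <- k + 1L
    chosen <- rownames(tm)[best]
    newly <- uncovered[tm[best, uncovered] > 0L]
    uncovered <- setdiff(uncovered, newly)
    steps[[k]] <- tibble(step = k, plot_id = chosen,
                         gain = length(newly),
                         represented = length(target) -
                           length(unrepresentable) - length(uncovered))
  }
  steps <- if (k > 0L) dplyr::bind_rows(steps) else
    tibble(step = integer(), plot_id = character(), gain = integer(),
           represented = integer())

  structure(
    list(
      steps = steps,
      target = target,
      unrepresentable = unrepresentable,
      plot_ids = rownames(m)
    ),
    class = "selection_result"
  )
}

#' Plot importance scores from a greedy selection
#'
#' Scores range from 0 (plot not part of the optimal conservation
#' scenario) to 1 (the plot with the highest richness of as-yet
#' unprotected target species): each selected plot scores its marginal
#' species gain divided by the maximum gain, so the first-selected plot
#' always scores 1; unselected plots score 0.
#'
#' @param selection A `selection_result`.
#' @return Tibble with `plot_id` and `score` for every input plot.
#' @export
importance_scores <- function(selection) {
  stopifnot(inherits(selection, "selection_result"))
  score <- setNames(rep(0, length(selection$plot_ids)), selection$plot_ids)
  if (nrow(selection$steps) > 0L) {
    score[selection$steps$plot_id] <-
      selection$steps$gain / max(selection$steps$gain)
  }
  tibble(plot_id = selection$plot_ids, score = unname(score))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d plots selected; %d/%d target species represented\n",
    nrow(x$steps),
    if (nrow(x$steps) > 0) max(x$steps$represented) else 0L,
    length(x$target)))
  if (length(x$unrepresentable) > 0) {
    cat(sprintf("unrepresentable: %d species\n", length(x$unrepresentable)))
  }
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$steps

#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    n_selected = nrow(x$steps),
    n_target = length(x$target),
    n_represented = if (nrow(x$steps) > 0) max(x$steps$represented) else 0L,
    n_unrepresentable = length(x$unrepresentable)
  )
}
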