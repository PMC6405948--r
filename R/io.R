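#' Read a plot-by-species occurrence matrix from CSV
#'
#' Expects a comma-separated, UTF-8, headered file whose first column holds
#' plot identifiers and whose remaining columns are 0/1 species incidences.
#' Any non-binary cell or duplicated plot/species identifier is a format
#' error naming the offending row or column.
#'
#' @param path CSV file path.
#' @param threatened Optional: either a character vector of threatened
#'   species ids or the path to a one-column CSV listing them. When absent,
#'   no species is flagged.
#' @return A tibble (`plot_id` plus one integer 0/1 column per species)
#'   with the threatened ids in the `"threatened"` attribute, retrievable
#'   with [threatened_species()].
#' @export
read_occurrence <- function(path, threatened = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Occurrence file not found: %s", path),
          class = "saiplan_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) {
    abort("Occurrence CSV needs a plot-id column plus at least one species.",
          class = "saiplan_format_error")
  }
  names(df)[1] <- "plot_id"
  df$plot_id <- as.character(df$plot_id)
  validate_occurrence(df)
  for (j in seq(2L, ncol(df))) df[[j]] <- as.integer(df[[j]])
  thr <- character()
  if (!is.null(threatened)) {
    if (length(threatened) == 1L && file.exists(threatened)) {
      thr_df <- readr::read_csv(threatened, show_col_types = FALSE,
                                progress = FALSE)
      thr <- as.character(thr_df[[1]])
    } else {
      thr <- as.character(threatened)
    }
    missing <- setdiff(thr, names(df)[-1])
    if (length(missing) > 0L) {
      abort(sprintf("Threatened species not present in occurrence columns: %s",
                    paste(head(missing, 5L), collapse = ", ")),
            class = "saiplan_format_error")
    }
  }
  attr(df, "threatened") <- thr
  df
}

validate_occurrence <- function(df) {
  if (anyDuplicated(df$plot_id)) {
    abort(sprintf("Duplicate plot ids: %s",
                  paste(unique(df$plot_id[duplicated(df$plot_id)]),
                        collapse = ", ")),
          class = "saiplan_format_error")
  }
  sp <- names(df)[-1]
  if (anyDuplicated(sp)) {
    abort(sprintf("Duplicate species ids: %s",
                  paste(unique(sp[duplicated(sp)]), collapse = ", ")),
          class = "saiplan_format_error")
  }
  for (j in seq(2L, ncol(df))) {
    v <- df[[j]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      abort(sprintf("Non-binary cell at row %d, column '%s'.",
                    bad[1], names(df)[j]),
            class = "saiplan_format_error")
    }
  }
  invisible(df)
}

#' Write an occurrence matrix to CSV
#'
#' @param occurrence Occurrence tibble (`plot_id` first column).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_occurrence <- function(occurrence, path) {
  readr::write_csv(occurrence, path)
  invisible(path)
}

#' Read a plot covariate table from CSV
#'
#' First column holds plot identifiers; the remaining columns are numeric or
#' categorical environmental variables. Rows containing missing values are
#' rejected with a report (the analysis defines no imputation procedure).
#'
#' @param path CSV file path.
#' @param soil_carbon Name of the designated soil organic carbon column
#'   (Mg C ha^-1 to 30 cm). Use `NULL` to skip the check.
#' @return A tibble with `plot_id` as first column.
#' @export
read_covariates <- function(path, soil_carbon = "soil_carbon") {
  if (!file.exists(path)) {
    abort(sprintf("Covariate file not found: %s", path),
          class = "saiplan_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "plot_id"
  df$plot_id <- as.character(df$plot_id)
  if (anyDuplicated(df$plot_id)) {
    abort("Duplicate plot ids in covariate table.",
          class = "saiplan_format_error")
  }
  na_rows <- which(rowSums(is.na(df)) > 0)
  if (length(na_rows) > 0L) {
    abort(sprintf("Missing values in covariate rows: %s",
                  paste(head(na_rows, 10L), collapse = ", ")),
          class = "saiplan_format_error")
  }
  if (!is.null(soil_carbon)) {
    if (!soil_carbon %in% names(df)) {
      abort(sprintf("Designated soil-carbon column '%s' is absent.",
                    soil_carbon),
            class = "saiplan_format_error")
    }
    if (!is.numeric(df[[soil_carbon]])) {
      abort(sprintf("Soil-carbon column '%s' must be numeric.", soil_carbon),
            class = "saiplan_format_error")
    }
  }
  df
}

#' Indicator-encode categorical covariates
#'
#' Expands each character or factor column into one indicator column per
#' level minus an alphabetical reference level (so that variance inflation
#' factors stay well defined); numeric columns pass through unchanged, and
#' row count and plot order are preserved. A categorical column with a
#' single level carries no information and is dropped with a warning.
#'
#' @param data Covariate tibble (an optional `plot_id` column passes
#'   through untouched).
#' @return An all-numeric tibble; new columns are named
#'   `<variable>_<level>`.
#' @export
#' @examples
#' encode_covariates(tibble::tibble(x = 1:3, lf = c("A", "B", "C")))
encode_covariates <- function(data) {
  data <- as_tibble(data)
  out <- list()
  for (nm in names(data)) {
    col <- data[[nm]]
    if (nm == "plot_id" || is.numeric(col) || is.logical(col)) {
      out[[nm]] <- if (is.logical(col)) as.integer(col) else col
      next
    }
    lev <- sort(unique(as.character(col)))
    if (length(lev) < 2L) {
      warn(sprintf("Dropping single-level categorical column '%s'.", nm))
      next
    }
    for (lv in lev[-1]) {
      out[[paste0(nm, "_", lv)]] <- as.integer(as.character(col) == lv)
    }
  }
  as_tibble(out)
}
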