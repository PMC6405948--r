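#' Configuration for a synthetic plot-by-species landscape
#'
#' Builds the parameter set for [simulate_landscape()]. The defaults emulate
#' the PEBANPA permanent-plot network in Southern Patagonia: 145 plots, 470
#' vascular plant species of which 37 are listed as threatened, a
#' right-skewed soil organic carbon stock, and a positive coupling between
#' soil carbon and threatened-species occurrence, so that most plots hold
#' zero or one threatened species.
#'
#' @param n_plots Number of plots (>= 2).
#' @param n_species Total number of species.
#' @param n_threatened Number of threatened species (<= `n_species`).
#' @param n_covariates Number of environmental covariates besides soil
#'   carbon (standard-normal scores).
#' @param soc_effect Log-odds slope of threatened-species occurrence on
#'   standardized soil carbon (positive values concentrate threatened
#'   species on carbon-rich plots).
#' @param baseline_prevalence_range Range of per-species baseline occurrence
#'   probabilities for non-threatened species.
#' @param threatened_prevalence_range Range of per-species baseline
#'   occurrence probabilities for threatened species. The default is
#'   calibrated so that, together with the default `soc_effect`, the
#'   majority of plots carry zero or one threatened species while every
#'   threatened species still occupies a plot or two.
#' @param collinear_pairs Number of covariates that receive a near-duplicate
#'   column (correlation about 0.98), used to exercise collinearity
#'   screening.
#' @param nontarget_coupling Log-odds slope of non-threatened occurrence on
#'   standardized soil carbon. Zero by default so any surrogacy signal
#'   traces to the threatened set.
#' @param seed Master seed; named substreams for covariates and occurrence
#'   are derived from it (see [substream_seed()]).
#' @return A list of class `landscape_config`.
#' @export
#' @examples
#' cfg <- landscape_config(n_plots = 40, n_species = 60, n_threatened = 8)
#' cfg$n_plots
landscape_config <- function(n_plots = 145,
                             n_species = 470,
                             n_threatened = 37,
                             n_covariates = 8,
                             soc_effect = 2,
                             baseline_prevalence_range = c(0.02, 0.30),
                             threatened_prevalence_range = c(0.002, 0.008),
                             collinear_pairs = 1,
                             nontarget_coupling = 0,
                             seed = 4913) {
  cfg <- structure(
    list(
      n_plots = as.integer(n_plots),
      n_species = as.integer(n_species),
      n_threatened = as.integer(n_threatened),
      n_covariates = as.integer(n_covariates),
      soc_effect = as.double(soc_effect),
      baseline_prevalence_range = as.double(baseline_prevalence_range),
      threatened_prevalence_range = as.double(threatened_prevalence_range),
      collinear_pairs = as.integer(collinear_pairs),
      nontarget_coupling = as.double(nontarget_coupling),
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
  validate_landscape_config(cfg)
  cfg
}

#' @rdname landscape_config
#' @export
default_config <- function() landscape_config()

validate_landscape_config <- function(cfg) {
  bad <- function(msg) {
    abort(msg, class = "saiplan_config_error")
  }
  if (cfg$n_plots < 2L) bad("`n_plots` must be at least 2.")
  if (cfg$n_species < 1L) bad("`n_species` must be positive.")
  if (cfg$n_threatened < 0L || cfg$n_threatened > cfg$n_species) {
    bad("`n_threatened` must lie in [0, n_species].")
  }
  if (cfg$n_covariates < 0L) bad("`n_covariates` must be nonnegative.")
  if (cfg$collinear_pairs < 0L || cfg$collinear_pairs > cfg$n_covariates) {
    bad("`collinear_pairs` must lie in [0, n_covariates].")
  }
  for (rng in list(cfg$baseline_prevalence_range,
                   cfg$threatened_prevalence_range)) {
    if (length(rng) != 2L || any(!is.finite(rng)) ||
        any(rng < 0) || any(rng > 1) || rng[1] > rng[2]) {
      bad("prevalence ranges must be ordered pairs of probabilities.")
    }
  }
  invisible(cfg)
}

# Domain-flavoured covariate names; padded with generic labels if needed.
covariate_name_pool <- c(
  "soil_age", "landform_index", "min_ndvi", "temp_wettest_quarter",
  "temp_coldest_quarter", "topographic_variability", "annual_precip",
  "elevation", "solar_radiation", "wind_speed"
)

#' Simulate a synthetic landscape
#'
#' Draws plot-level covariates and a plot-by-species presence/absence matrix
#' with the structure the downstream analysis assumes. Soil organic carbon
#' is log-normal (stocks are nonnegative and right-skewed in field data) and
#' standardized internally before use as a predictor; the other covariates
#' are standard normal, except that `collinear_pairs` of them receive a
#' near-duplicate column (correlation about 0.98). Each threatened species
#' occurs in a plot with probability
#' `plogis(qlogis(baseline) + soc_effect * z_soc)` where `z_soc` is the
#' plot's standardized soil carbon; non-threatened species are Bernoulli on
#' their baselines, independent of covariates unless `nontarget_coupling`
#' is nonzero. Species that land in zero plots are redrawn (with a message);
#' a species still absent after 100 redraws is dropped with a warning, since
#' an all-zero column carries no information for selection.
#'
#' @param config A [landscape_config()].
#' @return A list of class `saiplan_landscape` with elements
#'   * `occurrence`: tibble, `plot_id` plus one 0/1 column per species, with
#'     the threatened species ids stored in the `"threatened"` attribute;
#'   * `covariates`: tibble, `plot_id`, `soil_carbon` (Mg C ha^-1 to 30 cm,
#'     arbitrary calibration) and the environmental covariates;
#'   * `threatened`: character vector of threatened species ids;
#'   * `truth`: the generating slopes and per-species baselines;
#'   * `config`: the configuration used.
#' @export
#' @examples
#' land <- simulate_landscape(landscape_config(n_plots = 30, n_species = 40,
#'                                             n_threatened = 5, seed = 7))
#' dim(land$occurrence)
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  validate_landscape_config(config)
  n <- config$n_plots
  plot_ids <- sprintf("plot_%03d", seq_len(n))

  covs <- with_substream(config$seed, "covariates", {
    soil_carbon <- rlnorm(n, meanlog = log(60), sdlog = 0.5)
    base <- covariate_name_pool
    if (config$n_covariates > length(base)) {
      base <- c(base, sprintf("env_%02d", seq_len(config$n_covariates - length(base))))
    }
    nm <- base[seq_len(config$n_covariates)]
    env <- matrix(rnorm(n * config$n_covariates), nrow = n,
                  dimnames = list(NULL, nm))
    out <- tibble(plot_id = plot_ids, soil_carbon = soil_carbon)
    out <- dplyr::bind_cols(out, as_tibble(env))
    rho <- 0.98
    for (j in seq_len(config$collinear_pairs)) {
      twin <- rho * env[, j] + sqrt(1 - rho^2) * rnorm(n)
      out[[paste0(nm[j], "_alt")]] <- twin
    }
    out
  })

  # standardize on the log scale: carbon stocks are log-normal, and the
  # log transform keeps the logit-linear coupling out of its saturating
  # tail, so per-plot threatened counts stay in the observed 0-to-few range
  z_soc <- as.numeric(scale(log(covs$soil_carbon)))
  species_ids <- sprintf("sp_%04d", seq_len(config$n_species))
  threatened_ids <- species_ids[seq_len(config$n_threatened)]

  occ <- with_substream(config$seed, "occurrence", {
    thr_base <- runif(config$n_threatened,
                      config$threatened_prevalence_range[1],
                      config$threatened_prevalence_range[2])
    other_base <- runif(config$n_species - config$n_threatened,
                        config$baseline_prevalence_range[1],
                        config$baseline_prevalence_range[2])
    baselines <- c(thr_base, other_base)
    slopes <- c(rep(config$soc_effect, config$n_threatened),
                rep(config$nontarget_coupling,
                    config$n_species - config$n_threatened))
    cells <- matrix(0L, nrow = n, ncol = config$n_species,
                    dimnames = list(NULL, species_ids))
    n_resampled <- 0L
    dropped <- character()
    for (j in seq_len(config$n_species)) {
      p <- plogis(qlogis(baselines[j]) + slopes[j] * z_soc)
      draw <- rbinom(n, 1L, p)
      tries <- 0L
      while (sum(draw) == 0L && tries < 100L) {
        draw <- rbinom(n, 1L, p)
        tries <- tries + 1L
      }
      if (tries > 0L) n_resampled <- n_resampled + 1L
      if (sum(draw) == 0L) {
        dropped <- c(dropped, species_ids[j])
      } else {
        cells[, j] <- draw
      }
    }
    list(cells = cells, baselines = baselines, slopes = slopes,
         n_resampled = n_resampled, dropped = dropped)
  })

  if (occ$n_resampled > 0L) {
    inform(sprintf("Resampled %d species whose first draw occupied no plot.",
                   occ$n_resampled))
  }
  cells <- occ$cells
  if (length(occ$dropped) > 0L) {
    warn(sprintf("Dropped %d species absent from every plot after resampling: %s",
                 length(occ$dropped),
                 paste(head(occ$dropped, 5L), collapse = ", ")))
    keep <- setdiff(colnames(cells), occ$dropped)
    cells <- cells[, keep, drop = FALSE]
    threatened_ids <- setdiff(threatened_ids, occ$dropped)
  }

  occurrence <- dplyr::bind_cols(tibble(plot_id = plot_ids),
                                 as_tibble(cells))
  attr(occurrence, "threatened") <- threatened_ids

  structure(
    list(
      occurrence = occurrence,
      covariates = covs,
      threatened = threatened_ids,
      truth = list(
        soc_effect = config$soc_effect,
        nontarget_coupling = config$nontarget_coupling,
        baselines = setNames(occ$baselines, species_ids),
        dropped_species = occ$dropped
      ),
      config = config
    ),
    class = "saiplan_landscape"
  )
}

#' Threatened species ids attached to an occurrence table
#'
#' @param occurrence An occurrence tibble as produced by
#'   [simulate_landscape()] or [read_occurrence()].
#' @return Character vector of species ids (possibly empty).
#' @export
threatened_species <- function(occurrence) {
  thr <- attr(occurrence, "threatened", exact = TRUE)
  if (is.null(thr)) character() else thr
}

#' Write a landscape to CSV files
#'
#' Writes `occurrence.csv`, `covariates.csv` and `threatened.csv` (one
#' column, `species_id`) into `dir`, UTF-8 with header rows and plot ids in
#' the first column `plot_id`.
#'
#' @param landscape A `saiplan_landscape`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "saiplan_landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    occurrence = file.path(dir, "occurrence.csv"),
    covariates = file.path(dir, "covariates.csv"),
    threatened = file.path(dir, "threatened.csv")
  )
  readr::write_csv(landscape$occurrence, paths[["occurrence"]])
  readr::write_csv(landscape$covariates, paths[["covariates"]])
  readr::write_csv(tibble(species_id = landscape$threatened),
                   paths[["threatened"]])
  invisible(paths)
}

#' @export
print.saiplan_landscape <- function(x, ...) {
  cat(sprintf(
    "<saiplan_landscape> %d plots x %d species (%d threatened), %d covariates\n",
    nrow(x$occurrence), ncol(x$occurrence) - 1L, length(x$threatened),
    ncol(x$covariates) - 1L
  ))
  invisible(x)
}
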