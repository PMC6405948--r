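#' Run the full surrogacy analysis from one configuration
#'
#' Orchestrates the whole pipeline — simulate or ingest a landscape,
#' indicator-encode and VIF-screen the covariates, fit the
#' threatened-presence importance ensemble and the soil-carbon group
#' test, derive the optimal conservation scenario, and compute paired
#' SAI curves for three surrogate sets (soil carbon alone; the retained
#' abiotic variables; abiotic variables plus soil carbon) — writing every
#' result to `out_dir` together with a run manifest.
#'
#' The configuration is a list or a YAML file with top-level fields:
#' * `synthetic`: arguments for [landscape_config()] (either this or
#'   `inputs` is required);
#' * `inputs`: paths `occurrence`, `covariates`, `threatened`;
#' * `seed`: master seed (default 1), split into per-stage substreams by
#'   stable hashing of stage names;
#' * `vif_threshold` (default 3), `n_runs` (default 20),
#'   `train_fraction` (default 0.7);
#' * `sai`: arguments for [sai_config()] (e.g. `q_values`, `n_models`,
#'   `n_random`);
#' * `out_dir`: output directory.
#'
#' @param config Path to a YAML file or a configuration list.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`): configuration snapshot, per-stage seeds, package
#'   version, input digests, output paths with MD5 digests and per-stage
#'   wall-clock seconds.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config),
            class = "saiplan_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a YAML path.",
          class = "saiplan_config_error")
  }
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    abort("Config needs either a `synthetic` block or an `inputs` block.",
          class = "saiplan_config_error")
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    abort("No output directory: set `out_dir`.",
          class = "saiplan_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  stage_seed <- function(stage) substream_seed(seed, paste0("stage_", stage))
  timings <- list()
  outputs <- character()
  timed <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  write_json_out <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs[[name]] <<- path
  }

  # --- data stage -----------------------------------------------------
  input_digests <- character()
  land <- timed("data", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      if (is.null(syn$seed)) syn$seed <- stage_seed("data")
      cfg <- do.call(landscape_config, syn)
      l <- simulate_landscape(cfg)
      paths <- write_landscape(l, out_dir)
      outputs[names(paths)] <- paths
      l
    } else {
      ins <- config$inputs
      for (f in c("occurrence", "covariates", "threatened")) {
        if (is.null(ins[[f]]) || !file.exists(ins[[f]])) {
          abort(sprintf("Missing input file for '%s'.", f),
                class = "saiplan_config_error")
        }
      }
      input_digests <- tools::md5sum(unlist(ins[c("occurrence",
                                                  "covariates",
                                                  "threatened")]))
      occ <- read_occurrence(ins$occurrence, threatened = ins$threatened)
      cov <- read_covariates(ins$covariates,
                             soil_carbon = config$soil_carbon %||%
                               "soil_carbon")
      list(occurrence = occ, covariates = cov,
           threatened = threatened_species(occ))
    }
  })
  occurrence <- land$occurrence
  covariates <- align_covariates(occurrence, land$covariates)
  threatened <- land$threatened
  if (length(threatened) == 0L) {
    abort("No threatened species flagged; nothing to prioritize.",
          class = "saiplan_data_error")
  }

  # --- collinearity stage ---------------------------------------------
  vif_report <- timed("vif", {
    enc <- encode_covariates(covariates)
    red <- reduce_collinearity(enc, threshold = config$vif_threshold %||% 3)
    write_json_out(list(
      retained = red$retained,
      dropped = red$dropped,
      final_vifs = red$final_vifs,
      threshold = red$threshold
    ), "vif_report.json")
    list(reduction = red, encoded = enc)
  })
  retained <- vif_report$reduction$retained
  enc <- vif_report$encoded

  # --- importance stage -----------------------------------------------
  tm <- occurrence_cells(occurrence)[, threatened, drop = FALSE]
  threat_count <- rowSums(tm)
  ensemble <- timed("importance", {
    ens <- fit_presence_ensemble(
      enc[retained], presence = threat_count >= 1,
      n_runs = config$n_runs %||% 20,
      train_fraction = config$train_fraction %||% 0.7,
      seed = stage_seed("importance")
    )
    write_json_out(list(
      summary = summarize_importance(ens),
      accuracy = glance(ens),
      settings = list(n_runs = ens$n_runs,
                      train_fraction = ens$train_fraction,
                      ntree = ens$ntree, mtry = ens$mtry)
    ), "importance.json")
    ens
  })

  group_test <- timed("group_test", {
    gt <- soil_carbon_group_test(
      data.frame(soil_carbon = covariates$soil_carbon,
                 threatened_count = threat_count)
    )
    write_json_out(list(
      groups = gt$groups, anova_F = gt$anova_F, anova_p = gt$anova_p,
      pairwise = gt$pairwise
    ), "group_test.json")
    gt
  })

  # --- optimal selection stage ----------------------------------------
  selection <- timed("optimal", {
    sel <- greedy_richness_selection(occurrence, target = threatened)
    scores <- importance_scores(sel)
    readr::write_csv(scores, file.path(out_dir, "importance_scores.csv"))
    outputs[["importance_scores.csv"]] <-
      file.path(out_dir, "importance_scores.csv")
    write_json_out(list(steps = sel$steps, glance = glance(sel)),
                   "selection.json")
    sel
  })

  # --- surrogacy stage ------------------------------------------------
  comparison <- timed("sai", {
    sai_args <- config$sai %||% list()
    sai_args$seed <- sai_args$seed %||% stage_seed("sai")
    cfg <- do.call(sai_config, sai_args)
    abiotic <- setdiff(retained, "soil_carbon")
    sets <- list(
      soil_carbon = "soil_carbon",
      abiotic = abiotic,
      abiotic_plus_soil_carbon = union(abiotic, "soil_carbon")
    )
    cmp <- compare_surrogates(occurrence, enc, sets, cfg,
                              target = threatened)
    write_json_out(list(
      curves = purrr::map(cmp$curves, tidy),
      differences = cmp$differences,
      variant = cfg$variant,
      site_budget = attr(cmp$curves[[1]], "site_budget"),
      reliability_threshold = 0.2
    ), "sai_curves.json")
    cmp
  })

  manifest <- list(
    package_version = as.character(packageVersion("saiplan")),
    config = config,
    seed = seed,
    stage_seeds = lapply(
      setNames(nm = c("data", "importance", "sai")), stage_seed),
    input_digests = as.list(input_digests),
    outputs = as.list(outputs),
    output_digests = as.list(tools::md5sum(unlist(outputs))),
    timings_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(
    landscape = land, vif = vif_report$reduction, ensemble = ensemble,
    group_test = group_test, selection = selection, sai = comparison
  )))
}
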