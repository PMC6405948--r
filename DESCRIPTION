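Package: saiplan
Title: Surrogate-Based Conservation Prioritization with the Species
    Accumulation Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating abiotic surrogates (in particular soil
    organic carbon) in complementarity-based conservation planning.
    Simulates plot-by-species presence/absence landscapes with a tunable
    soil-carbon coupling to threatened-species occurrence, screens
    environmental covariates by iterative variance-inflation-factor
    reduction, fits random-forest ensembles for threatened-species
    presence with Gini variable importance, derives optimal conservation
    scenarios with the Rebelo-Siegfried greedy richness algorithm, and
    scores surrogate efficiency with the Species Accumulation Index
    (SAI) across calibration fractions, with paired comparisons between
    surrogate variable sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang (>= 1.0),
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
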