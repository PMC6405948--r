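# saiplan

Surrogate-based conservation prioritization with the Species
Accumulation Index.

## What it is for

Conservation planners in data-poor regions rarely have the wall-to-wall
species observations that systematic reserve selection assumes. A
*biodiversity surrogate* — an abiotic variable such as soil organic
carbon, mappable everywhere — can stand in for species data if its
spatial pattern predicts where threatened species occur. `saiplan` is a
toolkit for testing exactly that, built around a permanent-plot survey
design (plots × species presence/absence plus plot-level environmental
covariates):

* **Synthetic landscapes** (`simulate_landscape()`) emulating a
  145-plot, 470-species network with 37 threatened species and a
  tunable soil-carbon → threatened-occurrence coupling, so the whole
  pipeline is testable without field data.
* **Collinearity screening** (`reduce_collinearity()`) by iterative
  variance inflation factors, retaining variables with VIF < 3.
* **Threatened-presence modelling** (`fit_presence_ensemble()`): 20
  random forests on random 70% training splits, mean-decrease-in-Gini
  importance standardized per run, OOB training and held-out test
  accuracy; plus a one-way ANOVA / Tukey HSD comparison of soil carbon
  across threatened-count groups (`soil_carbon_group_test()`).
* **Optimal conservation scenario**
  (`greedy_richness_selection()`): the Rebelo–Siegfried
  complementarity greedy — each step takes the plot adding the most
  unrepresented target species — with plot importance scores in [0, 1]
  (`importance_scores()`).
* **Surrogacy evaluation** (`evaluate_surrogate()`,
  `compare_surrogates()`): for each calibration fraction q, forests
  predict plot importance from surrogate covariates calibrated on a
  random q% subset, the top sites are selected, and efficiency is
  scored with the Species Accumulation Index

  SAI = (S − R) / (O − R),

  where S is the species representation of the surrogate-selected
  sites, O the optimum achievable in the same number of sites and R the
  mean over random site sets. SAI = 1 matches the optimum, 0 is no
  better than random, values above 0.2 are conventionally considered
  reliable. (The alternative printed form (S − R)/(O − S) is available
  as `variant = "as_printed"`.)

Results are tibbles with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures; `run_pipeline()` drives everything
from one YAML configuration and writes a reproducibility manifest.

## Worked example

```r
library(saiplan)
library(dplyr)

land <- simulate_landscape(default_config())
#> <saiplan_landscape> 145 plots x 470 species (37 threatened), 10 covariates

enc <- encode_covariates(land$covariates)
red <- reduce_collinearity(enc, threshold = 3)
#> <vif_reduction> threshold 3: retained 9, dropped 1
#> dropped: soil_age_alt
```

The screen drops one of the deliberately collinear covariate pair and
keeps nine variables. Fit the threat ensemble and rank predictors:

```r
tc  <- rowSums(as.matrix(land$occurrence[-1])[, land$threatened])
ens <- fit_presence_ensemble(enc[red$retained], tc >= 1, n_runs = 20, seed = 1)
glance(ens)
#>   train_accuracy_mean train_accuracy_sd test_accuracy_mean test_accuracy_sd
#> 1               0.864            0.0153              0.860           0.0346
head(summarize_importance(ens), 3)
#>   variable             median   q25   q75  rank
#> 1 soil_carbon           1     1     1         1
#> 2 temp_coldest_quarter  0.178 0.163 0.195     2
#> 3 temp_wettest_quarter  0.176 0.158 0.192     3
```

Presence of a threatened species is predicted with ~86% accuracy, and
soil carbon is the top-ranked variable in every run (median
standardized importance 1), more than five times the runner-up. The
optimal scenario and a soil-carbon-only surrogate:

```r
sel <- greedy_richness_selection(land$occurrence)
glance(sel)
#>   n_selected n_target n_represented n_unrepresentable
#> 1         10       37            37                 0

cfg <- sai_config(q_values = c(10, 20, 40), n_models = 30, n_random = 500,
                  surrogate_variables = "soil_carbon", seed = 7)
evaluate_surrogate(land$occurrence, enc, cfg)
#> <sai_curve> surrogate: soil_carbon (site budget 10)
#>       q S_mean     O R_mean sai_mean ci_low ci_high
#> 1    10   28.6    37   8.26    0.708  0.275   0.836
#> 2    20   29.7    37   8.26    0.745  0.176   0.870
#> 3    40   31.1    37   8.26    0.796  0.566   0.870
```

Ten complementary plots cover all 37 threatened species. Selecting ten
plots by soil-carbon-calibrated forest predictions represents ~29–31 of
them versus 8.3 for random selection — SAI ≈ 0.7–0.8, far above the 0.2
reliability line. `autoplot()` on a curve or on a
`compare_surrogates()` result draws the SAI-versus-q figure with 95%
intervals and the reference line.

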