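---
title: "Evaluating soil carbon as a conservation-planning surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating soil carbon as a conservation-planning surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Systematic conservation planning needs georeferenced species data that
most regions do not have. A practical workaround is a *biodiversity
surrogate*: an abiotic variable, cheap to map everywhere, whose spatial
pattern predicts where the species of concern are. Soil organic carbon
(SOC) is a candidate with a plausible mechanism — carbon-rich lowland
soils attract agriculture, so the flora specialized on them tends to be
both concentrated and threatened.

`saiplan` implements the full evaluation chain for such a surrogate on a
network of vegetation survey plots: plot-level threatened-species
modelling, complementarity-based site prioritization, and a formal
surrogacy score, the Species Accumulation Index (SAI). Because the kind
of permanent-plot dataset this emulates (145 plots, 470 vascular plant
species, 37 of them threatened, in Southern Patagonia) is not publicly
deposited, the package ships a first-class synthetic generator so every
stage is testable end to end.

## The synthetic landscape

`simulate_landscape()` draws, for `n_plots` plots:

* **Soil carbon** — log-normal (`meanlog = log(60)`, `sdlog = 0.5`, in
  Mg C ha⁻¹ to 30 cm, arbitrary calibration). Stocks are nonnegative and
  right-skewed in field data; the log-normal is the simplest shape with
  both properties.
* **Abiotic covariates** — `n_covariates` standard-normal scores with
  field-flavoured names (soil age, landform index, NDVI, quarter
  temperatures, ...). `collinear_pairs` of them receive a near-duplicate
  (correlation ≈ 0.98) so collinearity screening has something to do.
* **Occurrence** — each threatened species occupies a plot with
  probability `plogis(qlogis(baseline) + soc_effect * z)`, where `z` is
  soil carbon standardized *on the log scale*. Standardizing the raw
  log-normal would hand its heavy right tail to the logit and saturate
  the top plots; the log transform keeps per-plot threatened counts in
  the observed zero-to-a-few range. Non-threatened species are Bernoulli
  on their baselines, independent of all covariates by default
  (`nontarget_coupling = 0`), so any surrogacy signal traces to the
  threatened set.

Default baselines are `threatened_prevalence_range = c(0.002, 0.008)`
and `baseline_prevalence_range = c(0.02, 0.30)` (non-threatened). The
threatened range was calibrated once, jointly with the default
`soc_effect = 2`, so that the emulated qualitative pattern holds: a
strong positive carbon–threat coupling, roughly 80–85% of plots holding
zero or one threatened species, a handful of carbon-rich plots with
several, and every threatened species still present somewhere. Two
ranges are used (rather than one shared range) because a slope of 2 on
the logit scale demands much lower baselines for the threatened set
than would be realistic for common species.

Species whose first draw lands in zero plots are redrawn (up to 100
times, with a message); a species still absent is dropped with a
warning, since an all-zero column carries no information for selection.
Redrawing conditions those rare species on being observed at least
once — exactly the ascertainment a real survey imposes.

Randomness is organised as named substreams hashed from one master seed
(`substream_seed()`), so covariate draws, occurrence draws, subset
draws and forest fits never share a stream: adding a covariate cannot
perturb the occurrence matrix, and paired surrogate comparisons can
share subset draws exactly.

What the generator does **not** emulate: spatial coordinates and
autocorrelation, taxonomy above the species level, observation error in
the surveys, and any real covariance structure among the abiotic
variables beyond the constructed collinear pairs. Tests passing on
these landscapes show the machinery is correct and well calibrated, not
that soil carbon is a good surrogate in any particular real region.

## Collinearity screening

`reduce_collinearity()` performs the standard stepwise
variance-inflation-factor loop: `VIF_j = 1/(1 - R²_j)` from an OLS
regression of covariate `j` on all others; while the maximum VIF is at
or above the threshold (default 3, the conventional strict cut), the
single worst variable is removed, with argmax ties broken
alphabetically for determinism. Exact linear dependences are reported
as an `Inf` sentinel rather than an error; constant columns are an
error naming the column. Categorical covariates enter as
reference-coded indicators (`encode_covariates()`); generalized VIF for
multi-level factors is deliberately out of scope.

## Threatened-species importance

`fit_presence_ensemble()` fits 20 random-forest classifiers of
plot-level presence (at least one threatened species) on the retained
covariates, each on a fresh uniform 70/30 split. Hyperparameters are
pinned — 500 trees, `floor(sqrt(p))` candidate variables per split,
unlimited depth — because "defaults" drift between implementations.
Importance is the mean decrease in the Gini index, standardized within
each run by the maximum so every run's top variable scores exactly 1.

Training accuracy is recorded as the *out-of-bag* accuracy on the
training partition: resubstitution accuracy of a random forest is
trivially near 1 and carries no information, while OOB accuracy is the
established honest estimate and is directly comparable to the held-out
test accuracy. Both mean ± SD and mean ± SE across runs are reported,
since conventions differ.

`soil_carbon_group_test()` is the companion univariate check: one-way
ANOVA of soil carbon across threatened-count groups with Tukey HSD for
all pairs. Count groups with fewer than two plots cannot contribute a
variance estimate and are merged into the better-populated adjacent
count category, with a warning.

## The optimal conservation scenario

`greedy_richness_selection()` is the classic complementarity greedy:
repeatedly take the plot adding the most not-yet-represented target
species, stopping at full representation of every representable species
(a `site_budget` override exists for truncated scenarios). Ties go to
the earlier plot in input order, for cross-platform determinism.
Species occurring nowhere are reported as unrepresentable, not an
error. `importance_scores()` maps the selection to plot scores in
[0, 1]: marginal gain divided by the maximum gain, so the first pick
scores 1 and unselected plots 0. Only the endpoints of that scale are
externally pinned; gain-ratio normalization is our choice of a monotone
interpolation and is recorded in output metadata.

## The Species Accumulation Index

For a site budget `k` (default: the size of the full-data greedy
selection), SAI compares `S`, the expected species representation of
surrogate-selected sites, with the optimum `O` and the random baseline
`R` (mean representation of 1000 uniform `k`-subsets). Two definitional
forms of the index circulate; the printed form `(S − R)/(O − S)` is
inconsistent with the index's stated range of (−∞, 1], so the package
defaults to the range-consistent `(S − R)/(O − R)` — equal to 1 exactly
when the surrogate matches the optimum, 0 when it matches random — and
offers the other as `variant = "as_printed"` (with an `Inf` sentinel at
`S = O`). When `O = R` surrogacy is unmeasurable and `NaN` is returned
with a warning. Values of 0.2 and above are conventionally read as a
reliable surrogate, and plots annotate that reference line.

`evaluate_surrogate()` mimics planning with species data for only q% of
plots: draw the subset, run the greedy selection *within* it, score its
plots, fit a regression forest (500 trees, `p/3` candidates per split)
of those scores on the subset's surrogate covariates, predict scores
for the whole network, take the top `k` plots, and count the threatened
species represented. The per-q curve reports the mean and 95%
percentile interval across `n_models` repetitions (default 100).

One methodological subtlety deserves emphasis: predictions for the
calibration plots themselves use the forest's *out-of-bag* values, not
in-sample predictions. An in-sample prediction memorizes the
calibration plot's own score, so even a covariate of pure noise would
"rediscover" the subset's best plots and score as a usable surrogate —
a leakage, not surrogacy. With OOB predictions a surrogate is credited
only for what its covariates generalize. The residual operating
characteristics are still imperfect in an identifiable way: because a
scored calibration plot's own spike is excluded from its OOB
prediction, the handful of species-rich plots that dominate the
landscape are slightly *under*-ranked by weak surrogates when they fall
in the calibration subset, which biases a pure-noise surrogate's SAI
somewhat below zero at large q; and at very small q a sparse surrogate
covariate (nonzero on only the ~10 optimal plots) is often constant
within the calibration subset, making the prediction constant and the
selection effectively arbitrary. The acceptance suite measures both
effects rather than hiding them.

`compare_surrogates()` evaluates several covariate sets on *identical*
subset draws and fit seeds (shared substreams), so per-q differences
are paired: duplicated sets are bitwise identical and the three-way
comparison (soil carbon alone; abiotic; abiotic + soil carbon) is
variance-reduced.

## Pipeline and reproducibility

`run_pipeline()` sequences everything from one YAML/list configuration
(synthetic block or CSV inputs), writes every result as CSV/JSON, and
emits a manifest with the configuration snapshot, per-stage substream
seeds, package version, and MD5 digests of inputs and outputs. Reruns
of an unchanged configuration reproduce byte-identical result files;
only the manifest's wall-clock timings differ.

## Problem sizes used by the tests

Unit tests run on small landscapes (40–80 plots, 25–80 species) where
exhaustive oracles are feasible: greedy selection is checked against
brute-force enumeration on 200 instances of up to 12 plots, the random
baseline against the exact mean over all C(10,3) subsets, and VIF
against closed-form values on columns with exactly prescribed sample
correlations. The end-to-end checks run at the emulated network's full
scale (145 × 470, 37 threatened) with 100 surrogate models per q and
1000 random baseline draws; the acceptance script uses 50 models per q.
These sizes were chosen as the smallest that make the Monte-Carlo
assertions stable.

## Known limitations

* No spatial structure: real reserve design would add connectivity and
  cost, which are out of scope here.
* The SAI evaluation's low-q behaviour is dominated by whether the
  calibration subset contains any high-score plot; with strongly
  concentrated landscapes (few plots holding most threatened
  incidences) the index is a blunt instrument below q ≈ 20%.
* VIF screening treats indicator columns as ordinary covariates;
  factors with many levels would deserve generalized VIF.
* The threatened/non-threatened dichotomy is an input; no attempt is
  made to model threat status itself.
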