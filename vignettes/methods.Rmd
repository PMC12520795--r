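---
title: "Methods: presence-only ensemble SDM with effort-bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only ensemble SDM with effort-bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasdm)
```

# The modelling problem

`invasdm` implements presence-background species distribution modelling for
a species observed in two regions with very different data quality: a
data-rich "invasive" region whose records are mostly GPS-precision
community-science observations, and a data-poor "native" region dominated
by retrospectively georeferenced specimens with positional uncertainty up
to many kilometers. The pipeline treats its output as an approximation of
the realized environmental niche: a map of the conditions the species
occupies in its accessible range, not a causal or mechanistic model.

Three statistical problems shape the design:

* **Sampling bias.** Community-science records concentrate where people
  are. The pipeline absorbs this with an *effort covariate* — the
  log-count of all community-science observations per cell — fitted
  alongside the environmental predictors, then frozen at a constant at
  projection time so maps reflect environment, not observers.
* **Positional uncertainty.** A record with a 10 km uncertainty radius
  says little about its 1 km² cell. The pipeline filters by per-region
  CU thresholds and, where retained uncertainty still spans multiple
  cells, excludes the whole uncertainty disc from pseudo-absence
  sampling so that "absences" are never drawn where the species may in
  fact have been present.
* **Background stochasticity and algorithm variance.** Pseudo-absence
  draws and train/validation splits are replicated (by default 10 sets ×
  10 splits) and predictions combined across replicates and algorithms in
  mean, committee-average, and skill-weighted ensembles.

# Pipeline stages and their parameters

## Occurrence preparation

Records pass three ordered stages: (1) validity/terrestrial screen (finite
coordinates, inside the grid, at least one non-NA predictor in the cell);
(2) per-region CU filter — retain iff CU ≤ threshold, with region defaults
1 km (invasive) and 15 km (native); (3) thinning to one presence per grid
cell, keeping the first record in input order (deterministic even when
dates are missing). Records with *missing* CU are excluded by default
(`keep_missing_cu = FALSE`): the thresholds are defined on CU and silent
retention would leak imprecise records; the count of exclusions is logged.

Cell assignment is half-open floor binning,
`col = floor((x - origin)/cell) + 1`, so boundary points belong to exactly
one cell.

## Effort layer

Cells score `0` (unsampled), `0.33` (one observation), `ln(n)` (n ≥ 2).
The 0.33 value keeps single-observation cells distinct from unsampled ones
(`ln 1 = 0` would conflate them) while remaining below `ln 2 ≈ 0.69`, so
the scale stays monotone in effort. The layer is never centered or scaled;
its mean non-zero value is recorded at build time because projection
reuses it (see *Projection*).

## Collinearity pruning and standardization

Pairwise Pearson correlations are computed over cells where all layers are
non-NA. While any kept pair exceeds `|r| = 0.7`, the layer with the
largest mean absolute correlation against all other kept layers is dropped
(ties alphabetical). We read "mean absolute correlation" against *all*
kept layers rather than only violating partners: the latter ties the two
members of a violating pair by construction and cannot reproduce the
intended behavior on a chain `a—b—c` where only `b` should fall.

Remaining layers are centered and scaled over their non-NA cells, pooled
across the two regions (a single model spans both, so a common scale is
required). The constants are frozen on the modelling extent and reused for
any projection stack, preventing leakage between fit and projection
domains.

## Pseudo-absences

1:1 with presences per region, ten sets by default, set *k* seeded with
`base_seed + k`. Draws are uniform without replacement within a set;
across sets, cells may recur (sets are independent replicates). Two
exclusion modes:

* **Cell exclusion** (precise records): presence cells are ineligible,
  their neighbors eligible.
* **Buffer exclusion** (imprecise records): a cell is ineligible iff its
  rectangle intersects any disc of radius CU centered on a record.
  Disc–rectangle intersection is computed exactly by nearest-point
  distance (clamp the disc center into the rectangle), not by polygon
  discretization; the unit tests verify it cell-for-cell against an
  exhaustive oracle on small grids.

## Fitting and splits

Each pseudo-absence set is joined with the fixed presences into a balanced
frame; ten (default) stratified 70/30 splits follow, stratified by
region × class so both regions keep their 1:1 balance in both partitions
(±1 row). "Ten cross-validation folds" are implemented as ten repeated
stratified splits rather than disjoint 10-fold partitions: the design
couples a 70/30 partition size with ten repetitions per set, and repeated
splits satisfy both simultaneously.

The algorithm registry holds RF (500 trees, √p features per split), GBM
(gradient-boosting configuration on the xgboost engine: 1000 stages,
depth 3, learning rate 0.01), CTA (rpart, cost-complexity pruned at the
internal-CV minimum), ANN (one hidden layer of 8 units, weight decay
0.01), XGBoost (its own defaults), and a MAXENT-style penalized logistic
regression (glmnet lasso with internal CV; fidelity to the original
maximum-entropy software is a non-goal). Every fit takes an explicit seed
derived from (algorithm, PA set, repetition). Class weights are omitted
deliberately: prevalence is held at 0.5 by the 1:1 design. FDA and MARS
are specified as optional plugins behind the same `register_algorithm()`
contract and are not shipped, since no suitable engine is available among
the package's dependencies.

## Evaluation

* **TSS**: maximized over candidate thresholds = midpoints of consecutive
  sorted unique scores plus {0, 1}; classification is positive iff
  score ≥ threshold; ties break toward the larger threshold. The search is
  computed by a single sorted sweep and is verified against a brute-force
  threshold scan in the tests.
* **Continuous Boyce index**: 101 overlapping windows of width 0.1 of the
  combined score range; each window's P/E is the presence fraction over
  the background fraction; windows with zero background mass are skipped;
  the index is the Spearman correlation of P/E with the window midpoint
  (duplicate P/E values retained, tied ranks averaged). If the retained
  P/E sequence is constant the index is defined as 0 (no association).
  Window width and count are configurable; the defaults follow the
  established continuous formulation.
* Metrics are always computed per region; pooled values are reported
  additionally, never instead.
* **Selection**: the ensemble with the highest unweighted mean of the four
  numbers {TSS, Boyce} × {region A, region B}; because the mean is
  unweighted, averaging regions before or after averaging the two metrics
  is equivalent. Candidates with an undefined region metric (e.g. a
  degenerate committee-vote distribution in the small-sample region) are
  excluded from selection and logged.

## Importance and regional contrasts

Permutation importance of a predictor is the mean over nine shuffles of
`1 − cor(reference predictions, shuffled-predictor predictions)` (Pearson,
matching the convention of the ensemble-SDM tooling this workflow follows).
A shuffle that produces constant predictions contributes correlation 1;
constant reference predictions yield importance 0 with a flag. Importances
are computed region-wise on the validation partition of the *first*
pseudo-absence set (validation rows only), then scaled to sum to one
within each run × region group.

Scaled importances are modelled with a beta-regression mixed model:
logit mean `~ region * predictor` plus a run-level random intercept, log
dispersion `~ region * predictor` (importance variance differs strongly
between region–predictor combinations), Laplace approximation via glmmTMB.
Boundary values are legal scaled importances but sit outside the open
beta support, so all outcomes are squeezed by `y' = (y(n−1) + 0.5)/n`
before fitting; the distortion vanishes with n. With fewer than five runs
the random-intercept variance is not identifiable and the model drops to
fixed effects only. Contrasts are differences of estimated marginal means
between regions on the logit scale with delta-method standard errors; the
sign convention is *native − invasive*, so negative estimates mark
predictors more influential in the invasive region.

## Projection, independent validation, overlap

Standardized-effort projection replaces every terrestrial effort value
with the mean non-zero effort of the *training* layer before predicting.
The constant is computed and stored at effort-build time, not hard-coded:
it is a property of the data, and any fixed literal would silently go
stale on a new effort surface. Independent survey data are aggregated to
one point per cell with precedence to presences, then scored against the
standardized-effort map (the generalizability question is about the
bias-corrected map). Focal-species occurrences are thinned to one per
cell; overlap is the mean ± SE of map suitability at those cells, with
occurrences in NA cells dropped and counted.

# The synthetic landscape

`synth_landscape()` generates the study system all tests run on: two
regions separated by a non-terrestrial strip; spatially autocorrelated
predictors as Gaussian-kernel-smoothed white noise (cheap, seed-stable,
and sufficient to induce realistic spatial structure without full
variogram simulation); controlled collinearity by mixing noise fields
before smoothing (`L2 = ρL1 + √(1−ρ²)ε` preserves ρ under the shared
linear smoother); a logistic suitability truth over standardized layers;
an observation-effort intensity field mildly coupled to suitability; and
occurrence sampling proportional to suitability × effort with
region-specific CU distributions (log-normal, median 31 m, truncated at
1 km in the invasive region; a 50/50 mixture of Uniform(4 m, 1 km) and
Uniform(1 km, 15 km) in the native region, mirroring a record pool where
only about half the records are GPS-precision).

Default sizes were chosen once to reproduce the intended study
conditions: a 100 × 180 km grid, 11 predictors including one pair at
|r| = 0.9, 60 000 effort points (≈ 80% of cells sampled; mean non-zero
effort ≈ 1.1–1.2), and raw occurrence draws of 1100/75, which thin to
roughly 950 and 75 presence cells — the two-orders-of-magnitude regional
imbalance the pipeline must tolerate.

What the generator does *not* emulate: temporal dynamics of sampling,
non-stationary predictor–suitability relationships, biotic interactions,
dispersal limitation, and detection probability varying with habitat.
Passing tests therefore demonstrate the *mechanics* of the pipeline
(filtering, exclusion geometry, metric arithmetic, calibration of the
inference layer) under a known truth, not that any real species' map is
correct. Proportionality of detections to suitability × effort is an
assumption of this module, chosen as the simplest detection model with
both required biases.

# Numerical choices and degenerate inputs

* All stochastic steps take explicit seeds; one pipeline seed fans out to
  per-stage seeds through a fixed integer hash so stages can be re-run in
  isolation from their logged seed.
* Thresholding uses `score ≥ threshold` everywhere, consistent with the
  midpoint candidate set and reproducible tie behavior.
* Cohen's kappa is defined as 0 when chance agreement is 1.
* All-zero importance groups scale to zeros with a flag rather than NaN.
* EMwmean floors negative-TSS weights to zero (a no-skill model should not
  subtract signal); an all-zero weight vector is an error.
* The Boyce index returns 0 for a flat P/E sequence and errors when fewer
  than two windows contain background mass.
* Ensemble prediction is lazy over member predictions with output
  identical to eager computation (tested).

# Problem sizes

The test suite and the acceptance script run everything at desk scale:
landscapes between 60 × 100 and 120 × 200 cells, 2–11 predictors, up to
10 pseudo-absence sets × 3 repetitions and ~950 presences for the full
synthetic study, 20-replicate simulations for metric-calibration checks.
These sizes were chosen as the smallest at which the statistical claims
(correlation contracts, metric calibration, GLMM coverage, importance
recovery) are measurable with reasonable Monte Carlo error.

# Known limitations

* The beta-GLMM's z-based inference is asymptotic; with very few runs the
  random intercept is dropped and p-values should be read cautiously.
* The continuous Boyce index has high sampling variance by construction
  (~10 effectively independent windows at the default width), so
  single-draw values carry uncertainty of roughly ±0.3 under weak signal;
  comparisons should average over replicates, as the pipeline does.
* The MAXENT entry is a penalized logistic approximation, not the original
  maximum-entropy software.
* Real-data raster acquisition, reprojection and alignment are out of
  scope: stacks are assumed aligned on a single planar grid.
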