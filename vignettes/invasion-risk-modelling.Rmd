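---
title: "Modelling forest-pest invasion risk on a hexagon grid"
author: "hexinvade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest-pest invasion risk on a hexagon grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexinvade)
```

## The modelling problem

The emerald ash borer (*Agrilus planipennis*, EAB) spreads through a
landscape by two routes: short-distance adult flight, which produces new
infestations within a few kilometres of brood trees, and long-distance
human-assisted movement of infested material, which produces satellite
infestations hundreds of kilometres from any known source. Detection
surveys code the landscape as a binary response on a hexagonal
tessellation: each surveyed hexagon-year is a presence (adults or
immatures found) or an absence (surveyed, nothing found). Hexagon-years
that were never surveyed are *not* absences and never enter the response.

`hexinvade` implements the full analysis pipeline around that response:

1. **Grid** — an equal-area flat-top hexagon tessellation with geodetic
   centroid distances (spherical haversine, mean Earth radius
   6,371,008.8 m).
2. **Infestation pressure** — a lagged "force of invasion" predictor: for
   hexagon $i$ in year $t$,
   $$\mathrm{Spatial}_i(t) \;=\; \sum_{k=1}^{N} \exp\!\big(-d_{ik}^{\,a}\big),$$
   where the sum runs over every hexagon $k$ infested in year $t-1$ or
   $t-2$ within 300 km, $d_{ik}$ is the centroid distance standardised by
   the 300-km cutoff (so $d \in [0,1]$), and $a$ reshapes the kernel: small
   $a$ concentrates colonisation risk near sources, large $a$ flattens it
   towards the cutoff. A hexagon infested in both lag years contributes one
   term per lag year, and a hexagon's own lagged infestation contributes
   $\exp(0)=1$ per lag year. Infestations in year $t$ itself never
   contribute.
3. **Logistic model selection** — single-predictor and driver-group
   logistic regressions (fitted with `stats::glm`, logit link), kernel
   shape selected by AIC among $a \in \{1, 3, 5, 10\}$, collinearity
   screening by pairwise Pearson correlation ($|r| \ge 0.75$ resolved by
   single-predictor AIC) and iterated VIF ($\ge 5$), backward elimination
   by single-term deletions with a protected term set, and an
   AIC/$\Delta$AIC/Akaike-weight comparison table.
4. **Multi-model comparison** — six families (GLM, MARS, ANN, CTA, GBM,
   RF) over 10 balanced pseudo-absence sets $\times$ 3 cross-validation
   runs (70/30 calibration/validation inside an 80/20 train/evaluation
   split), scored by the True Skill Statistic
   $\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$
   at the TSS-maximising threshold found on calibration data; a
   committee-averaging ensemble of members with validation TSS $> 0.6$;
   permutation variable importance ($1 - $ Pearson correlation between
   predictions before and after shuffling one predictor, averaged over six
   shuffles); marginal response curves; and a one-way ANOVA of TSS by
   family with pairwise Welch $t$ tests (Holm-adjusted).
5. **Projection** — committee predictions for an uninvaded region with the
   spatial term set to zero (the no-information baseline when no source
   lies within the kernel cutoff).

Because real EAB survey data are not redistributable, the package ships a
stratified-dispersal invasion simulator with known parameters; every
downstream stage is exercised and validated against it.

## Interpreting the kernel and its parameters

* `a` (dimensionless, default candidates 1, 3, 5, 10): the kernel shape
  parameter. With the power form `exp(-d_std^a)`, larger `a` gives
  *relatively* more weight to distant infestations (the kernel is flatter
  inside the cutoff). Published renderings of this kernel family are
  ambiguous between `exp(-d^a)` and `exp(-d/a)`; both match the
  qualitative role of `a`, so the power form is the default and the
  scale form is available via `pressure_config(form = "scale")`. All
  downstream code treats `a` as opaque.
* `cutoff_m` (default 300,000 m): both the neighbourhood radius and the
  denominator of the distance standardisation. The source text states a
  0–1 standardised distance without naming the denominator; the cutoff is
  the only stated length scale, so it is used.
* `lags` (default {1, 2}): source years, reflecting the beetle's one- or
  two-year life cycle.

## The synthetic invasion generator

`landscape_config()` / `simulate_study()` emulate the *statistical
structure* of a regional detection-survey dataset:

* **Landscape.** A 40 × 40 flat-top hexagon lattice of 2,500-km² cells
  (about 2,100 × 1,900 km). The real study system spans six to seven
  kernel cutoffs; at that ratio only a small fraction of the landscape is
  within reach of any one infestation and spread is wave-limited. (A 40-km
  or 400-km landscape against a fixed 300-km cutoff is either
  kernel-degenerate — all standardised distances near zero — or globally
  unstable, with every cell in reach of every source.) Cell area is a
  scenario parameter, not a claim about survey resolution.
* **Predictors.** Fifteen surfaces matching the occurrence study's
  predictor set (elevation, slope, aspect, road/rail lengths, stations,
  campgrounds, parks, population density, crown closure, treed %,
  broad-leaf %, dichotomous landcover, degree-days > 10 °C, coldest-quarter
  mean temperature). Each is a seeded white-noise field smoothed by a
  moving average over cells within `autocorr_range_km` (60 km default) and
  mapped to a Gaussian marginal centred in its physical support with
  sd = range/6 — landscapes concentrate around typical values rather than
  spreading uniformly over physical extremes. Landcover is derived by
  thresholding the population-density field at its 85th percentile so
  urban cells cluster. Counts (stations, campgrounds) are quantile-coupled
  Poisson draws.
* **Spread.** Epicentre cells (12, in 3 widely separated clusters — real
  invasions have multiple foci) are infested through the two burn-in
  years. From year 3 on, each uninfested cell is colonised with probability
  $\mathrm{logit}^{-1}\!\big(\beta_0 + \beta_s\,\mathrm{Spatial} +
  \textstyle\sum_j \beta_j (x_j - \bar x_j)\big)$, with the kernel computed
  at the generating shape `true_a`; Poisson(`jump_rate` = 0.3) long-range
  jumps land on uniformly random cells; infested cells never recover. The
  generating coefficients carry the sign structure of the fitted
  multivariable occurrence model (negative elevation and campgrounds
  effects; positive slope, population density, crown closure, urban
  landcover and degree-day effects), with the per-unit magnitudes of that
  model where they are usable and $\beta_s = 0.35$, $\beta_0 = -9.1$
  chosen so that a twelve-cell core grows to a few hundred cells over the
  15-year horizon without global takeoff.
* **Observation.** Infested cells are surveyed every year and detected
  with probability 0.9; a seeded 15% of uninfested cells is surveyed and
  recorded as absences (including false absences for infested-but-missed
  cells). These rates give roughly 3,500 surveyed hexagon-years at about
  7% presences (± 2 points across seeds), matching the strong class
  imbalance of the real data.

What the generator does **not** emulate: mechanistic phenology,
overwintering mortality, eradication or management, anisotropic or
road-network dispersal, and spatially uneven survey effort beyond the
infested-cell/background split. Passing tests therefore demonstrate that
the pipeline recovers what it should from data *of this structure*, not
that the fitted numbers transfer to any particular real landscape.

## Why kernel-shape validation is a conditional experiment

`recover_kernel_shape()` validates the AIC selection of `a` with a
conditional Monte-Carlo design: scattered source cells on a compact
landscape (~1.5 cutoffs, so standardised distances span the full 0–1
range), a colonisation response drawn from the kernel logistic itself,
and selection run exactly as in the pipeline. Piloting showed that
recovery from a full simulated invasion time series is not a well-posed
experiment, for four reasons worth recording:

1. *Persistence*: re-detections of established infestations carry their
   own lagged infestation at distance zero, which rewards the steepest
   kernel regardless of the generating shape.
2. *Trend aliasing*: once sources saturate the 300-km neighbourhood, the
   flat high-`a` kernels are nearly constant in space but track the
   growing source count — a year-trend surrogate.
3. *Link saturation*: at strong effects the logistic link lets a decaying
   kernel mimic a flat one by pushing near-source cells onto the
   probability plateau.
4. *Column collinearity*: sums over many clustered sources concentrate,
   making the candidate kernel columns nearly affine transforms of each
   other ($r > 0.97$).

The conditional design removes all four: the fitted class contains the
generating model, the effect is scaled to 4 logits at the 95th percentile
of in-reach pressure (strong enough to separate functional forms, weak
enough to avoid saturation), six scattered sources keep the columns
distinguishable, and a single response year removes trends. Its operating
point (n ≈ 2,100 cells, 25% event rate) was set by pilot power analysis;
at that point the generating shape is recovered in roughly 9 of 10
replicates for both `a = 1` and `a = 10`.

Relatedly, `select_kernel_shape()` defaults to the *at-risk* response
(`risk_set = "colonization"`): rows of cells with a previously recorded
presence are dropped, so presences are first detections. The pressure term
always uses the full occurrence table as sources.

## Numerical choices and degenerate inputs

* Logistic fits converge on a relative log-likelihood change
  below 1e-8 (up to 100 IRLS iterations). Complete separation is detected
  (boundary fitted probabilities with exploding standard errors), warned
  about, and flagged `converged = FALSE`. Singular designs error with the
  aliased column names.
* Kernel-shape ties (ΔAIC < 1e-6) break to the smallest `a`; a constant
  pressure column falls back to the intercept-only fit so all candidates
  tie.
* TSS threshold candidates are midpoints of sorted unique predictions plus
  {0, 1}; ties break to the smallest threshold. Classification uses
  `prob >= threshold`.
* Committee ties (even member counts) resolve to absence — conservative
  for a risk map — and the vote fraction is always reported so users can
  re-threshold.
* Permutation importance is clamped to [0, 1]; a model with constant
  predictions has importance 0 for every predictor by definition.
* Point-in-hexagon ties on shared edges resolve to the lower hexagon id.
  Haversine rounding overshoot is clamped so the central angle stays in
  $[0, \pi]$.
* Every random draw derives from one master seed through a pre-generated
  sub-seed table (`sample.int(2^31 - 2, n)` under the master seed), so
  adding draws never perturbs earlier ones and reruns are byte-identical.

## Model-family adapters

The six families are thin wrappers with fixed, logged hyperparameters:
GLM (`stats::glm`), RF (`randomForest`, 500 trees), CTA (`rpart`, grown at
cp = 0.001 and cost-complexity pruned at the minimum cross-validated
error), ANN (`nnet`, one hidden layer of 8 units, decay 0.01), GBM
(`xgboost`, 1,000 trees, learning rate 0.01, depth 3), and MARS — a
least-squares forward hinge-basis selection with backward GCV pruning
implemented in-package (mirrored hinge pairs at observed quantile knots;
GCV penalty of 3 effective parameters per knot; predictions clamped to
[0, 1]). Failed fits are caught and recorded as `status = "failed"`
without aborting the batch.

## Problem sizes used by the test-suite and acceptance runs

The shipped tests exercise the default scenario (40 × 40 cells, 15 years,
~3,500 surveyed hexagon-years, 180-model factorial), the kernel-recovery
experiment at 20 replicates per shape, oracle comparisons on grids up to
~270 cells, and 100-replicate coverage simulations at n = 2,000. These
sizes were chosen so a full validation run completes in a few minutes on a
single core while keeping every Monte-Carlo check adequately powered.

## Known limitations

* The pressure computation is exact but dense per year; for national-scale
  grids (10^6 cells) a true spatial index would be needed.
* Kernel-shape selection on observed survey data (as opposed to the
  conditional validation) inherits the identification caveats above; on
  the default simulated scenario it often prefers a flatter kernel than
  the generating one, and the same caution applies to real data.
* The committee ensemble votes binary labels only; probability-averaging
  ensembles are deliberately out of scope.
* Profile-likelihood intervals, mixed-effects and autologistic model
  variants are not implemented; Wald intervals are used throughout.
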