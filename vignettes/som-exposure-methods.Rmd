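---
title: "Self-organizing maps for exposure-driven outcome classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing maps for exposure-driven outcome classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somexposure)
```

## The procedure

The package classifies binary health outcomes (coded 1 = case) from mixed
exposure/demographic inputs with a Kohonen self-organizing map. The
analysis chain is: impute missing station measurements, interpolate
pollutants to patient coordinates at a lag of two days before
presentation, z-score continuous inputs and one-hot code nominal ones,
train the map, then cluster the trained codebook vectors to draw
boundaries and summarize quality.

A map is a `K x J` lattice (rectangular or hexagonal) of nodes, each with
a codebook vector of the input dimension, initialized uniformly at random
within each feature's observed range. Training is **online**: patterns are
presented one at a time in a seeded shuffled order, the node nearest the
pattern in Euclidean distance wins, and every node moves toward the
pattern by `h = eta(t) * exp(-d_grid^2 / (2 sigma(t)^2))`, where `d_grid`
is the lattice distance to the winner. Both the learning rate
`eta(t) = eta0 exp(-t/tau2)` and the radius `sigma(t) = sigma0 exp(-t/tau1)`
decay exponentially in the presentation counter `t`. The per-pattern
update (rather than a batch rule) mirrors the classical formulation of the
update equation; the Gaussian neighborhood is the canonical choice where
the formulation leaves the kernel unspecified.

The **supervised** variant appends a second codebook layer holding
per-node class proportions. During training the winner minimizes
`x_weight * d_X^2 + (1 - x_weight) * d_Y^2` with the outcome one-hot
coded, and both layers learn with the same neighborhood value; since the
Y-layer rows start on the probability simplex and every update is a convex
combination with a one-hot target, they remain on the simplex. Prediction
finds the winner on the X layer only — labels are not available at
prediction time — and returns the winning node's majority class, ties to
class 0. With `x_weight = 1` the X layer trains exactly as an unsupervised
map (a tested identity).

## Quality metrics and their conventions

The quantization error is printed in the literature both as a sum over
patterns and per object. The sum `sum_p ||z_p - w_bmu||^2` is retained,
but the headline value is the **mean squared distance per pattern**,
because per-node quality thresholds ("mean distance of objects mapped to a
unit") only make sense on a per-object scale. The topographic error is the
standard definition: the fraction of patterns whose best and second-best
nodes are not lattice-adjacent (4-neighborhood on rectangular, 6 on
hexagonal grids). Node quality counts occupied nodes whose mean Euclidean
(not squared) object distance is at or below a threshold, default 0.05.
That default is conventional; note that its meaning depends entirely on
the feature scaling — on 13 z-scored columns typical mean distances are
well above 0.05, so the threshold should be adjusted to the feature space
at hand (it is a parameter everywhere it appears).

Ward clustering of the codebooks uses the merge cost
`d_rs = n_r n_s / (n_r + n_s) * ||w_r - w_s||^2` — the squared-norm
reading, which is the standard Ward criterion (the unsquared variant is
available by flag). Merging is agglomerative with pooled-mean centroid
updates and ties broken toward the lowest pair of node indices; the merge
heights reproduce `stats::hclust(method = "ward.D2")` heights (squared,
halved) exactly, which the tests assert on 16-codebook problems. Nodes are
numbered from the bottom-left corner, left to right then bottom to top, in
every report and serialization.

## Tunable parameters

- `eta0` (initial learning rate, default 0.05, dimensionless in (0,1]);
  `tau2` (decay, default `n_epochs * n / 4` presentations): the usual
  trade-off between plasticity and convergence.
- `sigma0` (initial radius, default `max(K, J)/2` grid units) and `tau1`
  (default chosen so the radius decays to ~1 grid unit by the end of
  training): start global, end local.
- `n_epochs` (default 100) and `stop_tol` (default 1e-5): training stops
  early when the relative improvement of the epoch-end quantization error
  falls below `stop_tol`. Online training makes the epoch QE mildly noisy,
  so the stop often triggers within a handful of epochs once the map has
  stabilized; pass `stop_tol = -Inf` to force the full epoch budget (the
  convergence-limit tests do).
- `x_weight` (default 0.5): balance of feature vs outcome distance in the
  supervised winner search.
- IDW `power` (default 2) with an exactness tolerance of 1 m at stations;
  distances use an equirectangular planar approximation, adequate at
  metropolitan scale.
- Exposure `lag` (default 2 days): a single lagged day, not a window; a
  window would be a straightforward extension but only the single-day
  variant is implemented.

## The synthetic study generator

No patient-level data ship with the package, so `simulate_study()`
generates cohorts with the structure the analysis assumes: pollutant
surfaces are a per-pollutant baseline plus isotropic Gaussian source
plumes (the simplest field with smooth spatial gradients, so that
interpolation is meaningful), modulated by a lognormal AR(1) daily factor
and unit-mean lognormal observation noise, truncated at zero. Missingness
is MCAR or MAR; the MAR mechanism makes higher-ranked values more likely
missing — one concrete, testable choice. Ages are gamma(2, 18) years,
clipped to 4 months–86 years, giving the right skew and roughly
three-quarters adults-plus-elderly; age categories are 1 [0,1], 2 (1,9],
3 (9,19], 4 (19,65], 5 (65, inf) — the printed labels of such studies
leave (1,2) years unlabelled, and category 2 is the only gap-free
completion. Gender draws include a ~1.5% missing-gender fraction; race
uses four categories (0 = African or Black reference). Outcomes are
Bernoulli with logit linear in the standardized lagged exposures, centered
age category, and gender/race indicators. The default coefficients make
SO2 the strongest pollutant effect, PM10 second, NO2 third, and age
positive; the default intercept applies the logit-normal correction
`qlogis(0.19) * sqrt(1 + 0.346 var(eta))` so the marginal prevalence stays
near 19% with the slopes active (with all slopes zero, prevalence is
exactly `plogis(intercept)` in expectation).

The generator emulates the *statistical shape* of a two-city exposure
study, not its physics: no atmospheric dispersion, no street-level
geocoding error, no seasonality or day-of-week structure, no spatial
clustering of residences around sources. Passing tests therefore show the
pipeline recovers structure it is pointed at, not that any particular
real-world dataset would be classified equally well.

## Numerical and design choices

- **Imputation**: chained equations with ordinary least squares and
  Gaussian residual draws, 10 sweeps, one completed dataset (m = 1) — the
  analysis trains one map on completely imputed data, and no pooling rule
  across multiple imputations is defined for it. Observed cells are never
  altered; collinear predictors are dropped (aliased coefficients zeroed);
  imputed concentrations are truncated at zero.
- **Degenerate inputs** raise errors rather than guesses: all-missing
  series, zero-variance columns at scaling, unseen nominal levels,
  single-class supervised training, single-node topographic error, empty
  pattern sets.
- **Tie-breaks** are deterministic everywhere: lowest linear node index
  for winner search and Ward merges, class 0 for prediction ties.
- **Age** enters the model as one ordinal z-scored column rather than
  one-hot, so code plots show a single age segment; gender/race are
  one-hot (integer coding would be a config-level change).
- **Early stopping vs. monotonicity**: the stop rule can end on an epoch
  whose QE ticked slightly up (that is what triggers it), so the
  monotone-trend property (final epoch QE at or below the first epoch's)
  is asserted on full, non-early-stopped runs.
- **Serialization** is JSON (codebooks row-major in node order, resolved
  config, history); infinities round-trip as strings.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration — 483 patients, 8
stations, 365 days, an 8 × 8 supervised map trained for 100 epochs — which
completes in seconds, plus a 2,000-patient two-cluster recovery (6-sd
separation; held-out accuracy is required to reach 0.95) and twenty
2,000-patient no-signal null studies (held-out accuracy must stay at
chance, 0.45–0.55). The full-pipeline "separable" check uses strongly
localized pollution (plume amplitude 4, sd 0.1 degrees, 9 stations), a
near-deterministic outcome (`beta_SO2 = 50` with the intercept at −25,
placing the class boundary in the low-density gap between the exposure
modes) and low noise; this is the configuration under which the exposure
signal is genuinely separable end to end. Across arbitrary plume
geometries (other seeds) the same configuration lands between 0.92 and
0.97 — the residual errors are patients living exactly on a plume edge.

## Known limitations

- Online training is order-dependent; all reproducibility is via seeds,
  and results will differ across R versions only if the RNG changes.
- The linear-topology lattice is recognized in configuration but not
  implemented; batch SOM, growing maps and kriging/land-use-regression
  exposure models are out of scope.
- The per-node 0.05 quality threshold is scale-bound, as discussed above.
- IDW ignores elevation, wind and source directionality; it is a
  weighted average, so it can never extrapolate beyond the range of
  station values.
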