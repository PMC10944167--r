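---
title: "Methods: land-potential assessment from FAPAR time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-potential assessment from FAPAR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical conventions and design
choices behind `fapargap`, in the spirit of a methods appendix: what is
computed, under which assumptions, and where the genuinely open decisions
were made.

## 1. The assessment model

`fapargap` estimates *potential* vegetation productivity — the FAPAR a
pixel would exhibit in the hypothetical absence of short-term human
pressure — by counterfactual prediction. A single regression model

\[ \mathrm{FAPAR}(x, t, p) \approx f(\text{terrain}, \text{climate},
   \text{vegetation indicators}, \text{human pressure}, p) \]

is fitted on space-time samples spanning all months and three percentile
levels \(p \in \{0.05, 0.50, 0.95\}\) (the percentile enters as an ordinary
numeric feature, so one model serves the whole distribution). Potential
FAPAR is then the model's prediction with the four human-pressure layers
zeroed, the cropland indicator zeroed, and observed vegetation indicators
replaced by potential-biome indicators. Everything else is untouched,
which assumes vegetation–climate interactions are negligible at the grid
scale; this is a stated simplification, not a claim.

The approach is purely correlative. It can only remove pressure effects
that are expressed through the pressure covariates; legacy effects of past
land use, or pressure invisible to those layers, remain in the "potential".

## 2. Temporal aggregation

Monthly values are per-pixel percentiles of the 8-day composites dated
inside the month **plus one composite immediately before and after it**
(five to six values for interior months; edge months use only the side
that exists). The extra composites buffer missing dates. Numerical
conventions, fixed so tests can be exact:

* percentile definition: linear interpolation between order statistics
  (`stats::quantile(type = 7)`);
* the "before/after" composites are the nearest strictly outside the
  month;
* a pixel with no valid value in the window stays missing;
* a 365-day working calendar (the leap day folds into day 365).

Ground-station FIPAR readings combine upward and downward hemispherical
photography as \( \mathrm{FIPAR} = u + (1-u)\,d \); records with stated
measurement error above 0.1 or a quality flag above 1 are dropped (both
comparisons strict), survivors are averaged per station-month, and each
station-month is compared against the single containing pixel (no
neighbourhood averaging, assuming locally homogeneous cover). Which
percentile to compare stations against is not prescribed anywhere; the
median is the default (`match_stations(prob = 0.5)`), as the least
noise-sensitive level, with the level exposed as an argument.

## 3. Covariates

The geometric temperatures encode earth geometry as covariates:

\[ t_{\min} = 24.2\cos\phi - 15.7\,(1-\cos\theta)\sin|\phi| - 0.6\,z/100,
\qquad
   t_{\max} = 37\cos\phi - 15.4\,(1-\cos\theta)\sin|\phi| - 0.6\,z/100, \]

with phase \( \theta = (d - 18)\,2\pi/365 + 2^{1-\mathrm{sgn}\phi}\pi \)
(day 18 = coldest northern / warmest southern day; 0.6 °C per 100 m
lapse). `sgn(0) = 0` puts a \(2\pi\) offset at the equator — immaterial
because the seasonal term carries \(\sin|\phi| = 0\) there, but fixed for
determinism. Monthly covariate layers are evaluated at the mid-month day.

Vegetation indicators (forest / shrubland / grassland / cropland, values 0
or 100) come from a fixed crosswalk of level-4 land-cover codes; level-4
subclasses not printed in the crosswalk (e.g. evergreen/deciduous
shrubland 121/122) inherit their parent class's group. Mosaic classes
follow the crosswalk as printed, with no fractional splitting. The
potential-biome map uses its own crosswalk onto the three natural groups.

The covariate registry is a configurable container (`assemble_covariates`)
rather than a hard-coded 68-layer catalogue: the framework, not a specific
global layer list, is the artifact. Exactly four layers must carry the
human-pressure flag, because the counterfactual ablates that specific set.
Resampling uses natural cubic splines or bilinear interpolation for
continuous layers and nearest-neighbour (enforced) for categorical ones.

## 4. Sampling design

Strata combine three per-pixel categories — nightlight change (within ±1,
above +1, below −1 nW·cm⁻²·sr⁻¹), land-cover change (none/other,
forest‑wetland → grassland‑cropland, or the reverse) and pressure presence
(all four layers zero at both epochs, or not). Eleven listed combinations
map to codes 1–17 (odd), anything else collapses to code 18, water/ice is
code 0 and never sampled.

Allocation gives every stratum a minimum \(n_{\min}\) and distributes the
remainder proportionally to \(N_h S_h\) (the Neyman-optimal share), with
nearest-integer rounding and a largest-remainder correction that forces
the exact total. The descriptive phrase "proportionally to the standard
deviation" is ambiguous; only the \(N_h S_h\) share reproduces the
reference twelve-stratum allocations exactly, so that is what
`neyman_allocation()` implements (verified digit-for-digit in the test
suite). Design weights are \(W_h = N_h/n_h\), kept at full precision and
rounded only for display; all accuracy metrics use them. `stratum_table()`
additionally enforces feasibility on small synthetic populations (minima
capped at the stratum size, over-allocations redistributed) — the bare
allocation rule itself is left exactly in its reference form.

The regression matrix has one row per (location, month, percentile); rows
with missing targets are dropped; subsampling preserves per-stratum
proportions to within one row via largest-remainder apportionment. In the
synthetic default every location contributes all simulated months
(6 years × 12).

## 5. The stacked ensemble

Three base learners, with the selected hyperparameter set as package
defaults (`default_hyperparameters()`):

* **extremely randomized trees** (`ranger`, `splitrule = "extratrees"`):
  44 trees, depth 92, feature fraction 0.84, min split 16, min leaf 2;
* **gradient-boosted trees** (`xgboost`): 81 rounds, depth 50, learning
  rate 0.06, gamma 0.05, L1 0.007, L2 0.12, column subsampling
  0.88/0.66/0.47. The reported search ranges list both an `eta` of 1.999
  and a learning rate of 0.06, which alias the same parameter in xgboost;
  the implementation applies the learning-rate value (a shrinkage of ~2 is
  outside the sane range) and records the redundant entries unused;
* **feed-forward network**: 4 hidden layers × 128 ReLU units, dropout
  0.15, sigmoid output, Adam, 10 epochs, batch 256, learning rate 5·10⁻⁴.
  Implemented as a compact seeded matrix-algebra regressor with inputs
  standardized internally; deterministic for a fixed seed.

A linear meta-learner stacks the three. Whether stacking should use
out-of-fold base predictions is an open design point; `fapar_eml()`
defaults to out-of-fold stacking (spatially blocked inner folds) to avoid
leakage — in-sample tree predictions are near-interpolating and would give
the meta-learner a distorted view — with `stacking = "refit"` available
for comparison. Three inner folds are used by default: the meta-learner
has only four coefficients, so its estimate is insensitive to the fold
count, and this keeps the number of base fits proportionate. Ensemble
output is clipped to \([0,1]\) *after* the meta-learner (domain
constraint), and the per-pixel **model deviance** is the population
standard deviation of the three base predictions.

Evaluation uses design-weighted metrics: \(R^2\) with the weighted mean of
the observations in the denominator, Lin's concordance computed from
weighted (population-style) moments — no weighted CCC formula is
prescribed anywhere, so Lin's definition with weighted moments is used and
tested against an integer-replication oracle — plus weighted RMSE, MAE and
bias. Cross-validation is *strict spatial*: folds partition locations, all
rows of a location share its fold, and the pooled out-of-fold predictions
give the headline report.

Feature selection (`rfe_select`) runs recursive elimination with a
60-tree random-forest scorer inside spatially blocked CV to pick the
optimal feature count, then a final elimination ranking on all rows; how
to combine the two selection outputs is unspecified, so the implementation
truncates the final ranking at the CV-optimal count and labels this an
interpretation. Hyperparameter search (`tune_hyperparameters`) is
randomized successive halving over the declared bounds with a row-budget
cap of 20,000 per candidate evaluation; disabled by default in favour of
the selected set.

## 6. Gap and trend

The monthly gap is `actual − potential` at p0.95 (the level chosen for
potential prediction to damp residual noise); the **annual gap is the
arithmetic mean of the twelve monthly gaps** — the defining description names
the year but not the operator, and the mean is the natural unweighted
choice. Trend analysis also runs on the p0.95 monthly series (configurable here).

Per pixel, the series is gap-filled by linear interpolation, decomposed
with STL (period 12, `s.window = "periodic"`, robust fitting off — STL has
no universal defaults, so these are fixed and recorded), and the trend
component is regressed on time in years centered at the series midpoint.
Reported per pixel: intercept, slope (FAPAR/yr), slope standard error,
two-sided p and \(R^2\). **Caveat, deliberately preserved:** the t-test is
applied to a loess-smoothed, hence strongly autocorrelated, component; its
type-I error at the nominal p < 0.005 is inflated by construction. The
package replicates this procedure for fidelity rather than correcting it,
documents it, and the test suite only brackets the rejection rate rather
than asserting the nominal level. Class summaries therefore report both
thresholded and unthresholded area fractions of increasing/decreasing
trends.

## 7. The synthetic world

`generate_world()` builds the validation ground truth:

```r
actual(x, t) = clip01( potential(x, month(t))
                       - delta * pressure01(x)
                       + slope(x) * t + eps ),   eps ~ N(0, noise_sd)
```

with `potential(x, m)` a logistic (squashed) function of the synthetic
climate layers minus a latitude-scaled seasonal dip, exported in
machine-readable form by `generative_rule()` so oracles never re-derive it
from prose. Suppression acts on the *normalized* footprint
(`pressure01 = footprint / max(footprint)`) while the model sees the raw
layers, separating effect-size truth from covariate scaling. Clipping is
applied after all perturbations.

Defaults — chosen once as the package's study conditions: 64×64 pixels
over 32–48° N, 6 years of 8-day composites (day-of-year anchors 1, 9, …,
361; 46 per year), suppression `delta = 0.2` on an urban block,
an injected trend of `+0.01` FAPAR/yr in a designated block, seasonal
amplitude 0.15 at 45°, observation noise SD 0.05, 5 % missing composites,
400 sample locations with a per-stratum minimum of 25, and a 50,000-row
regression matrix. The global minimum of 200 per stratum is infeasible in
a 400-point desk design with four strata; the machinery is identical, the
constants smaller. The geography guarantees that the suppressed block's
potential stays above the suppression in every month, so clipping never
truncates the injected effect.

The generator emulates: latitude-driven seasonality, a smooth potential
surface, pressure-proportional suppression, linear trends, Gaussian noise,
missingness, flagged station records. It does **not** emulate: spatially
correlated noise, cloud-regime missingness patterns, mixed pixels,
sensor-change artifacts, or vegetation–climate feedback. Passing recovery
tests therefore demonstrates that the machinery is correct and unbiased
under known conditions — not that real-world accuracy will match.

A Monte-Carlo oracle (`signal_fraction()`) computes the best achievable
design-weighted \(R^2\) of a regression matrix directly from the
generative rule (40 noise redraws per row), giving the reference against
which the cross-validated ensemble \(R^2\) is compared (tolerance ±0.05).
The remaining recovery checks on the default world assert: counterfactual
gap over suppressed pixels within ±0.05 of −0.2, regional-mean recovered
slope within ±20 % of +0.01 FAPAR/yr, and the all-suppressed urban class
ranking first by fraction of negative gap.

## 8. Orchestration and I/O

The pipeline is driven from R (`pipeline_config()`,
`run_pipeline_stage()`, `run_fapar_pipeline()`); each stage writes its
outputs plus a JSON manifest (parameters, derived seed, output checksums),
and reruns with identical inputs yield identical manifests. All
persistence is plain text: rasters as TSV grids with a JSON sidecar
(nodata −9999), tables as CSV, regression matrices as CSV or Parquet with
a feature-order sidecar. A single base seed derives every stage seed by a
fixed offset.

## 9. Known limitations

* The counterfactual inherits every limitation of correlative models:
  collinearity between pressure and climate can shift part of the
  suppression signal onto non-ablated covariates, biasing the gap toward
  zero. The recovery tolerance (±0.05 on a 0.2 effect) brackets this at
  desk scale.
* The trend p-values are anticonservative (section 6) — by design.
* Percentile aggregation of noisy composites is biased at extreme levels
  (a p0.95 of six noisy values sits above the true p0.95); the bias
  cancels in the gap because actual and potential are compared at the
  same level, but absolute monthly values at p0.05/p0.95 carry it.
* The desk-scale problem sizes (64×64 world, 50,000 rows, three stacking
  folds) were fixed as the package's default study conditions; larger
  worlds only change runtime, not code paths.
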