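# fapargap

Land-potential assessment from FAPAR time series: counterfactual "potential
FAPAR" mapping, actual-versus-potential gap analysis, and long-term trend
detection.

## The problem

The Fraction of Absorbed Photosynthetically Active Radiation (FAPAR, unitless
in 0–1) is a direct biophysical proxy for vegetation productivity. Land
managers assessing degradation need a *reference state* to compare observed
productivity against. `fapargap` implements a data-driven version of the
potential-natural-vegetation idea: fit a machine-learning model of FAPAR on
biophysical **and** human-pressure covariates, then predict under a
counterfactual in which human pressure is removed. The difference

```
gap = FAPAR_actual − FAPAR_potential
```

(negative = observed productivity below its estimated potential) together
with per-pixel long-term trends gives a two-sided view of potential
degradation.

The full pipeline is:

1. **Temporal aggregation** — 8-day FAPAR composites are reduced to monthly
   per-pixel percentiles p0.05 / p0.50 / p0.95; each month's window also
   takes one composite before and after the month (5–6 composites).
2. **Covariates** — terrain, climate, geometric min/max temperature
   (closed-form pseudo-temperatures from latitude, day-of-year and
   elevation), vegetation-cover indicators crosswalked from land-cover
   codes, and four human-pressure layers (human footprint, population,
   cropland intensity, nightlights).
3. **Sampling design** — non-overlapping strata from nightlight change,
   land-cover change and pressure presence; sample sizes by Neyman
   allocation `n_h = n_min + round(N_h·S_h / Σ N_i·S_i · (n − n_min·H))`
   with design weights `W_h = N_h / n_h`; space-time regression matrix over
   all months and percentile levels.
4. **Stacked ensemble** — extremely randomized trees, gradient-boosted
   trees and a small feed-forward network (4×128 ReLU, dropout 0.15,
   sigmoid output), combined by a linear meta-learner trained on
   out-of-fold base predictions; evaluated with design-weighted R², Lin's
   CCC, RMSE, MAE and bias under *strict spatial cross-validation* (folds
   split by location, never by row).
5. **Counterfactual prediction** — pressure layers and the cropland
   indicator are zeroed, observed vegetation indicators are replaced by
   potential-biome indicators, and the model predicts the p0.95 potential
   FAPAR plus a per-pixel "model deviance" (SD of the three base learners).
6. **Gap & trend** — monthly and annual-mean gap maps; per-pixel STL
   season-trend decomposition followed by an OLS fit of the trend component
   (slope in FAPAR/yr, p from the slope t-test, significance at p < 0.005);
   summaries by aggregated land-cover (change) class.

Because real global inputs are terabyte-scale, the package ships a
**synthetic world generator** (`generate_world()`) whose potential surface,
suppression, trends and noise are known exactly, so every stage can be
validated end-to-end against ground truth.

## Worked example

```r
library(fapargap)

hp <- default_hyperparameters()
hp$ann$epochs <- 4; hp$et$n_trees <- 10          # desk-scale demo settings
hp$xgb$n_estimators <- 15; hp$meta$stack_folds <- 2

cfg <- pipeline_config(
  world = list(grid_rows = 16, grid_cols = 16, n_years = 3),
  n_total = 60, n_min = 10, n_rows = 4000, cv_folds = 2,
  hyperparameters = hp, seed = 7)
state <- run_fapar_pipeline(cfg, out_dir = tempfile())

state$cv$pooled
#> R2 = 0.7648  CCC = 0.8919  RMSE = 0.0695  MAE = 0.0547  bias = +0.0116  (n = 3000)

mean(state$gap$annual[state$world$regions$human])   # injected suppression: 0.2
#> [1] -0.1833988
mean(state$trend$beta[state$world$regions$trend])   # injected slope: 0.01 / yr
#> [1] 0.01185936

head(state$summary[, c("class", "n_pixels", "frac_gap_negative")], 3)
#>         class n_pixels frac_gap_negative
#> 1       URBAN       16         1.0000000
#> 2       WATER        2         1.0000000
#> 3 TREBE-CRPRF        8         0.5000000
```

Even at this toy scale (16×16 pixels, 3 years, weak learners) the
counterfactual gap over the suppressed urban block recovers most of the
injected 0.2 suppression, the injected 0.01 FAPAR/yr trend is recovered
within 20 %, and the urban class tops the negative-gap ranking. At the
package's default study scale (64×64, 6 years, 400 locations, 50,000 matrix
rows) recovery is substantially tighter; see the methods vignette.

The reference global sampling design is reproduced exactly:

```r
inv <- global_stratum_inventory()
neyman_allocation(inv$N_h, inv$S_h, n_total = 12500, n_min = 200)
#> [1] 7738  204  247  203  243  327  201  201  267  200  200 2469
```

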