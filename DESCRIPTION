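Package: fapargap
Title: Land-Potential Assessment from FAPAR Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing vegetation land potential from time series of
    the Fraction of Absorbed Photosynthetically Active Radiation (FAPAR).
    Implements monthly percentile aggregation of 8-day composites, geometric
    temperature and land-cover indicator covariates, Neyman-allocated
    stratified space-time sampling with design weights, a stacked ensemble
    regressor (extremely randomized trees, gradient-boosted trees and a small
    feed-forward network combined by a linear meta-learner) evaluated under
    strict spatial cross-validation, counterfactual prediction of potential
    FAPAR by zeroing human-pressure covariates, actual-versus-potential gap
    maps, per-pixel season-trend (STL) decomposition with ordinary
    least-squares trend fits, and land-cover-class summaries. A synthetic-world
    generator with exactly known potential, suppression and trends provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    xgboost
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
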