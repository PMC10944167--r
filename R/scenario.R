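#' Build the counterfactual (potential-vegetation) covariate scenario
#'
#' Produces the hypothetical no-human-impact covariate set used to predict
#' potential FAPAR: the four human-pressure layers are set to zero, the
#' cropland indicator is set to zero, and the observed forest / shrubland /
#' grassland indicators are replaced by the potential-biome indicators
#' ([biome_indicators()]). All other layers are untouched, assuming
#' negligible vegetation-climate interaction at the grid level. The
#' operation is idempotent.
#'
#' @param covariates A [assemble_covariates()] `covariate_set` whose four
#'   pressure-flagged layers are present.
#' @param biome Character matrix of potential-biome class names, aligned
#'   with the covariate grid.
#' @param veg_layers Names of the observed vegetation-indicator layers to
#'   replace, in the order forest, shrubland, grassland.
#' @param cropland_layer Name of the cropland indicator layer.
#' @return The modified `covariate_set`, with attribute `"scenario"` listing
#'   the modified layer names.
#' @export
build_potential_scenario <- function(covariates, biome,
                                     veg_layers = c("forest", "shrubland",
                                                    "grassland"),
                                     cropland_layer = "cropland") {
  reg <- covariate_registry(covariates)
  pressure <- reg$name[reg$pressure]
  if (length(pressure) != 4)
    stop("covariate set must carry exactly four pressure-flagged layers",
         call. = FALSE)
  if (!all(dim(biome) == c(covariates$grid$nrow, covariates$grid$ncol)))
    stop("biome map is not aligned with the covariate grid", call. = FALSE)
  missing <- setdiff(c(veg_layers, cropland_layer), reg$name)
  if (length(missing) > 0)
    stop("covariate set lacks indicator layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  out <- covariates
  for (nm in c(pressure, cropland_layer))
    out$layers[[nm]]$data[] <- 0
  bio <- biome_indicators(biome)
  for (i in seq_along(veg_layers)) {
    nm <- veg_layers[i]
    d <- out$layers[[nm]]$data
    if (length(dim(d)) == 3) {
      for (j in seq_len(dim(d)[3])) d[, , j] <- bio[[i]]
    } else d[] <- bio[[i]]
    out$layers[[nm]]$data <- d
  }
  attr(out, "scenario") <- list(zeroed = c(pressure, cropland_layer),
                                replaced = veg_layers)
  out
}

# per-pixel feature matrix for one (year, month, prob), in registry order
pixel_features <- function(covariates, year, month, prob) {
  reg <- covariate_registry(covariates)
  n <- covariates$grid$nrow * covariates$grid$ncol
  f <- vapply(reg$name, function(nm)
    as.vector(covset_layer_value(covariates, nm, year, month)), numeric(n))
  cbind(f, prob = rep(prob, n))
}

#' Predict potential FAPAR over the grid
#'
#' Applies a fitted ensemble to the counterfactual covariate scenario for
#' every requested month, at the 95th percentile by default (the level used
#' for potential-FAPAR mapping to damp residual noise), returning the
#' potential prediction and the per-pixel model deviance.
#'
#' @param model A [fapar_eml()] fit.
#' @param scenario A `covariate_set`, normally from
#'   [build_potential_scenario()].
#' @param year Year index within the covariate span.
#' @param months Months to predict (default all 12).
#' @param prob Probability-level feature value (default 0.95).
#' @return List with `potential` and `deviance` (rows x cols x months
#'   arrays), and the `year`, `months`, `prob` used.
#' @export
predict_potential <- function(model, scenario, year, months = 1:12,
                              prob = 0.95) {
  R <- scenario$grid$nrow; C <- scenario$grid$ncol
  pot <- array(NA_real_, c(R, C, length(months)))
  dev <- array(NA_real_, c(R, C, length(months)))
  for (i in seq_along(months)) {
    fm <- pixel_features(scenario, year, months[i], prob)
    pr <- predict(model, fm, deviance = TRUE)
    pot[, , i] <- matrix(pr$fit, R, C)
    dev[, , i] <- matrix(pr$deviance, R, C)
  }
  list(potential = pot, deviance = dev, year = year, months = months,
       prob = prob)
}

#' Extract one year of monthly rasters from a series
#'
#' @param series A [aggregate_monthly()] result.
#' @param year Year to extract.
#' @param prob Probability level.
#' @return A rows x cols x 12 array; errors listing any missing months.
#' @export
monthly_year_stack <- function(series, year, prob = 0.95) {
  i <- which(abs(series$probs - prob) < 1e-9)
  if (length(i) != 1) stop("prob level not present in series", call. = FALSE)
  k <- match(1:12, series$months$month[series$months$year == year])
  if (anyNA(k))
    stop("missing months for year ", year, ": ",
         paste(which(is.na(k)), collapse = ", "), call. = FALSE)
  rows <- which(series$months$year == year)[k]
  series$values[, , rows, i, drop = FALSE][, , , 1]
}

#' Actual-versus-potential FAPAR gap
#'
#' `gap = actual - potential` per pixel and month; negative values mean the
#' observed FAPAR falls below the estimated potential. The annual gap is the
#' arithmetic mean of the monthly gaps.
#'
#' @param actual,potential rows x cols x months arrays on the same grid
#'   (e.g. [monthly_year_stack()] and `predict_potential()$potential`).
#' @return List with `monthly` (array) and `annual` (matrix).
#' @export
compute_gap <- function(actual, potential) {
  if (!all(dim(actual) == dim(potential)))
    stop("actual and potential stacks are not aligned", call. = FALSE)
  monthly <- actual - potential
  annual <- apply(monthly, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  list(monthly = monthly, annual = annual)
}

#' Summarize gap and trend by land-cover class
#'
#' Per aggregated land-cover (change) class: pixel count, gap quantiles, the
#' fraction of pixels with a negative gap, and the fractions with a
#' significant positive / negative trend at the given p-value threshold.
#' Global area fractions of increasing and decreasing trends are attached as
#' attributes, both thresholded (`p < p_threshold`) and unthresholded (sign
#' of the slope only).
#'
#' @param gap_annual Matrix of annual gap values.
#' @param trend A [trend_raster()] result (uses `beta` and `p`).
#' @param classes Character matrix of class labels
#'   ([lc_change_classes()]).
#' @param p_threshold Significance threshold for trend fractions.
#' @return Data frame `class`, `n_pixels`, `gap_q05`, `gap_q50`, `gap_q95`,
#'   `frac_gap_negative`, `frac_trend_pos_sig`, `frac_trend_neg_sig`, sorted
#'   by `frac_gap_negative` (largest first); attributes `global_fractions`.
#' @export
summarize_by_class <- function(gap_annual, trend, classes,
                               p_threshold = 0.005) {
  if (!all(dim(gap_annual) == dim(classes)) ||
      !all(dim(trend$beta) == dim(classes)))
    stop("gap, trend and class rasters are not aligned", call. = FALSE)
  cls <- sort(unique(as.vector(classes)))
  cls <- cls[!is.na(cls)]
  rows <- lapply(cls, function(cl) {
    sel <- which(classes == cl)
    g <- gap_annual[sel]; b <- trend$beta[sel]; p <- trend$p[sel]
    gv <- g[!is.na(g)]
    tv <- !is.na(b) & !is.na(p)
    q <- if (length(gv) > 0) stats::quantile(gv, c(0.05, 0.5, 0.95),
                                             type = 7, names = FALSE)
         else rep(NA_real_, 3)
    data.frame(
      class = cl, n_pixels = length(sel),
      gap_q05 = q[1], gap_q50 = q[2], gap_q95 = q[3],
      frac_gap_negative = if (length(gv)) mean(gv < 0) else NA_real_,
      frac_trend_pos_sig = if (any(tv))
        mean(p[tv] < p_threshold & b[tv] > 0) else NA_real_,
      frac_trend_neg_sig = if (any(tv))
        mean(p[tv] < p_threshold & b[tv] < 0) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frac_gap_negative), ]
  rownames(out) <- NULL
  b <- trend$beta; p <- trend$p
  ok <- !is.na(b) & !is.na(p)
  attr(out, "global_fractions") <- c(
    pos_sig = mean(p[ok] < p_threshold & b[ok] > 0),
    neg_sig = mean(p[ok] < p_threshold & b[ok] < 0),
    pos_all = mean(b[ok] > 0),
    neg_all = mean(b[ok] < 0)
  )
  out
}
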