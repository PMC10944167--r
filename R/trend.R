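#' Season-trend decomposition of a monthly series
#'
#' Decomposes a monthly series into trend, seasonal and remainder components
#' with STL (seasonal-trend decomposition using loess), after linear
#' interpolation of internal missing values (edge gaps take the nearest
#' value). A periodic seasonal window is used so the seasonal cycle is
#' constant across years; the three components reconstruct the gap-filled
#' input exactly.
#'
#' @param x Numeric monthly series (length >= 2 periods).
#' @param period Observations per cycle (12 for monthly data).
#' @return List with `trend`, `seasonal`, `remainder`, `filled` (the
#'   gap-filled input) and `interpolated` (logical mask of filled values).
#' @export
stl_decompose <- function(x, period = 12) {
  n <- length(x)
  if (n < 2 * period)
    stop("series must cover at least two full periods", call. = FALSE)
  nas <- is.na(x)
  if (all(nas)) stop("series is entirely missing", call. = FALSE)
  filled <- x
  if (any(nas))
    filled <- stats::approx(which(!nas), x[!nas], xout = seq_len(n),
                            rule = 2)$y
  fit <- stats::stl(stats::ts(filled, frequency = period),
                    s.window = "periodic")
  comp <- fit$time.series
  list(trend = as.numeric(comp[, "trend"]),
       seasonal = as.numeric(comp[, "seasonal"]),
       remainder = as.numeric(comp[, "remainder"]),
       filled = filled, interpolated = nas)
}

#' Long-term trend of a monthly series
#'
#' Fits ordinary least squares to the STL trend component against time in
#' years (centered at the series midpoint). The slope is the long-term
#' change in FAPAR units per year; its p-value comes from the slope t-test.
#' Note that the t-test is applied to a loess-smoothed component, whose
#' autocorrelation makes the test anticonservative; this mirrors the
#' procedure being replicated and is deliberately left uncorrected.
#'
#' @param x Numeric monthly series.
#' @param t_years Numeric time axis in years since series start, same
#'   length as `x`.
#' @param period Observations per cycle.
#' @return List of class `trend_fit`: `alpha` (intercept at the series
#'   midpoint), `beta` (slope, FAPAR/year), `sd` (slope standard error),
#'   `p` (two-sided p-value), `r2`. All `NA` for an entirely missing
#'   series.
#' @export
trend_fit <- function(x, t_years, period = 12) {
  stopifnot(length(x) == length(t_years))
  if (length(x) < 24)
    stop("need at least 24 monthly values", call. = FALSE)
  na_fit <- structure(list(alpha = NA_real_, beta = NA_real_, sd = NA_real_,
                           p = NA_real_, r2 = NA_real_),
                      class = "trend_fit")
  if (all(is.na(x))) return(na_fit)
  dec <- stl_decompose(x, period = period)
  tc <- t_years - mean(t_years)
  fit <- stats::lm(dec$trend ~ tc)
  # a perfectly flat trend component triggers the "essentially perfect
  # fit" note; the zero slope it reports is the desired answer
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(alpha = unname(co[1, 1]), beta = unname(co[2, 1]),
                 sd = unname(co[2, 2]),
                 p = unname(co[2, 4]), r2 = sm$r.squared),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: beta = %+.5f /yr (sd %.5f, p = %.4g), alpha = %.4f, R2 = %.3f\n",
              x$beta, x$sd, x$p, x$alpha, x$r2))
  invisible(x)
}

#' Per-pixel trend rasters from a monthly series
#'
#' Applies [stl_decompose()] + [trend_fit()] to every pixel of a monthly
#' percentile series (the 95th percentile by default, the level used for
#' trend mapping) and returns the five coefficient rasters.
#'
#' @param series A [aggregate_monthly()] result covering the full span.
#' @param prob Probability level of the series to use.
#' @return List of matrices `alpha`, `beta`, `sd`, `p`, `r2` on the series
#'   grid.
#' @export
trend_raster <- function(series, prob = 0.95) {
  i <- which(abs(series$probs - prob) < 1e-9)
  if (length(i) != 1) stop("prob level not present in series", call. = FALSE)
  t_years <- series$months$t_years
  R <- dim(series$values)[1]; C <- dim(series$values)[2]
  out <- lapply(c("alpha", "beta", "sd", "p", "r2"),
                function(nm) matrix(NA_real_, R, C))
  names(out) <- c("alpha", "beta", "sd", "p", "r2")
  for (r in seq_len(R)) {
    for (c in seq_len(C)) {
      v <- series$values[r, c, , i]
      if (all(is.na(v))) next
      tf <- trend_fit(v, t_years)
      out$alpha[r, c] <- tf$alpha
      out$beta[r, c] <- tf$beta
      out$sd[r, c] <- tf$sd
      out$p[r, c] <- tf$p
      out$r2[r, c] <- tf$r2
    }
  }
  out
}
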