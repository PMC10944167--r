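#' Combine upward and downward FIPAR measurements
#'
#' Total intercepted fraction from a pair of upward/downward hemispherical
#' photography readings: `up + (1 - up) * down`. The upward reading
#' intercepts first; the downward reading only sees what the overstorey
#' transmitted.
#'
#' @param fipar_up,fipar_down Numeric vectors in `[0, 1]` (NA allowed).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' combine_fipar(0.6, 0.5)  # 0.8
#' @export
combine_fipar <- function(fipar_up, fipar_down) {
  ok <- is.na(fipar_up) | (fipar_up >= 0 & fipar_up <= 1)
  ok2 <- is.na(fipar_down) | (fipar_down >= 0 & fipar_down <= 1)
  if (!all(ok, ok2))
    stop("fipar_up and fipar_down must lie in [0, 1]", call. = FALSE)
  fipar_up + (1 - fipar_up) * fipar_down
}

# composite indices forming the aggregation window of (year, month):
# all composites whose timestamp falls in the month, plus the nearest
# composite strictly before the month's first day and the nearest strictly
# after its last day (absent sides at the series edges are skipped)
month_window_indices <- function(composite_index, year, month) {
  within <- which(composite_index$year == year &
                    composite_index$month == month)
  if (length(within) == 0)
    stop(sprintf("month %d-%02d is outside the composite span", year, month),
         call. = FALSE)
  before <- if (min(within) > 1) min(within) - 1L else integer(0)
  after <- if (max(within) < nrow(composite_index)) max(within) + 1L
           else integer(0)
  c(before, within, after)
}

#' Monthly percentile layers from 8-day composites
#'
#' For one calendar month, reduces the composite stack to per-pixel
#' percentiles. The aggregation window holds all composites dated inside the
#' month plus one composite each immediately before and after it (five to six
#' composites for interior months), which buffers missing dates and noise.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7) over the non-missing window values; a pixel
#' with no valid value in the window stays missing.
#'
#' @param world_or_stack A `fapar_world` or a list with elements `composites`
#'   (rows x cols x time array) and `composite_index` (data frame with
#'   columns `year`, `doy`, `month`).
#' @param year,month Calendar month to aggregate.
#' @param probs Probability levels, strictly inside (0, 1).
#' @return A list of matrices, one per probability level (named `p0.05` etc.).
#' @export
monthly_percentiles <- function(world_or_stack, year, month,
                                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(all(probs > 0 & probs < 1))
  x <- world_or_stack
  win <- month_window_indices(x$composite_index, year, month)
  R <- dim(x$composites)[1]; C <- dim(x$composites)[2]
  vals <- matrix(x$composites[, , win], nrow = R * C)
  qs <- t(apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) rep(NA_real_, length(probs))
    else stats::quantile(v, probs, type = 7, names = FALSE)
  }))
  out <- lapply(seq_along(probs), function(i) matrix(qs[, i], R, C))
  names(out) <- sprintf("p%.2f", probs)
  out
}

#' Aggregate a composite stack to a monthly percentile series
#'
#' Applies [monthly_percentiles()] to every month covered by the composite
#' stack; the first and last months use only the side composite that exists.
#'
#' @inheritParams monthly_percentiles
#' @return An object of class `fapar_monthly` with fields `grid`, `months`
#'   (data frame `year`, `month`, `t_years` at mid-month), `probs` and
#'   `values` (rows x cols x months x probs array).
#' @export
aggregate_monthly <- function(world_or_stack, probs = c(0.05, 0.5, 0.95)) {
  x <- world_or_stack
  idx <- x$composite_index
  if (is.null(idx) || nrow(idx) == 0) stop("empty composite stack",
                                           call. = FALSE)
  months <- unique(idx[, c("year", "month")])
  months <- months[order(months$year, months$month), ]
  rownames(months) <- NULL
  months$t_years <- (months$year - 1) + (months$month - 0.5) / 12
  R <- dim(x$composites)[1]; C <- dim(x$composites)[2]
  values <- array(NA_real_, c(R, C, nrow(months), length(probs)))
  for (k in seq_len(nrow(months))) {
    layers <- monthly_percentiles(x, months$year[k], months$month[k], probs)
    for (i in seq_along(probs)) values[, , k, i] <- layers[[i]]
  }
  structure(list(grid = x$grid, months = months, probs = probs,
                 values = values),
            class = "fapar_monthly")
}

#' @export
print.fapar_monthly <- function(x, ...) {
  cat(sprintf("<fapar_monthly> %d x %d pixels, %d months, probs: %s\n",
              dim(x$values)[1], dim(x$values)[2], nrow(x$months),
              paste(x$probs, collapse = ", ")))
  invisible(x)
}

# single percentile raster for (year, month, prob) from a fapar_monthly
monthly_layer <- function(series, year, month, prob) {
  k <- which(series$months$year == year & series$months$month == month)
  i <- which(abs(series$probs - prob) < 1e-9)
  if (length(k) != 1 || length(i) != 1)
    stop(sprintf("month %d-%02d at prob %g not present in series",
                 year, month, prob), call. = FALSE)
  series$values[, , k, i]
}

#' Filter and average station measurements per month
#'
#' Drops records with a stated measurement error greater than 0.1 or a
#' quality flag greater than 1 (both comparisons strict), combines paired
#' up/down readings through [combine_fipar()] (a record with only an upward
#' reading is used as-is), and averages the retained values per station and
#' calendar month.
#'
#' @param measurements Data frame with columns `station_id`, `year`, `month`
#'   (or `doy`), `fipar_up`, `fipar_down`, `error`, `qflag`.
#' @return Data frame `station_id`, `year`, `month`, `fipar` (monthly mean),
#'   `n` (records averaged). May have zero rows.
#' @export
station_monthly_means <- function(measurements) {
  m <- measurements
  if (is.null(m$month)) m$month <- month_of_doy(m$doy)
  keep <- !(m$error > 0.1) & !(m$qflag > 1)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(station_id = character(0), year = integer(0),
                      month = integer(0), fipar = numeric(0), n = integer(0)))
  m$fipar <- ifelse(is.na(m$fipar_down), m$fipar_up,
                    combine_fipar(m$fipar_up, m$fipar_down))
  agg <- stats::aggregate(fipar ~ station_id + year + month, data = m,
                          FUN = mean)
  cnt <- stats::aggregate(fipar ~ station_id + year + month, data = m,
                          FUN = length)
  agg$n <- cnt$fipar
  agg <- agg[order(agg$station_id, agg$year, agg$month), ]
  rownames(agg) <- NULL
  agg
}

#' Pair station monthly means with the matching pixel values
#'
#' For each station-month, looks up the monthly percentile value of the pixel
#' containing the station (no neighbourhood averaging) and returns the paired
#' table used for validating the raster series against ground measurements.
#' Stations outside the grid are skipped with a warning; station-months whose
#' pixel value is missing are omitted.
#'
#' @param series A [aggregate_monthly()] result.
#' @param stations Data frame `station_id`, `lat`, `lon`.
#' @param station_means Output of [station_monthly_means()].
#' @param prob Probability level of the raster series to match (default the
#'   median, `0.5`).
#' @return Data frame `station_id`, `year`, `month`, `observed` (raster
#'   value), `station` (ground value).
#' @export
match_stations <- function(series, stations, station_means, prob = 0.5) {
  loc <- grid_locate(series$grid, stations$lat, stations$lon)
  outside <- is.na(loc$row)
  if (any(outside)) {
    warning("skipping stations outside the grid: ",
            paste(stations$station_id[outside], collapse = ", "))
  }
  loc$station_id <- stations$station_id
  tab <- merge(station_means, loc[!outside, ], by = "station_id")
  i <- which(abs(series$probs - prob) < 1e-9)
  if (length(i) != 1) stop("prob level not present in series", call. = FALSE)
  k <- match(paste(tab$year, tab$month),
             paste(series$months$year, series$months$month))
  keep <- !is.na(k)
  tab <- tab[keep, ]; k <- k[keep]
  obs <- series$values[cbind(tab$row, tab$col, k, i)]
  out <- data.frame(station_id = tab$station_id, year = tab$year,
                    month = tab$month, observed = obs, station = tab$fipar)
  out <- out[!is.na(out$observed), ]
  rownames(out) <- NULL
  out
}
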