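# Plain-text persistence: rasters as TSV value grids with a JSON sidecar
# carrying the grid spec and nodata convention; tables as CSV; regression
# matrices as CSV or Parquet with a JSON sidecar naming the feature order.

NODATA <- -9999

#' Write a raster layer to disk
#'
#' Values go to a tab-separated grid (one line per pixel row, north first);
#' the grid specification and nodata value go to a `<path>.json` sidecar.
#'
#' @param x Numeric matrix.
#' @param path Output path (e.g. `"layer.tsv"`).
#' @param grid The layer's [fg_grid()]; optional.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, grid = NULL) {
  y <- x
  y[is.na(y)] <- NODATA
  utils::write.table(y, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(nrow = nrow(x), ncol = ncol(x), nodata = NODATA)
  if (!is.null(grid))
    meta <- c(meta, list(lat_range = grid$lat_range,
                         lon_range = grid$lon_range))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster layer written by [write_raster()]
#'
#' @param path Path to the TSV grid.
#' @return Numeric matrix with `NA` restored; if the sidecar holds a grid
#'   extent, an `fg_grid` is attached as attribute `"grid"`.
#' @export
read_raster <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x[x == meta$nodata] <- NA
  if (!is.null(meta$lat_range))
    attr(x, "grid") <- fg_grid(meta$nrow, meta$ncol, meta$lat_range,
                               meta$lon_range)
  x
}

#' Write the monthly percentile series to a directory
#'
#' One raster file per (probability level, year, month) following the naming
#' pattern `fapar_p{05|50|95}_{YYYY}_{MM}.tsv`.
#'
#' @param series A [aggregate_monthly()] result.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_monthly_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(series$probs)) {
    tag <- sprintf("p%02d", round(series$probs[i] * 100))
    for (k in seq_len(nrow(series$months))) {
      p <- file.path(dir, sprintf("fapar_%s_%04d_%02d.tsv", tag,
                                  series$months$year[k],
                                  series$months$month[k]))
      write_raster(series$values[, , k, i], p, series$grid)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write and read the covariate layer registry
#'
#' @param set A `covariate_set`.
#' @param path JSON path.
#' @return `path` (write) / data frame (read).
#' @export
write_registry <- function(set, path) {
  jsonlite::write_json(covariate_registry(set), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write and read a regression matrix
#'
#' CSV (default) or Parquet (via the arrow package) with a `<path>.json`
#' sidecar recording the feature order so a reloaded matrix feeds models
#' with the identical layout.
#'
#' @param matrix A `regression_matrix`.
#' @param path Output path.
#' @param format `"csv"` or `"parquet"`.
#' @return `path` (write) / the `regression_matrix` (read).
#' @export
write_matrix <- function(matrix, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  df <- as.data.frame(matrix)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for parquet output", call. = FALSE)
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  jsonlite::write_json(list(features = attr(matrix, "features"),
                            format = format),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- if (identical(meta$format, "parquet")) {
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path)
  }
  attr(df, "features") <- meta$features
  class(df) <- c("regression_matrix", "data.frame")
  df
}

#' Write station measurements as CSV
#'
#' Columns `station_id,date,fipar_up,fipar_down,error,qflag`; the date is
#' encoded as `YYYY-DDD` (synthetic year and day-of-year).
#'
#' @param measurements Measurement table from [generate_stations()].
#' @param path Output path.
#' @export
write_stations_csv <- function(measurements, path) {
  m <- measurements
  out <- data.frame(station_id = m$station_id,
                    date = sprintf("%04d-%03d", m$year, m$doy),
                    fipar_up = m$fipar_up, fipar_down = m$fipar_down,
                    error = m$error, qflag = m$qflag)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stations_csv
#' @export
read_stations_csv <- function(path) {
  out <- utils::read.csv(path)
  parts <- strsplit(out$date, "-", fixed = TRUE)
  out$year <- as.integer(vapply(parts, `[`, character(1), 1))
  out$doy <- as.integer(vapply(parts, `[`, character(1), 2))
  out$month <- month_of_doy(out$doy)
  out
}
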