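#' Define a regular geographic grid
#'
#' All rasters in fapargap are plain numeric matrices carrying a shared grid
#' specification: pixel-centered, row-major, north-up, 0-based pixel indices
#' when exported. Row 1 is the northernmost row, so latitude decreases with
#' the row index; longitude increases with the column index.
#'
#' @param nrow,ncol Number of pixel rows and columns.
#' @param lat_range Numeric length-2, southern and northern edge latitudes
#'   (degrees) of the grid extent.
#' @param lon_range Numeric length-2, western and eastern edge longitudes
#'   (degrees).
#' @return An object of class `fg_grid` with pixel-center coordinate vectors
#'   `lat` (length `nrow`, decreasing) and `lon` (length `ncol`, increasing).
#' @examples
#' g <- fg_grid(8, 8, c(40, 48), c(10, 18))
#' g$lat[1] > g$lat[8]   # north-up
#' @export
fg_grid <- function(nrow, ncol, lat_range = c(32, 48), lon_range = c(10, 26)) {
  stopifnot(length(nrow) == 1L, length(ncol) == 1L, nrow >= 1, ncol >= 1)
  lat_range <- sort(as.numeric(lat_range))
  lon_range <- sort(as.numeric(lon_range))
  dlat <- diff(lat_range) / nrow
  dlon <- diff(lon_range) / ncol
  g <- list(
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    lat_range = lat_range, lon_range = lon_range,
    # pixel centers; lat decreases with row index (north-up)
    lat = lat_range[2] - (seq_len(nrow) - 0.5) * dlat,
    lon = lon_range[1] + (seq_len(ncol) - 0.5) * dlon,
    dlat = dlat, dlon = dlon
  )
  class(g) <- "fg_grid"
  g
}

#' @export
print.fg_grid <- function(x, ...) {
  cat(sprintf("<fg_grid> %d x %d pixels, lat [%g, %g], lon [%g, %g]\n",
              x$nrow, x$ncol, x$lat_range[1], x$lat_range[2],
              x$lon_range[1], x$lon_range[2]))
  invisible(x)
}

#' @export
format.fg_grid <- function(x, ...) {
  sprintf("%dx%d [%g,%g]x[%g,%g]", x$nrow, x$ncol,
          x$lat_range[1], x$lat_range[2], x$lon_range[1], x$lon_range[2])
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a[c("nrow", "ncol", "lat_range", "lon_range")],
                   b[c("nrow", "ncol", "lat_range", "lon_range")]))
}

check_same_grid <- function(a, b, what = "layers") {
  if (!grid_equal(a, b)) stop("grid mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}

#' Locate points on a grid
#'
#' Maps point coordinates to the containing pixel's (row, col) indices.
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid An [fg_grid()].
#' @param lat,lon Numeric vectors of point coordinates (degrees).
#' @return A data frame with columns `row` and `col` (1-based indices).
#' @export
grid_locate <- function(grid, lat, lon) {
  row <- floor((grid$lat_range[2] - lat) / grid$dlat) + 1
  col <- floor((lon - grid$lon_range[1]) / grid$dlon) + 1
  bad <- row < 1 | row > grid$nrow | col < 1 | col > grid$ncol |
    !is.finite(lat) | !is.finite(lon)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# matrix of latitudes (one per pixel), shaped like the grid
lat_matrix <- function(grid) {
  matrix(grid$lat, nrow = grid$nrow, ncol = grid$ncol)
}

#' Clip values to the FAPAR domain
#'
#' @param x Numeric vector, matrix or array.
#' @return `x` with values clamped to `[0, 1]`, dimensions preserved.
#' @export
clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)   # pmin/pmax take attributes from their first argument
  y
}
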