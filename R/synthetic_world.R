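#' Configure a synthetic study region
#'
#' Builds the configuration for [generate_world()]. The synthetic world is a
#' small rectangular region with known "potential" vegetation FAPAR (a smooth
#' squashed function of climate and terrain with latitude-driven seasonality),
#' additive suppression proportional to normalized human pressure, an optional
#' linear trend injected in a designated block, Gaussian observation noise and
#' randomly missing composites. Because every ingredient is known exactly, the
#' world serves as ground truth for the whole assessment pipeline.
#'
#' @param grid_rows,grid_cols Pixel counts (both >= 8).
#' @param lat_range,lon_range Extent in degrees (south/north, west/east edges).
#' @param n_years Number of simulated years (>= 3); composites follow the
#'   8-day cadence with day-of-year anchors 1, 9, ..., 361 (46 per year).
#' @param suppression_delta Suppression of actual FAPAR per unit of normalized
#'   human pressure (FAPAR units; pressure is normalized to `[0, 1]` by its
#'   maximum).
#' @param trend_slope Linear trend (FAPAR units per year) injected in the
#'   designated trend block; 0 disables the trend.
#' @param seasonal_amplitude Peak-to-trough seasonal dip of potential FAPAR at
#'   45 degrees latitude (FAPAR units); scales with `sin(|lat|)`.
#' @param noise_sd Standard deviation of additive observation noise (FAPAR
#'   units).
#' @param missing_rate Fraction of composite observations masked as missing,
#'   in `[0, 1)`.
#' @param seed Integer seed controlling noise, missingness and any sampling.
#' @param composite_step_days Compositing cadence in days; only 8 is
#'   supported.
#' @return A list of class `world_config`.
#' @seealso [generate_world()], [generative_rule()]
#' @export
world_config <- function(grid_rows = 64, grid_cols = 64,
                         lat_range = c(32, 48), lon_range = c(10, 26),
                         n_years = 6, suppression_delta = 0.2,
                         trend_slope = 0.01, seasonal_amplitude = 0.15,
                         noise_sd = 0.05, missing_rate = 0.05, seed = 42,
                         composite_step_days = 8) {
  if (grid_rows < 8 || grid_cols < 8)
    stop("grid_rows and grid_cols must both be >= 8", call. = FALSE)
  if (n_years < 3) stop("n_years must be >= 3", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (composite_step_days != 8)
    stop("only the 8-day compositing cadence is supported", call. = FALSE)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    lat_range = lat_range, lon_range = lon_range,
    n_years = as.integer(n_years), suppression_delta = suppression_delta,
    trend_slope = trend_slope, seasonal_amplitude = seasonal_amplitude,
    noise_sd = noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed), composite_step_days = 8L
  ), class = "world_config")
}

#' The generative rule of the synthetic world, in machine-readable form
#'
#' Returns the exact rule used by [generate_world()] so that tests and oracles
#' evaluate the same formula instead of re-deriving it from documentation:
#'
#' `actual(x, t) = clip01(potential(x, month(t)) - delta * pressure01(x)
#'                         + slope(x) * t + eps)`, `eps ~ N(0, noise_sd)`,
#'
#' with `potential(x, m) = clip01(plogis(eta(x)) - A * sin(|lat|)/sin(45) *
#' (1 + cos(theta(mid_doy(m), lat)))/2)` and
#' `eta(x) = eta0 + eta_bio1 * bio1 + eta_bio12 * (bio12 - 600)`.
#' `theta` is the seasonal phase of [geom_temperature()], so the potential
#' dips in each hemisphere's cold season.
#'
#' @return A list with the coefficient set (`eta0`, `eta_bio1`, `eta_bio12`)
#'   and two functions: `potential(bio1, bio12, lat_deg, month, amplitude)`
#'   and `actual(potential, pressure01, slope, t_years, delta, eps)`.
#' @export
generative_rule <- function() {
  coef <- list(eta0 = -2, eta_bio1 = 0.09, eta_bio12 = 0.002)
  list(
    coefficients = coef,
    potential = function(bio1, bio12, lat_deg, month, amplitude) {
      eta <- coef$eta0 + coef$eta_bio1 * bio1 +
        coef$eta_bio12 * (bio12 - 600)
      cold <- (1 + cos(theta_phase(mid_month_doy(month), lat_deg))) / 2
      season <- sin(abs(lat_deg) * pi / 180) / sin(pi / 4)
      clip01(stats::plogis(eta) - amplitude * season * cold)
    },
    actual = function(potential, pressure01, slope, t_years, delta, eps) {
      clip01(potential - delta * pressure01 + slope * t_years + eps)
    }
  )
}

# designated regions of the synthetic world, as logical masks scaling with
# the grid (fractions of the extent, rounded to whole pixel rows/columns)
world_regions <- function(R, C) {
  rows <- function(a, b) {
    m <- matrix(FALSE, R, C)
    m[max(1, floor(a * R) + 1):max(1, floor(b * R)), ] <- TRUE
    m
  }
  cols <- function(a, b) {
    m <- matrix(FALSE, R, C)
    m[, max(1, floor(a * C) + 1):max(1, floor(b * C))] <- TRUE
    m
  }
  west <- cols(0, 0.5)
  list(
    water     = rows(15 / 16, 1) & cols(0, 1 / 8),
    human     = rows(0, 1 / 4) & cols(1 / 2, 3 / 4),
    trend     = rows(1 / 2, 3 / 4) & cols(5 / 8, 7 / 8),
    to_crop   = rows(3 / 4, 13 / 16) & west,          # forest -> cropland
    to_forest = rows(13 / 16, 7 / 8) & !west,         # cropland -> forest
    forest    = west,
    grass     = !west
  )
}

#' Generate a synthetic world
#'
#' Simulates the full artificial study region described in [world_config()]:
#' static terrain and climate layers, human-pressure layers for a start and an
#' end epoch, land-cover maps for the first and last year, a potential-biome
#' map, the true monthly potential FAPAR and the 8-day actual FAPAR composite
#' stack. Deterministic for a fixed seed.
#'
#' @param config A [world_config()].
#' @return An object of class `fapar_world` containing (among others):
#'   `grid`, static `layers` (elevation, bio1, bio12), `pressure_start` /
#'   `pressure_end` (footprint, population, cropland, nightlights),
#'   `pressure01` (normalized footprint driving the suppression term),
#'   `lc_first` / `lc_last` (ESA-CCI-style level-4 codes), `biome`
#'   (Biome-6000-style class names), `potential` (rows x cols x 12 months),
#'   `composites` (rows x cols x timestamps, `NA` where missing),
#'   `composite_index` (year, day-of-year, month, time in years since start)
#'   and the designated `regions`.
#' @examples
#' w <- generate_world(world_config(grid_rows = 8, grid_cols = 8, n_years = 3,
#'                                  missing_rate = 0, noise_sd = 0))
#' range(w$potential)
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config"))
    stop("config must be created by world_config()", call. = FALSE)
  R <- config$grid_rows; C <- config$grid_cols
  grid <- fg_grid(R, C, config$lat_range, config$lon_range)
  regions <- world_regions(R, C)
  phi <- lat_matrix(grid)

  ur <- matrix((seq_len(R) - 0.5) / R, R, C)
  uc <- matrix((seq_len(C) - 0.5) / C, R, C, byrow = TRUE)

  elevation <- 200 + 600 * sin(pi * ur) * sin(pi * uc)
  # annual means of the geometric temperature pair, lapse included
  bio1 <- 30.6 * cos(phi * pi / 180) - 15.55 * sin(abs(phi) * pi / 180) -
    0.6 * elevation / 100
  bio12 <- 600 + 1200 * sin(pi * uc) * (0.55 + 0.45 * cos(pi * ur))

  rule <- generative_rule()
  potential <- array(NA_real_, c(R, C, 12))
  for (m in 1:12)
    potential[, , m] <- rule$potential(bio1, bio12, phi, m,
                                       config$seasonal_amplitude)

  press_layer <- function(value) value * regions$human
  pressure_start <- list(footprint = press_layer(40),
                         population = press_layer(800),
                         cropland = press_layer(0.6),
                         nightlights = press_layer(15))
  pressure_end <- pressure_start
  pressure_end$nightlights <- press_layer(17)

  mx <- max(pressure_start$footprint)
  pressure01 <- if (mx > 0) pressure_start$footprint / mx else
    pressure_start$footprint

  lc_first <- matrix(130L, R, C)   # grassland baseline
  lc_first[regions$forest] <- 70L  # needleleaved evergreen forest
  lc_first[regions$to_crop] <- 50L # broadleaved evergreen forest
  lc_first[regions$to_forest] <- 10L
  lc_first[regions$human] <- 190L
  lc_first[regions$water] <- 210L
  lc_last <- lc_first
  lc_last[regions$to_crop] <- 10L
  lc_last[regions$to_forest] <- 50L

  biome <- matrix("Tropical savanna", R, C)
  biome[regions$forest] <- "Cool mixed forest"

  slope_map <- config$trend_slope * regions$trend

  years <- seq_len(config$n_years)
  composite_index <- data.frame(
    year = rep(years, each = length(COMPOSITE_DOY)),
    doy = rep(COMPOSITE_DOY, length(years))
  )
  composite_index$month <- month_of_doy(composite_index$doy)
  composite_index$t_years <- (composite_index$year - 1) +
    (composite_index$doy - 1) / 365

  Tn <- nrow(composite_index)
  set.seed(config$seed)
  composites <- array(NA_real_, c(R, C, Tn))
  for (j in seq_len(Tn)) {
    eps <- if (config$noise_sd > 0)
      matrix(stats::rnorm(R * C, 0, config$noise_sd), R, C) else 0
    composites[, , j] <- rule$actual(
      potential[, , composite_index$month[j]], pressure01, slope_map,
      composite_index$t_years[j], config$suppression_delta, eps)
  }
  if (config$missing_rate > 0) {
    miss <- array(stats::runif(R * C * Tn) < config$missing_rate, c(R, C, Tn))
    composites[miss] <- NA_real_
  }

  structure(list(
    config = config, grid = grid, regions = regions,
    layers = list(elevation = elevation, bio1 = bio1, bio12 = bio12),
    pressure_start = pressure_start, pressure_end = pressure_end,
    pressure01 = pressure01, slope_map = slope_map,
    lc_first = lc_first, lc_last = lc_last, biome = biome,
    potential = potential, composites = composites,
    composite_index = composite_index
  ), class = "fapar_world")
}

#' @export
print.fapar_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<fapar_world> %d x %d pixels, %d years (%d composites)\n",
    "  suppression %.3g, trend %.3g/yr, noise sd %.3g, missing %.3g\n"),
    cfg$grid_rows, cfg$grid_cols, cfg$n_years, nrow(x$composite_index),
    cfg$suppression_delta, cfg$trend_slope, cfg$noise_sd, cfg$missing_rate))
  invisible(x)
}

# expected (noise-free, pre-missingness) composite values; used by oracles
world_expected_composites <- function(world, j = NULL) {
  idx <- world$composite_index
  if (is.null(j)) j <- seq_len(nrow(idx))
  rule <- generative_rule()
  out <- array(NA_real_, c(world$config$grid_rows, world$config$grid_cols,
                           length(j)))
  for (k in seq_along(j)) {
    jj <- j[k]
    out[, , k] <- rule$actual(world$potential[, , idx$month[jj]],
                              world$pressure01, world$slope_map,
                              idx$t_years[jj], world$config$suppression_delta,
                              0)
  }
  out
}

#' True actual-versus-potential gap of a synthetic world
#'
#' Computes the exact expected gap `potential - E[actual]` per pixel from the
#' generative rule: the suppression term plus (negated) accumulated trend.
#' This is an oracle for validating the estimated gap; it plays no part in
#' model fitting.
#'
#' @param world A [generate_world()] result.
#' @param t_years Time point (years since series start) at which the trend has
#'   accumulated; defaults to the last composite timestamp.
#' @return A matrix (FAPAR units); positive values mean actual below
#'   potential.
#' @export
true_gap <- function(world, t_years = NULL) {
  stopifnot(inherits(world, "fapar_world"))
  if (is.null(t_years)) t_years <- max(world$composite_index$t_years)
  world$config$suppression_delta * world$pressure01 -
    world$slope_map * t_years
}

#' Simulate ground-station FIPAR measurements
#'
#' Places stations at pixel centers of non-water pixels and simulates paired
#' upward/downward hemispherical-photography readings at every composite
#' date. The pair is constructed so that the standard up/down combination
#' ([combine_fipar()]) recovers the pixel's expected actual FAPAR, before
#' measurement noise. A configurable fraction of records carries a large
#' stated measurement error or a raised quality flag to exercise downstream
#' filtering.
#'
#' @param world A [generate_world()] result.
#' @param n_stations Number of stations (>= 1, at most the number of non-water
#'   pixels).
#' @param seed Integer seed.
#' @param error_scale Standard deviation of measurement noise added to each of
#'   the up/down readings (also reported in the `error` column).
#' @param flagged_fraction Fraction of records made invalid (stated error
#'   above 0.1 or quality flag above 1).
#' @return A list with `stations` (id, row, col, lat, lon) and `measurements`
#'   (station_id, year, doy, month, fipar_up, fipar_down, error, qflag).
#' @export
generate_stations <- function(world, n_stations = 12, seed = 1,
                              error_scale = 0.02, flagged_fraction = 0.1) {
  stopifnot(inherits(world, "fapar_world"), n_stations >= 1)
  ok <- which(!world$regions$water)
  if (n_stations > length(ok))
    stop("n_stations exceeds the number of available pixels", call. = FALSE)
  set.seed(seed)
  pix <- sort(sample(ok, n_stations))
  R <- world$config$grid_rows
  row <- ((pix - 1) %% R) + 1
  col <- ((pix - 1) %/% R) + 1
  stations <- data.frame(
    station_id = sprintf("ST%03d", seq_len(n_stations)),
    row = row, col = col,
    lat = world$grid$lat[row], lon = world$grid$lon[col]
  )

  idx <- world$composite_index
  expected <- world_expected_composites(world)
  n_rec <- n_stations * nrow(idx)
  v <- numeric(n_rec)
  for (s in seq_len(n_stations))
    v[(s - 1) * nrow(idx) + seq_len(nrow(idx))] <- expected[row[s], col[s], ]
  # split v into an up/down pair whose Beer-Lambert-style combination
  # returns v exactly: up = down = 1 - sqrt(1 - v)
  u <- 1 - sqrt(pmax(0, 1 - v))
  up <- clip01(u + stats::rnorm(n_rec, 0, error_scale))
  down <- clip01(u + stats::rnorm(n_rec, 0, error_scale))
  err <- rep(error_scale, n_rec)
  qflag <- rep(1L, n_rec)
  n_bad <- round(flagged_fraction * n_rec)
  if (n_bad > 0) {
    bad <- sample(n_rec, n_bad)
    half <- bad[seq_len(ceiling(length(bad) / 2))]
    err[half] <- 0.1 + stats::runif(length(half), 0.01, 0.2)
    qflag[setdiff(bad, half)] <- 2L
  }
  measurements <- data.frame(
    station_id = rep(stations$station_id, each = nrow(idx)),
    year = rep(idx$year, n_stations), doy = rep(idx$doy, n_stations),
    month = rep(idx$month, n_stations),
    fipar_up = up, fipar_down = down, error = err, qflag = qflag
  )
  list(stations = stations, measurements = measurements)
}
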