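#' Seasonal phase angle for the geometric temperatures
#'
#' Phase `theta = (day - 18) * 2*pi/365 + 2^(1 - sgn(lat)) * pi`, where day 18
#' is the coldest day of the northern and warmest day of the southern
#' hemisphere. `sgn(0) = 0`, so the equator gets a phase offset of `2*pi`;
#' this is immaterial downstream because the seasonal term is scaled by
#' `sin(|lat|) = 0` there. Uses the 365-day working calendar.
#'
#' @param day Day of year (1-365).
#' @param phi Latitude in degrees (-90..90).
#' @return Phase angle in radians.
#' @export
theta_phase <- function(day, phi) {
  stopifnot(all(day >= 1 & day <= 365), all(abs(phi) <= 90))
  (day - 18) * 2 * pi / 365 + 2^(1 - sign(phi)) * pi
}

#' Geometric minimum and maximum temperature
#'
#' Analytic pseudo-temperatures encoding earth geometry (latitude,
#' day-of-year and elevation) as model covariates:
#' `t_min = 24.2*cos(phi) - 15.7*(1 - cos(theta))*sin(|phi|) - 0.6*z/100` and
#' `t_max = 37*cos(phi) - 15.4*(1 - cos(theta))*sin(|phi|) - 0.6*z/100`,
#' with the phase from [theta_phase()]. At the equator they are constant
#' (24.2 and 37 degrees C at sea level); 0.6 is the lapse in degrees C per
#' 100 m of elevation.
#'
#' @inheritParams theta_phase
#' @param z Elevation in meters.
#' @param which `"min"` or `"max"`.
#' @return Temperature in degrees C (vectorized over the inputs).
#' @examples
#' geom_temperature(1, 0, 0, "min")  # 24.2
#' geom_temperature(1, 0, 0, "max")  # 37
#' @export
geom_temperature <- function(day, phi, z = 0, which = c("min", "max")) {
  which <- match.arg(which)
  th <- theta_phase(day, phi)
  phir <- phi * pi / 180
  seas <- (1 - cos(th)) * sin(abs(phir))
  if (which == "min") 24.2 * cos(phir) - 15.7 * seas - 0.6 * z / 100
  else 37 * cos(phir) - 15.4 * seas - 0.6 * z / 100
}

#' Monthly anomaly layer
#'
#' Elementwise difference between an actual monthly layer and its long-term
#' monthly counterpart; missing values propagate.
#'
#' @param actual,longterm Matrices on the same grid.
#' @return Matrix `actual - longterm`.
#' @export
monthly_anomaly <- function(actual, longterm) {
  if (!all(dim(actual) == dim(longterm)))
    stop("grid mismatch between actual and long-term layers", call. = FALSE)
  actual - longterm
}

# ESA-CCI-style level-4 land-cover codes grouped into the four vegetation
# cover types; level-4 subclasses (61, 62, 71, ... 121, 122, 151, 152) carry
# their parent class's group
CCI_GROUPS <- list(
  forest    = c(50L, 60L, 61L, 62L, 70L, 71L, 72L, 80L, 81L, 82L, 90L,
                100L, 160L, 170L),
  shrubland = c(120L, 121L, 122L),
  grassland = c(110L, 130L),
  cropland  = c(10L, 11L, 12L, 20L, 30L)
)
CCI_NONVEG <- c(40L, 140L, 150L, 151L, 152L, 180L, 190L, 200L, 201L, 202L,
                210L, 220L)
CCI_CODES <- c(unlist(CCI_GROUPS, use.names = FALSE), CCI_NONVEG)

# Biome-6000-style class names grouped into vegetation cover types
BIOME_GROUPS <- list(
  forest = c("Cold deciduous forest", "Cold evergreen needleleaf forest",
             "Cool evergreen needleleaf forest", "Cool mixed forest",
             "Cool temperate rainforest", "Temperate deciduous broadleaf forest",
             "Temperate evergreen needleleaf open woodland",
             "Temperate sclerophyll woodland and shrubland",
             "Tropical deciduous broadleaf forest and woodland",
             "Tropical evergreen broadleaf forest",
             "Tropical semi evergreen broadleaf forest",
             "Warm temperate evergreen and mixed forest"),
  shrubland = "Xerophytic woods scrub",
  grassland = "Tropical savanna"
)

#' Vegetation cover indicator layers from a land-cover map
#'
#' Derives the four presence/absence indicator layers (values 0 or 100) for
#' forest, shrubland, grassland and cropland from level-4 land-cover codes.
#' Non-vegetation codes (bare, urban, water, ice, ...) set all four
#' indicators to 0; at most one indicator is 100 per pixel.
#'
#' @param landcover Integer matrix of supported level-4 codes.
#' @return Named list of four matrices (`forest`, `shrubland`, `grassland`,
#'   `cropland`).
#' @export
vegetation_indicators <- function(landcover) {
  codes <- unique(as.vector(landcover))
  codes <- codes[!is.na(codes)]
  unknown <- setdiff(codes, CCI_CODES)
  if (length(unknown) > 0)
    stop("unknown land-cover code(s): ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  lapply(CCI_GROUPS, function(g) {
    m <- matrix(0, nrow(landcover), ncol(landcover))
    m[landcover %in% g] <- 100
    m[is.na(landcover)] <- NA
    m
  })
}

#' Vegetation indicator layers from a potential-biome map
#'
#' Maps biome class names to the three natural vegetation groups (forest,
#' shrubland, grassland) as presence/absence layers (0 or 100). Used to build
#' the counterfactual covariate stack, where observed vegetation cover is
#' replaced by the potential biome distribution.
#'
#' @param biome Character matrix of biome class names.
#' @return Named list of three matrices (`forest`, `shrubland`, `grassland`).
#' @export
biome_indicators <- function(biome) {
  classes <- unique(as.vector(biome))
  classes <- classes[!is.na(classes)]
  unknown <- setdiff(classes, unlist(BIOME_GROUPS, use.names = FALSE))
  if (length(unknown) > 0)
    stop("unmapped biome class(es): ", paste(unknown, collapse = "; "),
         call. = FALSE)
  lapply(BIOME_GROUPS, function(g) {
    m <- matrix(0, nrow(biome), ncol(biome))
    m[biome %in% g] <- 100
    m[is.na(biome)] <- NA
    m
  })
}

#' Resample a raster layer to a new pixel count
#'
#' Separable interpolation from source to target pixel centers over the same
#' extent. Continuous layers use bilinear or cubic-spline interpolation;
#' categorical layers must use nearest-neighbour.
#'
#' @param layer Numeric matrix.
#' @param target_dim Integer length-2: target `c(nrow, ncol)`.
#' @param method `"bilinear"`, `"cubic"` (natural cubic splines) or
#'   `"nearest"`.
#' @param categorical Logical; if `TRUE`, only `"nearest"` is allowed.
#' @return Matrix of dimension `target_dim` with a `resample_method`
#'   attribute.
#' @export
resample_layer <- function(layer, target_dim,
                           method = c("bilinear", "cubic", "nearest"),
                           categorical = FALSE) {
  method <- match.arg(method)
  if (categorical && method != "nearest")
    stop("categorical layers must be resampled with method = \"nearest\"",
         call. = FALSE)
  nr <- nrow(layer); nc <- ncol(layer)
  tr <- target_dim[1]; tc <- target_dim[2]
  ys <- (seq_len(nr) - 0.5) / nr; xs <- (seq_len(nc) - 0.5) / nc
  yt <- (seq_len(tr) - 0.5) / tr; xt <- (seq_len(tc) - 0.5) / tc
  if (identical(c(nr, nc), as.integer(c(tr, tc)))) {
    out <- layer
  } else if (method == "nearest") {
    ri <- pmin(nr, pmax(1L, as.integer(round(yt * nr + 0.5 - 1e-9))))
    ci <- pmin(nc, pmax(1L, as.integer(round(xt * nc + 0.5 - 1e-9))))
    out <- layer[ri, ci, drop = FALSE]
  } else {
    interp1 <- function(x, y, xout) {
      if (length(x) == 1) return(rep(y, length(xout)))
      if (method == "bilinear")
        stats::approx(x, y, xout, rule = 2)$y
      else
        stats::spline(x, y, xout = xout, method = "natural")$y
    }
    tmp <- t(apply(layer, 1, function(row) interp1(xs, row, xt)))
    out <- apply(tmp, 2, function(col) interp1(ys, col, yt))
    out <- matrix(out, tr, tc)
  }
  attr(out, "resample_method") <- method
  out
}

#' Assemble a named covariate set
#'
#' Bundles static, annual and monthly covariate layers into the single named,
#' ordered container used for building regression matrices and making
#' predictions. Layer order is fixed at assembly so fitted models see a
#' reproducible feature order. Human-pressure layers (and only those) carry a
#' pressure flag; exactly four are required because the counterfactual
#' scenario ablates that specific set.
#'
#' @param grid An [fg_grid()].
#' @param n_years Number of years spanned by annual/monthly layers.
#' @param layers Named list; each element a list with fields `kind`
#'   (`"static"`, `"annual"` or `"monthly"`), `units`, `pressure` (logical)
#'   and `data` (matrix for static, rows x cols x n_years array for annual,
#'   rows x cols x 12*n_years array for monthly).
#' @return An object of class `covariate_set`.
#' @export
assemble_covariates <- function(grid, n_years, layers) {
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm))
    stop("layer names must be present and unique", call. = FALSE)
  for (n in nm) {
    l <- layers[[n]]
    stopifnot(l$kind %in% c("static", "annual", "monthly"))
    d <- dim(l$data)
    if (d[1] != grid$nrow || d[2] != grid$ncol)
      stop("layer ", n, " does not share the grid", call. = FALSE)
    want <- switch(l$kind, static = NA, annual = n_years,
                   monthly = 12L * n_years)
    if (!is.na(want) && (length(d) != 3 || d[3] != want))
      stop("layer ", n, " has the wrong temporal depth for kind ", l$kind,
           call. = FALSE)
  }
  pressure <- nm[vapply(layers, function(l) isTRUE(l$pressure), logical(1))]
  if (length(pressure) != 4)
    stop("exactly four layers must carry the human-pressure flag (got ",
         length(pressure), ")", call. = FALSE)
  structure(list(grid = grid, n_years = as.integer(n_years), layers = layers),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, character(1), "kind")
  cat(sprintf("<covariate_set> %d layers on %s (%d static, %d annual, %d monthly)\n",
              length(x$layers), format(x$grid), sum(kinds == "static"),
              sum(kinds == "annual"), sum(kinds == "monthly")))
  invisible(x)
}

#' Layer registry of a covariate set
#'
#' @param set A [assemble_covariates()] result.
#' @return Data frame `name`, `kind`, `units`, `pressure` in feature order.
#' @export
covariate_registry <- function(set) {
  data.frame(
    name = names(set$layers),
    kind = vapply(set$layers, `[[`, character(1), "kind"),
    units = vapply(set$layers, `[[`, character(1), "units"),
    pressure = vapply(set$layers, function(l) isTRUE(l$pressure), logical(1)),
    row.names = NULL
  )
}

# value of one layer at (year, month) as a matrix
covset_layer_value <- function(set, name, year, month) {
  l <- set$layers[[name]]
  switch(l$kind,
         static = l$data,
         annual = l$data[, , year],
         monthly = l$data[, , (year - 1) * 12 + month])
}

#' Covariate set of a synthetic world
#'
#' Builds the model-facing covariate registry of a [generate_world()] world:
#' terrain and climate statics (elevation, bio1, bio12), monthly geometric
#' minimum/maximum temperatures, annual vegetation-cover indicators derived
#' from the land-cover maps, the four human-pressure layers and a year-index
#' layer giving the model access to the temporal position of each
#' observation. The raw (unnormalized) pressure layers are what the model
#' sees; the generative suppression acts on the normalized pressure, keeping
#' effect-size truth separate from covariate scaling.
#'
#' @param world A [generate_world()] result.
#' @return A [assemble_covariates()] `covariate_set`.
#' @export
world_covariates <- function(world) {
  R <- world$config$grid_rows; C <- world$config$grid_cols
  ny <- world$config$n_years
  phi <- lat_matrix(world$grid)
  z <- world$layers$elevation

  monthly_geom <- function(which) {
    a <- array(NA_real_, c(R, C, 12 * ny))
    for (m in 1:12) {
      layer <- geom_temperature(mid_month_doy(m), phi, z, which)
      for (y in seq_len(ny)) a[, , (y - 1) * 12 + m] <- layer
    }
    a
  }
  annual_rep <- function(first, last) {
    a <- array(NA_real_, c(R, C, ny))
    for (y in seq_len(ny)) a[, , y] <- if (y < ny) first else last
    a
  }
  veg_first <- vegetation_indicators(world$lc_first)
  veg_last <- vegetation_indicators(world$lc_last)
  year_frac <- array(rep((seq_len(ny) - 0.5), each = R * C), c(R, C, ny))

  lay <- function(kind, units, data, pressure = FALSE)
    list(kind = kind, units = units, data = data, pressure = pressure)
  layers <- list(
    elevation = lay("static", "m", z),
    bio1 = lay("static", "degC", world$layers$bio1),
    bio12 = lay("static", "mm", world$layers$bio12),
    tmin_geom = lay("monthly", "degC", monthly_geom("min")),
    tmax_geom = lay("monthly", "degC", monthly_geom("max")),
    forest = lay("annual", "indicator", annual_rep(veg_first$forest,
                                                   veg_last$forest)),
    shrubland = lay("annual", "indicator", annual_rep(veg_first$shrubland,
                                                      veg_last$shrubland)),
    grassland = lay("annual", "indicator", annual_rep(veg_first$grassland,
                                                      veg_last$grassland)),
    cropland = lay("annual", "indicator", annual_rep(veg_first$cropland,
                                                     veg_last$cropland)),
    footprint = lay("annual", "score",
                    annual_rep(world$pressure_start$footprint,
                               world$pressure_end$footprint), TRUE),
    population = lay("annual", "count",
                     annual_rep(world$pressure_start$population,
                                world$pressure_end$population), TRUE),
    cropland_intensity = lay("annual", "fraction",
                             annual_rep(world$pressure_start$cropland,
                                        world$pressure_end$cropland), TRUE),
    nightlights = lay("annual", "nW.cm-2.sr-1",
                      annual_rep(world$pressure_start$nightlights,
                                 world$pressure_end$nightlights), TRUE),
    year_frac = lay("annual", "years", year_frac)
  )
  assemble_covariates(world$grid, ny, layers)
}
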