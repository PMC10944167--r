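test_that("seasonal phase hits the cold/warm extremes on day 18", {
  expect_equal(cos(theta_phase(18, 45)), -1)   # northern coldest day
  expect_equal(cos(theta_phase(18, -45)), 1)   # southern warmest day
  expect_equal(theta_phase(18, 0), 2 * pi)     # sgn(0) = 0 convention
  expect_error(theta_phase(400, 10))
})

test_that("geometric temperatures match closed-form evaluations", {
  for (day in c(1, 18, 100, 200, 365)) {
    expect_equal(geom_temperature(day, 0, 0, "min"), 24.2)
    expect_equal(geom_temperature(day, 0, 0, "max"), 37)
  }
  # elevation lapse: 0.6 degrees per 100 m
  expect_equal(geom_temperature(100, 30, 0, "min") -
                 geom_temperature(100, 30, 500, "min"), 3)
  # northern winter at 65N: both seasonal terms at full swing
  expect_equal(geom_temperature(18, 65, 0, "min"),
               24.2 * cos(65 * pi / 180) - 15.7 * 2 * sin(65 * pi / 180),
               tolerance = 1e-12)
  expect_equal(geom_temperature(18, 65, 0, "min"), -18.2307,
               tolerance = 1e-4)
})

test_that("t_max dominates t_min and seasons mirror across hemispheres", {
  days <- seq(1, 365, by = 7)
  phis <- seq(-85, 85, by = 5)
  grid <- expand.grid(day = days, phi = phis, z = c(0, 1500))
  tmin <- geom_temperature(grid$day, grid$phi, grid$z, "min")
  tmax <- geom_temperature(grid$day, grid$phi, grid$z, "max")
  expect_true(all(tmax >= tmin))
  # near-periodicity across the year boundary: day 365 sits one day from
  # day 1 on the seasonal circle
  one_day <- abs(geom_temperature(19, 40, 0, "min") -
                   geom_temperature(18, 40, 0, "min"))
  expect_lt(abs(geom_temperature(365, 40, 0, "min") -
                  geom_temperature(1, 40, 0, "min")),
            2 * max(one_day, 0.05))
  # hemisphere mirror: the north on day 18 equals the south half a year
  # later (day 200/201), to within one composite step
  north <- geom_temperature(18, 50, 0, "min")
  south <- geom_temperature(200, -50, 0, "min")
  expect_lt(abs(north - south),
            abs(geom_temperature(26, 50, 0, "min") -
                  geom_temperature(18, 50, 0, "min")) + 1e-6)
})

test_that("monthly anomalies subtract elementwise and propagate missing", {
  a <- matrix(c(12, NA, 3, 4), 2, 2)
  b <- matrix(c(10, 1, 3, 1), 2, 2)
  expect_equal(monthly_anomaly(a, b), matrix(c(2, NA, 0, 3), 2, 2))
  expect_equal(monthly_anomaly(b, b), matrix(0, 2, 2))
  set.seed(1)
  x <- matrix(rnorm(64), 8, 8); y <- matrix(rnorm(64), 8, 8)
  expect_equal(monthly_anomaly(x, y), x - y)
  expect_error(monthly_anomaly(x, matrix(0, 4, 4)), "mismatch")
})

test_that("vegetation indicators follow the land-cover crosswalk", {
  lc <- matrix(c(70L, 130L, 210L, 10L, 120L, 110L, 190L, 50L, 30L), 3, 3)
  ind <- vegetation_indicators(lc)
  expect_equal(ind$forest[lc == 70], 100)
  expect_equal(ind$forest[lc == 50], 100)
  expect_equal(ind$grassland[lc == 130], 100)
  expect_equal(ind$grassland[lc == 110], 100)
  expect_equal(ind$shrubland[lc == 120], 100)
  expect_equal(ind$cropland[lc %in% c(10, 30)], c(100, 100))
  # water and urban carry no vegetation indicator
  for (g in ind) expect_equal(g[lc %in% c(210, 190)], c(0, 0))
  # at most one indicator set per pixel
  tot <- ind$forest + ind$shrubland + ind$grassland + ind$cropland
  expect_true(all(tot %in% c(0, 100)))
  expect_error(vegetation_indicators(matrix(999L)), "999")
})

test_that("biome indicators map classes to vegetation groups", {
  b <- matrix(c("Cool mixed forest", "Tropical savanna",
                "Xerophytic woods scrub", "Tropical savanna"), 2, 2)
  ind <- biome_indicators(b)
  expect_equal(ind$forest[1, 1], 100)
  expect_equal(ind$grassland[b == "Tropical savanna"], c(100, 100))
  expect_equal(ind$shrubland[1, 2], 100)
  expect_error(biome_indicators(matrix("Atlantis kelp")), "Atlantis")
})

test_that("resampling preserves constants, bounds and categorical rules", {
  const <- matrix(0.7, 5, 5)
  for (m in c("bilinear", "cubic", "nearest")) {
    up <- resample_layer(const, c(20, 20), method = m)
    expect_equal(up, matrix(0.7, 20, 20), ignore_attr = TRUE)
    expect_equal(attr(up, "resample_method"), m)
  }
  ramp <- outer(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10), "+")
  up <- resample_layer(ramp, c(37, 41), method = "bilinear")
  expect_true(all(up >= min(ramp) & up <= max(ramp)))
  expect_equal(resample_layer(ramp, c(10, 10)), ramp, ignore_attr = TRUE)
  expect_error(resample_layer(ramp, c(20, 20), method = "cubic",
                              categorical = TRUE), "nearest")
  down <- resample_layer(ramp, c(5, 5), method = "cubic")
  expect_equal(dim(down), c(5, 5))
})

test_that("covariate assembly fixes names, order and pressure flags", {
  w <- clean_world()
  covs <- world_covariates(w)
  reg <- covariate_registry(covs)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(sort(reg$name[reg$pressure]),
               sort(c("footprint", "population", "cropland_intensity",
                      "nightlights")))
  # monthly layers answer by (year, month); annual by year
  tm <- fapargap:::covset_layer_value(covs, "tmin_geom", 2, 7)
  phi <- matrix(w$grid$lat, 16, 16)
  expect_equal(tm, geom_temperature(fapargap:::mid_month_doy(7), phi,
                                    w$layers$elevation, "min"))
  # assembling with a wrong pressure count fails
  lay <- covs$layers
  lay$footprint$pressure <- FALSE
  expect_error(assemble_covariates(covs$grid, covs$n_years, lay),
               "four")
  names(lay)[1] <- "bio1"
  expect_error(assemble_covariates(covs$grid, covs$n_years, lay), "unique")
})
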