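test_that("the counterfactual scenario ablates exactly the right layers", {
  w <- tiny_world()
  covs <- world_covariates(w)
  scen <- build_potential_scenario(covs, w$biome)
  reg <- covariate_registry(covs)

  for (nm in reg$name[reg$pressure])
    expect_true(all(scen$layers[[nm]]$data == 0))
  expect_true(all(scen$layers$cropland$data == 0))
  # natural vegetation indicators now follow the biome map
  bio <- biome_indicators(w$biome)
  expect_equal(scen$layers$forest$data[, , 1], bio$forest)
  expect_equal(scen$layers$grassland$data[, , 2], bio$grassland)
  # continuous, non-pressure layers are bit-identical
  for (nm in c("elevation", "bio1", "bio12", "tmin_geom", "tmax_geom",
               "year_frac"))
    expect_identical(scen$layers[[nm]]$data, covs$layers[[nm]]$data)

  # idempotence
  scen2 <- build_potential_scenario(scen, w$biome)
  expect_equal(scen2$layers, scen$layers)

  # an urban pixel in a forest-biome region flips cropland/urban off and
  # forest on
  w2 <- w
  w2$biome[] <- "Cool mixed forest"
  scen3 <- build_potential_scenario(covs, w2$biome)
  hb <- which(w$regions$human, arr.ind = TRUE)[1, ]
  expect_equal(scen3$layers$forest$data[hb[1], hb[2], 1], 100)
  expect_equal(scen3$layers$cropland$data[hb[1], hb[2], 1], 0)
})

test_that("gap is an antisymmetric difference with a mean annual summary", {
  set.seed(5)
  a <- array(runif(4 * 4 * 12), c(4, 4, 12))
  b <- array(runif(4 * 4 * 12), c(4, 4, 12))
  g1 <- compute_gap(a, b)
  g2 <- compute_gap(b, a)
  expect_equal(g1$monthly, -g2$monthly)
  expect_equal(g1$annual, -g2$annual)
  expect_equal(compute_gap(a, a)$annual, matrix(0, 4, 4))
  expect_equal(compute_gap(array(0.6, dim(a)), array(0.8, dim(a)))$annual,
               matrix(-0.2, 4, 4))
  # annual mean equals the brute-force mean over months
  manual <- matrix(0, 4, 4)
  for (m in 1:12) manual <- manual + (a[, , m] - b[, , m]) / 12
  expect_equal(g1$annual, manual)
  expect_error(compute_gap(a, b[, , 1:6]), "aligned")
})

test_that("year extraction demands complete months", {
  w <- clean_world()
  series <- aggregate_monthly(w)
  stack <- monthly_year_stack(series, 2, 0.95)
  expect_equal(dim(stack), c(16, 16, 12))
  short <- series
  keep <- !(short$months$year == 2 & short$months$month %in% c(3, 8))
  short$months <- short$months[keep, ]
  short$values <- short$values[, , keep, , drop = FALSE]
  expect_error(monthly_year_stack(short, 2, 0.95), "3, 8")
})

test_that("STL reconstructs its input and isolates clean components", {
  t <- 1:72
  # constant series
  d0 <- stl_decompose(rep(0.4, 72))
  expect_equal(d0$trend + d0$seasonal + d0$remainder, rep(0.4, 72))
  expect_lt(max(abs(d0$seasonal)), 1e-6)
  expect_lt(max(abs(d0$remainder)), 1e-6)

  # pure seasonal cycle: the trend stays flat and the cycle goes seasonal
  x <- 0.5 + 0.2 * sin(2 * pi * t / 12)
  d <- stl_decompose(x)
  expect_equal(d$trend + d$seasonal + d$remainder, x, tolerance = 1e-12)
  expect_lt(max(d$trend) - min(d$trend), 0.02)
  expect_gt(max(d$seasonal) - min(d$seasonal), 0.35)

  # missing values are interpolated, then the identity holds on the fill
  x2 <- x; x2[c(5, 20, 21, 60)] <- NA
  d2 <- stl_decompose(x2)
  expect_equal(d2$trend + d2$seasonal + d2$remainder, d2$filled,
               tolerance = 1e-12)
  expect_error(stl_decompose(x[1:20]), "two full periods")
})

test_that("trend fits recover slopes and degenerate inputs behave", {
  t_years <- (seq_len(72) - 0.5) / 12
  x <- 0.3 + 0.01 * t_years + 0.1 * sin(2 * pi * seq_len(72) / 12)
  tf <- trend_fit(x, t_years)
  expect_lt(abs(tf$beta - 0.01), 1e-3)
  expect_gt(tf$r2, 0.99)

  flat <- trend_fit(rep(0.4, 72), t_years)
  expect_equal(flat$beta, 0, tolerance = 1e-10)

  all_na <- trend_fit(rep(NA_real_, 72), t_years)
  expect_true(is.na(all_na$beta))
  expect_error(trend_fit(x[1:12], t_years[1:12]), "24")
})

test_that("white-noise series reject at an inflated but bounded rate", {
  # the slope test runs on a loess-smoothed component, so its type-I error
  # exceeds the nominal 0.005 by construction; assert it stays within an
  # order of magnitude of a plain OLS-on-noise reference
  set.seed(31)
  t_years <- (seq_len(72) - 0.5) / 12
  p <- replicate(200, trend_fit(rnorm(72, 0.5, 0.05), t_years)$p)
  expect_gt(mean(p < 0.005), 0)       # it does fire
  expect_lt(mean(p < 0.005), 0.6)     # but not always
})

test_that("per-pixel trend rasters equal the scalar pipeline", {
  w <- generate_world(world_config(grid_rows = 8, grid_cols = 8, n_years = 6,
                                   trend_slope = 0.02, noise_sd = 0.02,
                                   missing_rate = 0.05, seed = 13))
  series <- aggregate_monthly(w)
  tr <- trend_raster(series)
  expect_equal(dim(tr$beta), c(8, 8))
  i95 <- which(series$probs == 0.95)
  for (px in list(c(1, 1), c(5, 6), c(8, 8))) {
    v <- series$values[px[1], px[2], , i95]
    tf <- trend_fit(v, series$months$t_years)
    expect_equal(tr$beta[px[1], px[2]], tf$beta)
    expect_equal(tr$p[px[1], px[2]], tf$p)
    expect_equal(tr$alpha[px[1], px[2]], tf$alpha)
  }
  # injected slope recovered inside the block, absent outside
  expect_lt(abs(mean(tr$beta[w$regions$trend]) - 0.02), 0.2 * 0.02)
  expect_lt(abs(mean(tr$beta[!w$regions$trend])), 0.004)
})

test_that("land-cover change classes compose two aggregations", {
  expect_equal(lc_aggregate(11L), "CRPRF")
  expect_equal(lc_aggregate(71L), "TRENE")
  cls <- lc_change_classes(matrix(c(50L, 71L), 1, 2),
                           matrix(c(10L, 71L), 1, 2))
  expect_equal(cls[1, 1], "TREBE-CRPRF")
  expect_equal(cls[1, 2], "TRENE")
  expect_error(lc_change_classes(matrix(33L), matrix(33L)), "33")
  # every supported code has a class
  expect_true(all(!is.na(lc_aggregate(fapargap:::CCI_CODES))))
})

test_that("class summaries count gaps and significant trends per class", {
  classes <- matrix(c("A", "A", "B", "B"), 2, 2)
  gap <- matrix(c(-0.1, -0.2, 0.1, 0.05), 2, 2)
  trend <- list(beta = matrix(c(0.01, 0.02, -0.01, 0.02), 2, 2),
                p = matrix(c(0.001, 0.5, 0.0001, 0.0001), 2, 2))
  s <- summarize_by_class(gap, trend, classes)
  a <- s[s$class == "A", ]; b <- s[s$class == "B", ]
  expect_equal(a$frac_gap_negative, 1)
  expect_equal(b$frac_gap_negative, 0)
  expect_equal(a$frac_trend_pos_sig, 0.5)
  expect_equal(b$frac_trend_pos_sig, 0.5)
  expect_equal(b$frac_trend_neg_sig, 0.5)
  expect_equal(s$class[1], "A")   # sorted by fraction negative
  gf <- attr(s, "global_fractions")
  expect_equal(unname(gf["pos_sig"] + gf["neg_sig"]), 0.75)
  # zero gap everywhere: no negative fractions
  s0 <- summarize_by_class(matrix(0, 2, 2), trend, classes)
  expect_true(all(s0$frac_gap_negative == 0))
})
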