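# exhaustive-search oracle: all allocations >= n_min summing to n_total,
# minimizing the L1 distance to the exact minimum-plus-Neyman-share target
oracle_allocation_objective <- function(N, S, n_total, n_min) {
  H <- length(N)
  exact <- n_min + N * S / sum(N * S) * (n_total - n_min * H)
  best <- Inf
  grids <- expand.grid(lapply(seq_len(H - 1), function(i)
    n_min:(n_total - n_min * (H - 1))))
  for (r in seq_len(nrow(grids))) {
    n <- c(as.numeric(grids[r, ]), n_total - sum(grids[r, ]))
    if (n[H] < n_min) next
    best <- min(best, sum(abs(n - exact)))
  }
  best
}

test_that("strata classification covers the land mask with listed codes", {
  w <- tiny_world()
  nl <- w$pressure_end$nightlights - w$pressure_start$nightlights
  strata <- classify_strata(nl, w$lc_first, w$lc_last, w$pressure_start,
                            w$pressure_end)
  # every pixel gets exactly one code; water is 0; others in the code list
  expect_true(all(strata %in% c(0L, 1:5, 7L, 9L, 11L, 13L, 15L, 17L, 18L)))
  expect_true(all(strata[w$regions$water] == 0))
  expect_true(all(strata[w$regions$human] == 7))    # nightlight jump, pressure
  expect_true(all(strata[w$regions$to_crop] == 2))  # forest -> cropland
  expect_true(all(strata[w$regions$to_forest] == 4))

  # unit pixels against the code table
  one <- function(nl, lc1, lc2, p) {
    zero <- matrix(0, 1, 1)
    pl <- list(footprint = matrix(p, 1, 1), population = zero,
               cropland = zero, nightlights = zero)
    classify_strata(matrix(nl, 1, 1), matrix(lc1, 1, 1), matrix(lc2, 1, 1),
                    pl, pl)[1, 1]
  }
  expect_equal(one(0.5, 130L, 130L, 5), 1L)    # within, stable, pressured
  expect_equal(one(0.2, 70L, 10L, 0), 2L)      # forest->cropland, no pressure
  expect_equal(one(0.2, 130L, 130L, 0), 18L)   # unlisted combination
  expect_equal(one(2, 130L, 130L, 5), 7L)
  expect_equal(one(-2, 10L, 70L, 5), 17L)
  expect_equal(one(0, 210L, 210L, 5), 0L)      # water mask
})

test_that("stratum statistics pool pixels across images", {
  strata <- matrix(1L, 4, 4)
  imgs <- list(matrix(0.5, 4, 4), matrix(0.5, 4, 4))
  st <- stratum_stats(strata, imgs)
  expect_equal(st$N_h, 16)
  expect_equal(st$S_h, 0)

  set.seed(3)
  strata2 <- matrix(sample(c(1L, 2L), 64, replace = TRUE), 8, 8)
  imgs2 <- list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
  st2 <- stratum_stats(strata2, imgs2)
  for (h in 1:2) {
    vals <- c(imgs2[[1]][strata2 == h], imgs2[[2]][strata2 == h])
    expect_equal(st2$S_h[st2$code == h], 100 * sd(vals))
  }
})

test_that("allocation is symmetric, exact-sum, and Neyman when unconstrained", {
  # identical strata share the total equally
  expect_equal(neyman_allocation(rep(1000, 5), rep(10, 5), 5 * 60, 50),
               rep(60L, 5))
  # with no minimum the allocation reduces to the pure Neyman closed form
  set.seed(7)
  for (rep in 1:20) {
    H <- sample(3:6, 1)
    N <- sample(100:10000, H)
    S <- runif(H, 1, 50)
    n <- sample(200:2000, 1)
    got <- neyman_allocation(N, S, n, n_min = 0)
    expect_equal(sum(got), n)
    exact <- N * S / sum(N * S) * n
    expect_true(all(abs(got - exact) <= 1))
  }
  expect_error(neyman_allocation(c(10, 10), c(1, 1), 100, n_min = 60),
               "infeasible")
})

test_that("allocation matches the exhaustive L1-optimal oracle", {
  set.seed(42)
  for (rep in 1:5) {
    N <- sample(50:500, 3)
    S <- runif(3, 1, 20)
    n_total <- 60
    n_min <- 5
    got <- neyman_allocation(N, S, n_total, n_min)
    exact <- n_min + N * S / sum(N * S) * (n_total - n_min * 3)
    expect_equal(sum(got), n_total)
    expect_equal(sum(abs(got - exact)),
                 oracle_allocation_objective(N, S, n_total, n_min),
                 tolerance = 1e-9)
  }
})

test_that("weights are inverse inclusion probabilities", {
  expect_equal(sampling_weights(100, 100), 1)
  expect_equal(round(sampling_weights(23517852472, 7738)), 3039268)
  expect_equal(round(sampling_weights(13870136, 204)), 67991)
  expect_error(sampling_weights(10, 0), "positive")
})

test_that("point draws honour the design and are seed-deterministic", {
  w <- tiny_world()
  nl <- w$pressure_end$nightlights - w$pressure_start$nightlights
  strata <- classify_strata(nl, w$lc_first, w$lc_last, w$pressure_start,
                            w$pressure_end)
  imgs <- list(w$potential[, , 1], w$potential[, , 7])
  design <- stratum_table(stratum_stats(strata, imgs), 60, 10)
  expect_equal(sum(design$n_h), 60)
  expect_true(all(design$n_h <= design$N_h))

  pts <- draw_points(strata, design, w$grid, seed = 5)
  expect_identical(pts, draw_points(strata, design, w$grid, seed = 5))
  got <- table(pts$stratum)
  expect_equal(as.integer(got[as.character(design$code)]), design$n_h)
  # points carry their stratum's pixels
  expect_true(all(strata[cbind(pts$row, pts$col)] == pts$stratum))

  # Horvitz-Thompson identity: summed weights recover the population
  expect_equal(sum(pts$weight), sum(design$N_h))

  # a stratum fully sampled returns every pixel
  full <- stratum_table(stratum_stats(strata, imgs), sum(design$N_h),
                        n_min = 1)
  pts_full <- draw_points(strata, full, w$grid, seed = 1)
  expect_equal(nrow(pts_full), sum(strata != 0))
})

test_that("the regression matrix has one row per point-month-percentile", {
  w <- clean_world()
  series <- aggregate_monthly(w)
  covs <- world_covariates(w)
  pts <- data.frame(location_id = sprintf("L%02d", 1:10),
                    row = 1:10, col = 3:12,
                    lat = w$grid$lat[1:10], lon = w$grid$lon[3:12],
                    stratum = 18L, weight = 2)
  m <- build_regression_matrix(pts, series, covs)
  expect_equal(nrow(m), 10 * 36 * 3)
  expect_equal(attr(m, "features"),
               c(covariate_registry(covs)$name, "prob"))
  # spot-check rows against direct raster lookups
  set.seed(2)
  for (r in sample(nrow(m), 5)) {
    row <- m[r, ]
    pt <- pts[pts$location_id == row$location_id, ]
    k <- which(series$months$year == row$year &
                 series$months$month == row$month)
    i <- which(series$probs == row$prob)
    expect_equal(row$target, series$values[pt$row, pt$col, k, i])
    expect_equal(row$elevation, w$layers$elevation[pt$row, pt$col])
    expect_equal(row$footprint,
                 w$pressure_start$footprint[pt$row, pt$col])
  }
})

test_that("missing targets drop rows; subsampling preserves proportions", {
  w <- tiny_world(missing_rate = 0.3)
  series <- aggregate_monthly(w)
  covs <- world_covariates(w)
  nl <- w$pressure_end$nightlights - w$pressure_start$nightlights
  strata <- classify_strata(nl, w$lc_first, w$lc_last, w$pressure_start,
                            w$pressure_end)
  design <- stratum_table(stratum_stats(strata, list(w$potential[, , 1])),
                          60, 10)
  pts <- draw_points(strata, design, w$grid, seed = 3)
  m <- build_regression_matrix(pts, series, covs)
  expect_lte(nrow(m), 60 * 36 * 3)
  expect_false(any(is.na(m$target)))

  # identity subsample
  expect_equal(nrow(subsample_matrix(m, nrow(m))), nrow(m))
  sub <- subsample_matrix(m, 1000, seed = 9)
  expect_equal(nrow(sub), 1000)
  expect_identical(subsample_matrix(m, 1000, seed = 9), sub)
  p_full <- table(m$stratum) / nrow(m)
  p_sub <- table(sub$stratum) / nrow(sub)
  expect_true(all(abs(p_sub - p_full[names(p_sub)]) <= 1.5 / 1000 +
                    1e-12 + abs(p_full[names(p_sub)]) * 0.02))
  # per-stratum counts deviate from exact shares by at most one row
  exact <- as.numeric(p_full) * 1000
  cnt <- as.integer(table(sub$stratum)[names(p_full)])
  expect_true(all(abs(cnt - exact) <= 1))

  sub_loc <- subsample_matrix(m, 2000, seed = 4, by_location = TRUE)
  expect_lt(length(unique(sub_loc$location_id)),
            length(unique(m$location_id)))
})
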