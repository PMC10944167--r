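# stratum codes keyed by (nightlight category, land-cover-change category,
# pressure category); combinations outside this list collapse to code 18
STRATUM_CODE_TABLE <- data.frame(
  nl = c("within", "within", "within", "within", "within",
         "up", "up", "up", "down", "down", "down"),
  lc = c(0L, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 0L, 1L, 2L),
  pr = c(100L, 0L, 100L, 0L, 100L, 100L, 100L, 100L, 100L, 100L, 100L),
  code = c(1L, 2L, 3L, 4L, 5L, 7L, 9L, 11L, 13L, 15L, 17L)
)

#' Classify pixels into sampling strata
#'
#' Builds the non-overlapping sampling strata from three per-pixel
#' categories: the nightlight change between epochs (within +/-1, above +1,
#' or below -1 nW cm-2 sr-1), the land-cover change category (0 none/other,
#' 1 forest/wetland to grassland/cropland, 2 the reverse) and the
#' human-pressure category (0 when all four pressure layers are zero at both
#' epochs, 100 otherwise). The eleven listed category combinations map to
#' stratum codes 1, 2, 3, 4, 5, 7, 9, 11, 13, 15, 17; any other combination
#' collapses to code 18, and the permanent water/ice mask gets code 0
#' (excluded from sampling).
#'
#' @param nightlight_change Matrix of nightlight differences (end - start).
#' @param lc_first,lc_last Integer land-cover matrices (level-4 codes).
#' @param pressure_start,pressure_end Lists of the four pressure-layer
#'   matrices at the start and end epochs.
#' @param water_mask Optional logical matrix; defaults to water/ice codes in
#'   either land-cover map.
#' @return Integer stratum-code matrix.
#' @export
classify_strata <- function(nightlight_change, lc_first, lc_last,
                            pressure_start, pressure_end,
                            water_mask = NULL) {
  d <- dim(nightlight_change)
  for (m in c(list(lc_first, lc_last), pressure_start, pressure_end))
    if (!all(dim(m) == d)) stop("grid mismatch between strata inputs",
                                call. = FALSE)
  nl <- matrix("within", d[1], d[2])
  nl[nightlight_change > 1] <- "up"
  nl[nightlight_change < -1] <- "down"

  lc <- matrix(0L, d[1], d[2])
  lc[lc_first %in% LC_FOREST_WETLAND & lc_last %in% LC_GRASS_CROP] <- 1L
  lc[lc_first %in% LC_GRASS_CROP & lc_last %in% LC_FOREST_WETLAND] <- 2L

  zero <- Reduce(`&`, lapply(c(pressure_start, pressure_end),
                             function(m) m == 0))
  pr <- ifelse(zero, 0L, 100L)

  key <- paste(nl, lc, pr)
  tab_key <- paste(STRATUM_CODE_TABLE$nl, STRATUM_CODE_TABLE$lc,
                   STRATUM_CODE_TABLE$pr)
  code <- STRATUM_CODE_TABLE$code[match(key, tab_key)]
  code[is.na(code)] <- 18L
  code <- matrix(code, d[1], d[2])
  if (is.null(water_mask))
    water_mask <- (lc_first %in% LC_WATER_ICE) | (lc_last %in% LC_WATER_ICE)
  code[water_mask] <- 0L
  code
}

#' Per-stratum population size and standard deviation
#'
#' `N_h` is the pixel count of each stratum; `S_h` is the standard deviation
#' pooled over all pixels of the stratum across all supplied FAPAR images
#' (the design uses quarterly images of the first and last year). Values are
#' reported on the conventional FAPAR x 100 scale.
#'
#' @param stratum_raster Integer stratum-code matrix (code 0 = masked).
#' @param fapar_images List of FAPAR matrices aligned with the strata.
#' @return Data frame `code`, `N_h`, `S_h` (one row per non-masked stratum).
#' @export
stratum_stats <- function(stratum_raster, fapar_images) {
  for (img in fapar_images)
    if (!all(dim(img) == dim(stratum_raster)))
      stop("grid mismatch between strata and FAPAR images", call. = FALSE)
  codes <- sort(unique(as.vector(stratum_raster)))
  codes <- codes[codes != 0]
  out <- lapply(codes, function(h) {
    sel <- stratum_raster == h
    vals <- unlist(lapply(fapar_images, function(img) img[sel]))
    vals <- vals[!is.na(vals)]
    data.frame(code = h, N_h = sum(sel),
               S_h = if (length(vals) > 1) 100 * stats::sd(vals) else 0)
  })
  do.call(rbind, out)
}

#' Neyman sample allocation with a per-stratum minimum
#'
#' Allocates a total sample of `n_total` points over strata: each stratum
#' receives the minimum `n_min`, and the remainder is distributed
#' proportionally to `N_h * S_h` (the Neyman-optimal share) with
#' nearest-integer rounding. If rounding breaks the exact total, a
#' largest-remainder correction adds or removes single points from the
#' strata whose rounded allocation deviates most from the exact share until
#' the total is met. With `n_min = 0` this reduces to pure Neyman
#' allocation.
#'
#' @param N_h Numeric vector of stratum population sizes (all > 0).
#' @param S_h Numeric vector of stratum standard deviations.
#' @param n_total Total sample size.
#' @param n_min Minimum sample size per stratum.
#' @return Integer vector of per-stratum sample sizes summing exactly to
#'   `n_total`.
#' @export
neyman_allocation <- function(N_h, S_h, n_total, n_min = 200) {
  stopifnot(length(N_h) == length(S_h), all(N_h > 0), all(S_h >= 0))
  H <- length(N_h)
  if (n_total < n_min * H)
    stop("infeasible design: n_total < n_min * number of strata",
         call. = FALSE)
  remainder <- n_total - n_min * H
  share <- N_h * S_h / sum(N_h * S_h) * remainder
  n_h <- round(share)
  diff <- remainder - sum(n_h)
  if (diff != 0) {
    resid <- share - n_h
    ord <- order(if (diff > 0) -resid else resid)
    take <- ord[seq_len(abs(diff))]
    n_h[take] <- n_h[take] + sign(diff)
  }
  as.integer(n_min + n_h)
}

#' Design weights from population and sample sizes
#'
#' The inverse inclusion probability `W_h = N_h / n_h`, kept at full
#' precision; round for display.
#'
#' @param N_h,n_h Numeric vectors (all `n_h > 0`).
#' @return Numeric vector of weights.
#' @export
sampling_weights <- function(N_h, n_h) {
  if (any(n_h <= 0)) stop("all sample sizes must be positive", call. = FALSE)
  N_h / n_h
}

#' Build a stratum table
#'
#' Combines [stratum_stats()], [neyman_allocation()] and
#' [sampling_weights()] into the per-stratum design table. Unlike the bare
#' allocation rule, the table enforces feasibility on small populations:
#' per-stratum minima are capped at the stratum population, and any
#' allocation exceeding its population is fixed at the population size with
#' the excess redistributed over the remaining strata.
#'
#' @param stats Data frame `code`, `N_h`, `S_h` (e.g. from
#'   [stratum_stats()]).
#' @param n_total Total sample size.
#' @param n_min Minimum per-stratum sample size.
#' @return Data frame of class `stratum_table` with columns `code`, `N_h`,
#'   `S_h`, `n_h`, `W_h` and attributes `n_total`, `H`.
#' @export
stratum_table <- function(stats, n_total, n_min = 200) {
  keep <- stats$N_h > 0
  stats <- stats[keep, , drop = FALSE]
  H <- nrow(stats)
  if (n_total > sum(stats$N_h))
    stop("n_total exceeds the total population", call. = FALSE)
  n_h <- rep(NA_integer_, H)
  fixed <- rep(FALSE, H)
  repeat {
    free <- which(!fixed)
    avail <- n_total - sum(n_h[fixed])
    base <- pmin(n_min, stats$N_h[free])
    if (avail < sum(base))
      stop("infeasible design: n_total too small for the per-stratum minima",
           call. = FALSE)
    share <- stats$N_h[free] * stats$S_h[free]
    share <- if (sum(share) > 0) share / sum(share) else
      rep(1 / length(free), length(free))
    exact <- share * (avail - sum(base))
    add <- round(exact)
    diff <- (avail - sum(base)) - sum(add)
    if (diff != 0) {
      resid <- exact - add
      ord <- order(if (diff > 0) -resid else resid)
      take <- ord[seq_len(abs(diff))]
      add[take] <- add[take] + sign(diff)
    }
    cand <- base + add
    over <- cand > stats$N_h[free]
    n_h[free] <- pmin(cand, stats$N_h[free])
    if (!any(over)) break
    fixed[free[over]] <- TRUE
  }
  stats$n_h <- as.integer(n_h)
  stats$W_h <- sampling_weights(stats$N_h, stats$n_h)
  attr(stats, "n_total") <- n_total
  attr(stats, "H") <- nrow(stats)
  class(stats) <- c("stratum_table", "data.frame")
  stats
}

#' @export
print.stratum_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$W_h <- round(y$W_h)
  cat(sprintf("Stratified design: %d strata, n = %d\n", attr(x, "H"),
              attr(x, "n_total")))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Stratum inventory of the reference global sampling design
#'
#' The twelve-stratum inventory of the global 250 m design: stratum codes
#' with population pixel counts and pooled standard deviations (FAPAR x 100)
#' of four quarterly FAPAR images of the first and last year. These are the
#' inputs to [neyman_allocation()] for the global 12,500-point design.
#'
#' @return Data frame `code`, `N_h`, `S_h`.
#' @export
global_stratum_inventory <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 7L, 9L, 11L, 13L, 15L, 17L, 18L),
    N_h = c(23517852472, 13870136, 174111464, 11797016, 163219120,
            529097288, 3092984, 2689992, 270521584, 1914936, 1278024,
            6670463000),
    S_h = c(72.02, 70.29, 60.17, 58.52, 59.30, 53.98, 50.65, 48.41,
            55.27, 52.32, 49.04, 76.44)
  )
}

#' Draw sample points within strata
#'
#' Simple random sampling without replacement within each stratum, at the
#' allocated per-stratum sizes. Deterministic for a fixed seed.
#'
#' @param stratum_raster Integer stratum-code matrix (0 = masked, never
#'   sampled).
#' @param table A [stratum_table()] (columns `code`, `n_h`, `W_h`).
#' @param grid The [fg_grid()] of the raster.
#' @param seed Integer seed.
#' @return Data frame `location_id`, `row`, `col`, `lat`, `lon`, `stratum`,
#'   `weight`.
#' @export
draw_points <- function(stratum_raster, table, grid, seed = 1) {
  set.seed(seed)
  R <- nrow(stratum_raster)
  pieces <- lapply(seq_len(nrow(table)), function(i) {
    h <- table$code[i]; n_h <- table$n_h[i]
    cells <- which(stratum_raster == h)
    if (n_h > length(cells))
      stop(sprintf("stratum %d: allocation %d exceeds population %d",
                   h, n_h, length(cells)), call. = FALSE)
    pick <- if (length(cells) == 1) cells else sort(sample(cells, n_h))
    data.frame(row = ((pick - 1) %% R) + 1, col = ((pick - 1) %/% R) + 1,
               stratum = h, weight = table$W_h[i])
  })
  pts <- do.call(rbind, pieces)
  pts$location_id <- sprintf("L%05d", seq_len(nrow(pts)))
  pts$lat <- grid$lat[pts$row]
  pts$lon <- grid$lon[pts$col]
  pts[, c("location_id", "row", "col", "lat", "lon", "stratum", "weight")]
}

#' Assemble the space-time regression matrix
#'
#' Overlays sample points with every month of the monthly percentile series
#' and every probability level, and attaches the covariate values in
#' registry order. One row per (point, month, probability level); rows with
#' a missing target are dropped. The probability level is recorded as a
#' numeric feature (`prob`) so a single model serves all percentiles.
#'
#' @param points A [draw_points()] result.
#' @param series A [aggregate_monthly()] result.
#' @param covariates A [assemble_covariates()] `covariate_set` spanning the
#'   same years.
#' @return Data frame of class `regression_matrix`: identifier columns
#'   (`location_id`, `lat`, `lon`, `year`, `month`, `prob`, `stratum`,
#'   `weight`), the `target` FAPAR and the feature columns; attribute
#'   `features` holds the feature-column names in model order.
#' @export
build_regression_matrix <- function(points, series, covariates) {
  reg <- covariate_registry(covariates)
  n_pts <- nrow(points)
  months <- series$months
  probs <- series$probs
  blocks <- vector("list", nrow(months) * length(probs))
  b <- 0
  ij <- cbind(points$row, points$col)
  for (k in seq_len(nrow(months))) {
    feat_k <- vapply(reg$name, function(nm)
      covset_layer_value(covariates, nm, months$year[k],
                         months$month[k])[ij],
      numeric(n_pts))
    for (i in seq_along(probs)) {
      tgt <- series$values[, , k, i][ij]
      df <- data.frame(
        location_id = points$location_id, lat = points$lat, lon = points$lon,
        year = months$year[k], month = months$month[k], prob = probs[i],
        stratum = points$stratum, weight = points$weight, target = tgt
      )
      df <- cbind(df, feat_k)
      b <- b + 1
      blocks[[b]] <- df[!is.na(tgt), , drop = FALSE]
    }
  }
  out <- do.call(rbind, blocks)
  if (nrow(out) == 0) stop("regression matrix is empty", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "features") <- c(reg$name, "prob")
  class(out) <- c("regression_matrix", "data.frame")
  out
}

#' Subsample a regression matrix
#'
#' Uniform row subsampling that preserves per-stratum row proportions to
#' within one row (largest-remainder apportionment of the per-stratum
#' counts). With `by_location = TRUE`, whole locations are sampled instead
#' and all their rows kept, targeting approximately `n_rows`.
#'
#' @param matrix A [build_regression_matrix()] result.
#' @param n_rows Target number of rows (`<=` current rows).
#' @param seed Integer seed.
#' @param by_location Sample whole locations instead of rows.
#' @return The subsampled `regression_matrix` (attributes preserved).
#' @export
subsample_matrix <- function(matrix, n_rows, seed = 1, by_location = FALSE) {
  if (n_rows > nrow(matrix)) stop("n_rows exceeds available rows",
                                  call. = FALSE)
  set.seed(seed)
  if (n_rows == nrow(matrix)) return(matrix)
  if (by_location) {
    locs <- unique(matrix$location_id)
    per_loc <- nrow(matrix) / length(locs)
    n_loc <- max(1, round(n_rows / per_loc))
    pick <- sample(locs, min(n_loc, length(locs)))
    keep <- which(matrix$location_id %in% pick)
  } else {
    strata <- split(seq_len(nrow(matrix)), matrix$stratum)
    exact <- vapply(strata, length, numeric(1)) / nrow(matrix) * n_rows
    cnt <- floor(exact)
    short <- n_rows - sum(cnt)
    if (short > 0) {
      ord <- order(exact - cnt, decreasing = TRUE)
      cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
    }
    keep <- sort(unlist(mapply(function(rows, m) {
      if (m >= length(rows)) rows else sample(rows, m)
    }, strata, cnt, SIMPLIFY = FALSE), use.names = FALSE))
  }
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "features") <- attr(matrix, "features")
  class(out) <- class(matrix)
  out
}
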