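#' Explainable-signal fraction of the generative model
#'
#' Monte-Carlo evaluation of the best achievable design-weighted R2 for a
#' regression matrix drawn from a synthetic world: the fraction of the
#' (weighted) target variance carried by the conditional expectation of the
#' monthly percentile given the covariates. For each row, the noiseless
#' window values implied by the generative rule are perturbed with fresh
#' observation noise `n_draws` times and the percentile recomputed; the
#' within-row variance of these draws is irreducible, everything else is
#' signal. This is a test oracle: no model output enters the computation.
#'
#' @param world A [generate_world()] result.
#' @param matrix A [build_regression_matrix()] result drawn from that world.
#' @param n_draws Monte-Carlo draws per row.
#' @param seed Integer seed.
#' @return Scalar in `[0, 1]`: `Var_w(E[y|x]) / (Var_w(E[y|x]) +
#'   mean_w(Var[y|x]))`.
#' @export
signal_fraction <- function(world, matrix, n_draws = 40, seed = 1) {
  stopifnot(inherits(world, "fapar_world"))
  set.seed(seed)
  loc <- grid_locate(world$grid, matrix$lat, matrix$lon)
  sdn <- world$config$noise_sd
  w <- matrix$weight
  mu <- rep(NA_real_, nrow(matrix))
  vv <- rep(NA_real_, nrow(matrix))
  groups <- split(seq_len(nrow(matrix)),
                  paste(matrix$year, matrix$month))
  for (g in groups) {
    yr <- matrix$year[g[1]]; mo <- matrix$month[g[1]]
    win <- month_window_indices(world$composite_index, yr, mo)
    base <- world_expected_composites(world, win)
    observed <- !is.na(world$composites[, , win, drop = FALSE])
    # pixel-wise draws, shared across the probability levels of the pixel
    keys <- paste(loc$row[g], loc$col[g])
    for (pix in unique(keys)) {
      rows <- g[keys == pix]
      r <- loc$row[rows[1]]; c <- loc$col[rows[1]]
      valid <- observed[r, c, ]
      if (!any(valid)) next
      b <- base[r, c, valid]
      probs <- matrix$prob[rows]
      draws <- vapply(seq_len(n_draws), function(d) {
        v <- clip01(b + stats::rnorm(length(b), 0, sdn))
        stats::quantile(v, probs, type = 7, names = FALSE)
      }, numeric(length(probs)))
      draws <- matrix(draws, nrow = length(probs))
      mu[rows] <- rowMeans(draws)
      vv[rows] <- apply(draws, 1, stats::var)
    }
  }
  ok <- !is.na(mu)
  wm <- function(v, w) sum(w * v) / sum(w)
  sig <- wm((mu[ok] - wm(mu[ok], w[ok]))^2, w[ok])
  noise <- wm(vv[ok], w[ok])
  sig / (sig + noise)
}
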