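#' Strict spatial cross-validation folds
#'
#' Partitions geographic locations (not rows) into `k` folds uniformly at
#' random, then assigns every row its location's fold: all space-time rows of
#' one location always share a fold, so validation rows are never seen
#' spatially during training.
#'
#' @param location_ids Vector of per-row location identifiers.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k) per row.
#' @export
spatial_folds <- function(location_ids, k = 5, seed = 1) {
  stopifnot(k >= 2)
  locs <- unique(location_ids)
  if (length(locs) < k)
    stop("fewer locations than folds", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(locs)
  fold_of <- rep(seq_len(k), length.out = length(locs))
  fold_of <- fold_of[order(order(shuffled))]  # fold per element of locs
  names(fold_of) <- locs
  unname(fold_of[as.character(location_ids)])
}

#' Design-weighted accuracy metrics
#'
#' Computes the weighted coefficient of determination, Lin's concordance
#' correlation coefficient, RMSE, MAE and bias, all with per-row design
#' weights (inverse inclusion probabilities). Weighted moments use the
#' weighted mean of the observations; with integer weights the report equals
#' the unweighted report on the correspondingly replicated vectors.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @param weights Positive per-row weights (default all 1).
#' @return An object of class `fapar_eval` with fields `r2`, `ccc`, `rmse`,
#'   `mae`, `bias`, `n`.
#' @export
weighted_eval <- function(pred, obs, weights = NULL) {
  stopifnot(length(pred) == length(obs))
  if (is.null(weights)) weights <- rep(1, length(obs))
  stopifnot(all(weights > 0))
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]; w <- weights[ok]
  wm <- function(v) sum(w * v) / sum(w)
  ob <- wm(obs); pb <- wm(pred)
  var_o <- wm((obs - ob)^2)
  if (var_o == 0) stop("observations have zero variance; R2 undefined",
                       call. = FALSE)
  var_p <- wm((pred - pb)^2)
  cov_op <- wm((obs - ob) * (pred - pb))
  structure(list(
    r2 = 1 - wm((obs - pred)^2) / var_o,
    ccc = 2 * cov_op / (var_o + var_p + (ob - pb)^2),
    rmse = sqrt(wm((obs - pred)^2)),
    mae = wm(abs(obs - pred)),
    bias = pb - ob,
    n = length(obs)
  ), class = "fapar_eval")
}

#' @export
print.fapar_eval <- function(x, ...) {
  cat(sprintf("R2 = %.4f  CCC = %.4f  RMSE = %.4f  MAE = %.4f  bias = %+.4f  (n = %d)\n",
              x$r2, x$ccc, x$rmse, x$mae, x$bias, x$n))
  invisible(x)
}

#' Default ensemble hyperparameters
#'
#' The selected hyperparameter set of the three base learners: extremely
#' randomized trees, gradient-boosted trees and the feed-forward network
#' (4 layers of 128 ReLU units, dropout 0.15, sigmoid output, 10 epochs,
#' batch 256, learning rate 0.0005). For the boosted trees, `learning_rate`
#' is the shrinkage actually applied (the `alpha` and `eta` entries record
#' the redundant search-space names and are not consumed).
#'
#' @return Nested list with components `et`, `xgb`, `ann` and `meta`.
#' @export
default_hyperparameters <- function() {
  list(
    et = list(n_trees = 44, max_depth = 92, max_features = 0.84,
              min_samples_split = 16, min_samples_leaf = 2),
    xgb = list(n_estimators = 81, max_depth = 50, learning_rate = 0.06,
               gamma = 0.05, reg_alpha = 0.007, reg_lambda = 0.12,
               colsample_bytree = 0.88, colsample_bylevel = 0.66,
               colsample_bynode = 0.47, alpha = 1.19, eta = 1.999),
    ann = list(epochs = 10, batch_size = 256, learning_rate = 5e-4,
               n_layers = 4, n_neurons = 128, dropout = 0.15),
    meta = list(stack_folds = 3)
  )
}

# search-space bounds for the tunable base learners
hyperparameter_space <- function() {
  list(
    et = list(n_trees = c(10, 100), max_depth = c(5, 100),
              max_features = c(0, 1), min_samples_split = c(2, 100),
              min_samples_leaf = c(1, 10)),
    xgb = list(n_estimators = c(10, 100), max_depth = c(3, 100),
               learning_rate = c(0, 0.2), gamma = c(0, 2),
               reg_alpha = c(0, 0.2), reg_lambda = c(0, 0.2),
               colsample_bytree = c(0, 1), colsample_bylevel = c(0, 1),
               colsample_bynode = c(0, 1))
  )
}

# ---- base learners ---------------------------------------------------------

fit_et <- function(x, y, weights, hp, seed) {
  p <- ncol(x)
  ranger::ranger(
    x = as.data.frame(x), y = y, case.weights = weights,
    num.trees = hp$n_trees, max.depth = hp$max_depth,
    mtry = max(1L, min(p, round(hp$max_features * p))),
    min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
    splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1,
    num.threads = 1, seed = seed
  )
}

predict_et <- function(model, x) {
  stats::predict(model, as.data.frame(x), num.threads = 1)$predictions
}

fit_xgb <- function(x, y, weights, hp, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, weight = weights)
  params <- list(
    max_depth = hp$max_depth, eta = hp$learning_rate, gamma = hp$gamma,
    alpha = hp$reg_alpha, lambda = hp$reg_lambda,
    colsample_bytree = hp$colsample_bytree,
    colsample_bylevel = hp$colsample_bylevel,
    colsample_bynode = hp$colsample_bynode,
    objective = "reg:squarederror", nthread = 1, seed = seed
  )
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$n_estimators, verbose = 0)
}

predict_xgb <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
}

fit_ann <- function(x, y, weights, hp, seed) {
  mlp_fit(x, y, weights = weights, epochs = hp$epochs,
          batch_size = hp$batch_size, learning_rate = hp$learning_rate,
          n_hidden = hp$n_layers, units = hp$n_neurons,
          dropout = hp$dropout, seed = seed)
}

predict_ann <- function(model, x) mlp_predict(model, x)

BASE_LEARNERS <- c("et", "xgb", "ann")

fit_base <- function(which, x, y, weights, hp, seed) {
  switch(which,
         et = fit_et(x, y, weights, hp$et, seed),
         xgb = fit_xgb(x, y, weights, hp$xgb, seed),
         ann = fit_ann(x, y, weights, hp$ann, seed))
}

predict_base <- function(which, model, x) {
  switch(which,
         et = predict_et(model, x),
         xgb = predict_xgb(model, x),
         ann = predict_ann(model, x))
}

# extract (x, y, weights, locations) from a regression_matrix
matrix_parts <- function(matrix) {
  features <- attr(matrix, "features")
  if (is.null(features)) stop("not a regression_matrix", call. = FALSE)
  list(x = as.matrix(as.data.frame(matrix)[, features, drop = FALSE]),
       y = matrix$target, weights = matrix$weight,
       locations = matrix$location_id, features = features)
}

#' Fit a stacked ensemble FAPAR model
#'
#' Fits the three base learners (extremely randomized trees via ranger,
#' gradient-boosted trees via xgboost and a feed-forward network) on all
#' rows, then combines them with a linear meta-learner. By default the
#' meta-learner is trained on out-of-fold base predictions (spatially
#' blocked inner folds) so it never sees in-sample base output; naive refit
#' stacking is available for comparison. Ensemble predictions are clipped to
#' the FAPAR domain `[0, 1]`.
#'
#' @param x A `regression_matrix` from [build_regression_matrix()], or a
#'   numeric feature matrix.
#' @param y,weights,locations Target, design weights and location ids; taken
#'   from `x` when it is a `regression_matrix`.
#' @param hyperparameters Nested list as from [default_hyperparameters()].
#' @param stacking `"oof"` (out-of-fold, default) or `"refit"`.
#' @param seed Integer seed for all base learners and fold draws.
#' @param ... Unused.
#' @return An object of class `fapar_eml` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()` and `plot()` methods.
#'   `coef()` returns the meta-learner's affine coefficients over the base
#'   predictions.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- clip01(0.3 + 0.4 * x[, 1] + rnorm(200, 0, 0.02))
#' hp <- default_hyperparameters()
#' hp$ann$epochs <- 2
#' fit <- fapar_eml(x, y, locations = rep(1:20, each = 10),
#'                  hyperparameters = hp, seed = 1)
#' coef(fit)
#' @export
fapar_eml <- function(x, ...) UseMethod("fapar_eml")

#' @rdname fapar_eml
#' @export
fapar_eml.regression_matrix <- function(x, ...) {
  parts <- matrix_parts(x)
  fapar_eml.default(parts$x, parts$y, weights = parts$weights,
                    locations = parts$locations, ...)
}

#' @rdname fapar_eml
#' @export
fapar_eml.default <- function(x, y, weights = NULL, locations = NULL,
                              hyperparameters = default_hyperparameters(),
                              stacking = c("oof", "refit"), seed = 1, ...) {
  stacking <- match.arg(stacking)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!all(is.finite(x))) {
    bad <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))]
    stop("non-finite feature values in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x)
  if (n == 0) stop("empty training matrix", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(locations)) locations <- seq_len(n)

  base <- lapply(BASE_LEARNERS, function(l)
    fit_base(l, x, y, weights, hyperparameters, seed))
  names(base) <- BASE_LEARNERS

  if (stacking == "oof") {
    kf <- hyperparameters$meta$stack_folds
    fold <- spatial_folds(locations, k = kf, seed = seed + 1000L)
    zp <- matrix(NA_real_, n, 3, dimnames = list(NULL, BASE_LEARNERS))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      for (l in BASE_LEARNERS) {
        m <- fit_base(l, x[tr, , drop = FALSE], y[tr], weights[tr],
                      hyperparameters, seed + f)
        zp[!tr, l] <- predict_base(l, m, x[!tr, , drop = FALSE])
      }
    }
  } else {
    zp <- vapply(BASE_LEARNERS, function(l)
      predict_base(l, base[[l]], x), numeric(n))
  }
  meta_fit <- stats::lm.wfit(cbind(1, zp), y, weights)
  meta <- stats::setNames(meta_fit$coefficients,
                          c("(Intercept)", BASE_LEARNERS))
  meta[is.na(meta)] <- 0

  obj <- structure(list(
    base = base, meta = meta, features = colnames(x),
    hyperparameters = hyperparameters, stacking = stacking, seed = seed,
    n = n
  ), class = "fapar_eml")
  ins <- predict(obj, x, deviance = FALSE)
  obj$fitted <- ins
  obj$y <- y
  obj$weights <- weights
  obj$train_eval <- tryCatch(weighted_eval(ins, y, weights),
                             error = function(e) NULL)
  obj
}

# coerce prediction input to the model's feature matrix
model_feature_matrix <- function(object, newdata) {
  if (inherits(newdata, "regression_matrix"))
    newdata <- as.data.frame(newdata)[, attr(newdata, "features"),
                                      drop = FALSE]
  nd <- as.matrix(newdata)
  if (is.null(colnames(nd))) {
    if (ncol(nd) != length(object$features))
      stop("newdata has ", ncol(nd), " columns; model expects ",
           length(object$features), call. = FALSE)
    colnames(nd) <- object$features
  }
  missing <- setdiff(object$features, colnames(nd))
  extra <- setdiff(colnames(nd), object$features)
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(extra) > 0)
    nd <- nd[, object$features, drop = FALSE]
  nd[, object$features, drop = FALSE]
}

#' Predict from a stacked ensemble, optionally with model deviance
#'
#' The ensemble prediction is the meta-learner's affine combination of the
#' three base predictions, clipped to `[0, 1]`. The model deviance is the
#' population standard deviation of the three base predictions per row — the
#' ensemble's per-pixel agreement measure.
#'
#' @param object A [fapar_eml()] fit.
#' @param newdata Feature matrix / data frame / `regression_matrix` with the
#'   model's features.
#' @param deviance If `TRUE`, return a data frame with columns `fit` and
#'   `deviance`; otherwise the prediction vector.
#' @param ... Unused.
#' @export
predict.fapar_eml <- function(object, newdata, deviance = FALSE, ...) {
  nd <- model_feature_matrix(object, newdata)
  zp <- vapply(BASE_LEARNERS, function(l)
    predict_base(l, object$base[[l]], nd), numeric(nrow(nd)))
  zp <- matrix(zp, nrow = nrow(nd))
  fit <- clip01(as.vector(cbind(1, zp) %*% object$meta))
  if (!deviance) return(fit)
  mu <- rowMeans(zp)
  dev <- sqrt(rowMeans((zp - mu)^2))
  data.frame(fit = fit, deviance = dev)
}

#' @export
fitted.fapar_eml <- function(object, ...) object$fitted

#' @export
residuals.fapar_eml <- function(object, ...) object$y - object$fitted

#' @export
coef.fapar_eml <- function(object, ...) object$meta

#' @export
print.fapar_eml <- function(x, ...) {
  cat(sprintf("<fapar_eml> stacked ensemble (%s stacking), %d rows, %d features\n",
              x$stacking, x$n, length(x$features)))
  cat("meta-learner: fit =",
      paste(sprintf("%+.3f*%s", x$meta[-1], names(x$meta)[-1]),
            collapse = " "),
      sprintf("%+.3f", x$meta[1]), "\n")
  invisible(x)
}

#' @export
summary.fapar_eml <- function(object, ...) {
  structure(list(meta = object$meta, train_eval = object$train_eval,
                 features = object$features, n = object$n,
                 stacking = object$stacking,
                 hyperparameters = object$hyperparameters),
            class = "summary.fapar_eml")
}

#' @export
print.summary.fapar_eml <- function(x, ...) {
  cat("Stacked ensemble FAPAR model\n")
  cat(sprintf("  rows: %d   features: %d   stacking: %s\n", x$n,
              length(x$features), x$stacking))
  cat("  meta coefficients:\n")
  print(round(x$meta, 4))
  cat("  in-sample weighted accuracy: ")
  print(x$train_eval)
  invisible(x)
}

#' @export
plot.fapar_eml <- function(x, ...) {
  graphics::smoothScatter(x$y, x$fitted, xlab = "observed FAPAR",
                          ylab = "ensemble fit", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Spatially blocked cross-validation of the ensemble
#'
#' Trains the full stacked ensemble on `k - 1` location folds and predicts
#' the held-out fold, so no held-out row's location ever contributes to its
#' own prediction. The pooled out-of-fold predictions give the headline
#' design-weighted accuracy report.
#'
#' @param x A `regression_matrix`, or a feature matrix (then give `y`,
#'   `weights`, `locations`).
#' @inheritParams fapar_eml.default
#' @param k Number of spatial folds (>= 2).
#' @return An object of class `fapar_cv`: `pooled` (a [weighted_eval()]
#'   report), `per_fold` (list of reports), and `predictions` (data frame
#'   `fold`, `pred`, `obs`, `weight`, `location_id` in row order).
#' @export
cross_validate <- function(x, y = NULL, weights = NULL, locations = NULL,
                           k = 5, hyperparameters = default_hyperparameters(),
                           stacking = c("oof", "refit"), seed = 1) {
  stacking <- match.arg(stacking)
  if (inherits(x, "regression_matrix")) {
    parts <- matrix_parts(x)
    x <- parts$x; y <- parts$y; weights <- parts$weights
    locations <- parts$locations
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(locations)) locations <- seq_len(n)
  fold <- spatial_folds(locations, k = k, seed = seed)
  pred <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    stopifnot(length(intersect(locations[tr], locations[!tr])) == 0)
    fit <- fapar_eml.default(x[tr, , drop = FALSE], y[tr],
                             weights = weights[tr],
                             locations = locations[tr],
                             hyperparameters = hyperparameters,
                             stacking = stacking, seed = seed + f)
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    per_fold[[f]] <- weighted_eval(pred[!tr], y[!tr], weights[!tr])
  }
  structure(list(
    pooled = weighted_eval(pred, y, weights),
    per_fold = per_fold, k = k,
    predictions = data.frame(fold = fold, pred = pred, obs = y,
                             weight = weights, location_id = locations)
  ), class = "fapar_cv")
}

#' @export
print.fapar_cv <- function(x, ...) {
  cat(sprintf("%d-fold strict spatial cross-validation, pooled: ", x$k))
  print(x$pooled)
  invisible(x)
}

# recursive-elimination feature ranking with a random-forest scorer;
# returns feature names from most to least important
rfe_ranking <- function(x, y, weights, n_trees, step, seed) {
  remaining <- colnames(x)
  ranking <- character(0)
  while (length(remaining) > 1) {
    rf <- ranger::ranger(x = as.data.frame(x[, remaining, drop = FALSE]),
                         y = y, case.weights = weights,
                         num.trees = n_trees, importance = "impurity",
                         num.threads = 1, seed = seed)
    imp <- sort(rf$variable.importance)  # ascending
    n_drop <- max(1L, floor(step * length(remaining)))
    drop <- names(imp)[seq_len(min(n_drop, length(remaining) - 1))]
    ranking <- c(drop[order(imp[drop], decreasing = TRUE)], ranking)
    remaining <- setdiff(remaining, drop)
  }
  c(remaining, ranking)
}

#' Recursive feature elimination with spatial cross-validation
#'
#' Ranks features by recursively eliminating the least important ones with a
#' random-forest scorer, chooses the cross-validation-optimal feature count
#' (spatially blocked folds), then produces a final elimination ranking on
#' all rows. The selected set is the final ranking truncated at the optimal
#' count.
#'
#' @param x Feature matrix with column names, or a `regression_matrix`.
#' @param y,weights,locations As in [fapar_eml()].
#' @param k Number of spatial folds.
#' @param n_trees Trees of the random-forest scorer.
#' @param step Fraction of remaining features dropped per elimination round.
#' @param seed Integer seed.
#' @return List with `optimal_n`, `ranking` (best first), `selected`, and
#'   `cv_scores` (data frame `n_features`, `r2`).
#' @export
rfe_select <- function(x, y = NULL, weights = NULL, locations = NULL,
                       k = 5, n_trees = 60, step = 0.2, seed = 1) {
  if (inherits(x, "regression_matrix")) {
    parts <- matrix_parts(x)
    x <- parts$x; y <- parts$y; weights <- parts$weights
    locations <- parts$locations
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two features", call. = FALSE)
  if (stats::var(y) == 0) stop("constant target; nothing to rank",
                               call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (is.null(locations)) locations <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  # candidate counts follow the elimination schedule
  counts <- ncol(x)
  while (counts[length(counts)] > 1) {
    cur <- counts[length(counts)]
    counts <- c(counts, cur - max(1L, floor(step * cur)))
  }
  counts <- sort(unique(counts))

  fold <- spatial_folds(locations, k = k, seed = seed)
  scores <- matrix(NA_real_, k, length(counts))
  for (f in seq_len(k)) {
    tr <- fold != f
    rk <- rfe_ranking(x[tr, , drop = FALSE], y[tr], weights[tr],
                      n_trees, step, seed + f)
    for (j in seq_along(counts)) {
      feats <- rk[seq_len(counts[j])]
      rf <- ranger::ranger(x = as.data.frame(x[tr, feats, drop = FALSE]),
                           y = y[tr], case.weights = weights[tr],
                           num.trees = n_trees, num.threads = 1,
                           seed = seed + f)
      pv <- stats::predict(rf, as.data.frame(x[!tr, feats, drop = FALSE]),
                           num.threads = 1)$predictions
      scores[f, j] <- weighted_eval(pv, y[!tr], weights[!tr])$r2
    }
  }
  mean_r2 <- colMeans(scores)
  optimal_n <- counts[which.max(mean_r2)]
  ranking <- rfe_ranking(x, y, weights, n_trees, step, seed)
  list(optimal_n = optimal_n, ranking = ranking,
       selected = ranking[seq_len(optimal_n)],
       cv_scores = data.frame(n_features = counts, r2 = mean_r2))
}

#' Hyperparameter search by successive halving
#'
#' Randomized successive-halving search over the declared bounds for one
#' base learner, scored by spatially blocked hold-out R2. Candidates start
#' on a small row budget; each rung doubles the budget (capped at
#' `max_resource` rows) and keeps the better half. With `enabled = FALSE`
#' the selected default set is returned unchanged.
#'
#' @param x Feature matrix or `regression_matrix`.
#' @param y,weights,locations As in [fapar_eml()].
#' @param learner `"et"` or `"xgb"` (the network's architecture is fixed).
#' @param n_candidates Number of sampled candidates (>= 1).
#' @param max_resource Maximum rows used to evaluate one candidate.
#' @param enabled If `FALSE`, skip the search and return defaults.
#' @param seed Integer seed.
#' @return List: the chosen hyperparameter set for `learner`, with attribute
#'   `"search"` holding the evaluated candidates when tuning ran.
#' @export
tune_hyperparameters <- function(x, y = NULL, weights = NULL,
                                 locations = NULL, learner = c("et", "xgb"),
                                 n_candidates = 8, max_resource = 20000,
                                 enabled = TRUE, seed = 1) {
  learner <- match.arg(learner)
  if (!enabled) return(default_hyperparameters()[[learner]])
  if (inherits(x, "regression_matrix")) {
    parts <- matrix_parts(x)
    x <- parts$x; y <- parts$y; weights <- parts$weights
    locations <- parts$locations
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (is.null(locations)) locations <- seq_len(nrow(x))
  space <- hyperparameter_space()[[learner]]
  if (length(space) == 0) stop("empty search space", call. = FALSE)
  set.seed(seed)
  draw <- function() {
    cand <- lapply(space, function(b) stats::runif(1, b[1], b[2]))
    for (nm in c("n_trees", "max_depth", "min_samples_split",
                 "min_samples_leaf", "n_estimators"))
      if (nm %in% names(cand)) cand[[nm]] <- max(space[[nm]][1],
                                                 round(cand[[nm]]))
    if (learner == "xgb") cand$learning_rate <- max(cand$learning_rate, 0.01)
    if (learner == "et") cand$max_features <- max(cand$max_features, 0.05)
    cand
  }
  candidates <- replicate(n_candidates, draw(), simplify = FALSE)

  fold <- spatial_folds(locations, k = 3, seed = seed)
  val <- fold == 1
  score_rows <- function(cand, n_rows) {
    tr <- which(!val)
    if (length(tr) > n_rows) tr <- sort(sample(tr, n_rows))
    hp <- default_hyperparameters()
    hp[[learner]] <- utils::modifyList(hp[[learner]], cand)
    m <- fit_base(learner, x[tr, , drop = FALSE], y[tr], weights[tr], hp,
                  seed)
    pv <- predict_base(learner, m, x[val, , drop = FALSE])
    weighted_eval(pv, y[val], weights[val])$r2
  }
  rung_rows <- max(500, ceiling(max_resource / 2^ceiling(log2(max(
    2, n_candidates)))))
  trace <- list()
  while (length(candidates) > 1) {
    r2 <- vapply(candidates, score_rows, numeric(1), n_rows = rung_rows)
    trace[[length(trace) + 1]] <- data.frame(rows = rung_rows, r2 = r2)
    keep <- order(r2, decreasing = TRUE)[seq_len(ceiling(
      length(candidates) / 2))]
    candidates <- candidates[keep]
    rung_rows <- min(max_resource, rung_rows * 2)
  }
  best <- candidates[[1]]
  out <- utils::modifyList(default_hyperparameters()[[learner]], best)
  if (length(trace) > 0) attr(out, "search") <- trace
  out
}
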