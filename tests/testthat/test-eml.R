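test_that("spatial folds partition locations evenly and disjointly", {
  locs <- rep(sprintf("L%02d", 1:10), each = 7)
  fold <- spatial_folds(locs, k = 5, seed = 3)
  expect_equal(length(fold), length(locs))
  per_loc <- tapply(fold, locs, function(f) length(unique(f)))
  expect_true(all(per_loc == 1))            # a location never splits
  sizes <- table(tapply(fold, locs, unique))
  expect_true(all(sizes == 2))              # 10 locations over 5 folds
  expect_error(spatial_folds(1:3, k = 5), "fewer locations")

  fold2 <- spatial_folds(rep(1:11, each = 3), k = 4, seed = 1)
  sizes2 <- table(tapply(fold2, rep(1:11, each = 3), unique))
  expect_lte(diff(range(sizes2)), 1)
})

test_that("weighted metrics satisfy their defining identities", {
  obs <- c(0.2, 0.4, 0.6, 0.8)
  perfect <- weighted_eval(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$bias, 0)

  # constant prediction at the weighted mean: CCC collapses to zero
  w <- c(1, 2, 3, 4)
  ob <- sum(w * obs) / sum(w)
  flat <- weighted_eval(rep(ob, 4), obs, w)
  expect_equal(flat$ccc, 0)
  expect_equal(flat$r2, 0)
  expect_equal(flat$bias, 0)

  expect_error(weighted_eval(obs, rep(0.5, 4)), "zero variance")
})

test_that("integer weights equal replication exactly", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 20
    obs <- runif(n); pred <- clip01(obs + rnorm(n, 0, 0.1))
    w <- sample(1:5, n, replace = TRUE)
    weighted <- weighted_eval(pred, obs, w)
    replicated <- weighted_eval(rep(pred, w), rep(obs, w))
    for (f in c("r2", "ccc", "rmse", "mae", "bias"))
      expect_equal(weighted[[f]], replicated[[f]], tolerance = 1e-12)
  }
})

test_that("concordance never exceeds the absolute correlation", {
  set.seed(11)
  for (rep in 1:20) {
    a <- rnorm(50); b <- 0.4 * a + rnorm(50)
    ev <- weighted_eval(clip01(plogis(b)), clip01(plogis(a)))
    r <- cor(clip01(plogis(a)), clip01(plogis(b)))
    expect_lte(abs(ev$ccc), abs(r) + 1e-12)
  }
})

test_that("model deviance is the population spread of the base learners", {
  toy <- toy_regression()
  hp <- fast_hyperparameters()
  fit <- fapar_eml(toy$x, toy$y, locations = toy$locations,
                   hyperparameters = hp, seed = 2)
  pr <- predict(fit, toy$x[1:20, ], deviance = TRUE)
  expect_true(all(pr$deviance >= 0))
  expect_true(all(pr$fit >= 0 & pr$fit <= 1))
  # frozen example: base predictions {0.2, 0.5, 0.8}
  expect_equal(sqrt(mean((c(0.2, 0.5, 0.8) - 0.5)^2)), sqrt(0.06))
  expect_equal(sqrt(0.06), 0.2449490, tolerance = 1e-6)
})

test_that("the ensemble is deterministic, clipped and learns a clean signal", {
  toy <- toy_regression(noise = 0.01)
  hp <- fast_hyperparameters()
  hp$ann$epochs <- 5
  f1 <- fapar_eml(toy$x, toy$y, locations = toy$locations,
                  hyperparameters = hp, seed = 7)
  f2 <- fapar_eml(toy$x, toy$y, locations = toy$locations,
                  hyperparameters = hp, seed = 7)
  expect_identical(predict(f1, toy$x), predict(f2, toy$x))
  expect_gt(f1$train_eval$r2, 0.9)

  # meta coefficients are an affine combination over three base learners
  expect_named(coef(f1), c("(Intercept)", "et", "xgb", "ann"))

  # adversarial inputs cannot escape [0, 1]
  crazy <- matrix(c(1e6, -1e6, 0, 1e3), 1, 4,
                  dimnames = list(NULL, colnames(toy$x)))
  expect_true(predict(f1, crazy) >= 0 && predict(f1, crazy) <= 1)

  # constant target: predictions collapse to it
  yc <- rep(0.5, length(toy$y))
  fc <- fapar_eml(toy$x, yc, locations = toy$locations,
                  hyperparameters = hp, seed = 7)
  expect_lt(max(abs(predict(fc, toy$x) - 0.5)), 0.02)

  # feature-name mismatches are reported
  bad <- toy$x[1:5, 1:3]
  expect_error(predict(f1, bad), "missing features")
  xna <- toy$x; xna[1, 1] <- NA
  expect_error(fapar_eml(xna, toy$y, hyperparameters = hp), "non-finite")
})

test_that("cross-validation never trains on a held-out location", {
  toy <- toy_regression(n_loc = 20, per_loc = 6)
  cv <- cross_validate(toy$x, toy$y, locations = toy$locations, k = 4,
                       hyperparameters = fast_hyperparameters(), seed = 1)
  expect_equal(nrow(cv$predictions), length(toy$y))
  expect_false(any(is.na(cv$predictions$pred)))
  # fold labels constant within location
  per_loc <- tapply(cv$predictions$fold, cv$predictions$location_id,
                    function(f) length(unique(f)))
  expect_true(all(per_loc == 1))
  expect_s3_class(cv$pooled, "fapar_eval")
  expect_length(cv$per_fold, 4)
})

test_that("recursive elimination recovers planted features", {
  set.seed(21)
  n <- 800
  x <- matrix(runif(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- clip01(0.2 + 0.5 * x[, 2] + 0.3 * x[, 5] - 0.25 * x[, 7] +
                rnorm(n, 0, 0.02))
  locs <- rep(1:80, each = 10)
  sel <- rfe_select(x, y, locations = locs, k = 3, n_trees = 40, seed = 2)
  expect_true(all(c("f2", "f5", "f7") %in%
                    sel$ranking[seq_len(max(3, sel$optimal_n))]))
  expect_true(all(c("f2", "f5", "f7") %in% sel$selected))
  expect_gte(sel$optimal_n, 1)

  # a duplicated informative column must not break the ranking
  x2 <- cbind(x, f2_copy = x[, 2])
  sel2 <- rfe_select(x2, y, locations = locs, k = 3, n_trees = 40, seed = 2)
  expect_true(any(c("f2", "f2_copy") %in% sel2$selected))

  expect_error(rfe_select(x, rep(0.5, n), locations = locs), "constant")
  expect_error(rfe_select(x[, 1, drop = FALSE], y), "two features")
})

test_that("hyperparameter search respects bounds, defaults and budgets", {
  # disabled tuning returns the selected defaults
  off <- tune_hyperparameters(NULL, learner = "et", enabled = FALSE)
  expect_equal(off$n_trees, 44)
  expect_equal(off$max_depth, 92)
  off2 <- tune_hyperparameters(NULL, learner = "xgb", enabled = FALSE)
  expect_equal(off2$n_estimators, 81)
  expect_equal(off2$learning_rate, 0.06)

  toy <- toy_regression(n_loc = 15, per_loc = 8)
  # single-candidate budget returns that candidate
  one <- tune_hyperparameters(toy$x, toy$y, locations = toy$locations,
                              learner = "et", n_candidates = 1,
                              max_resource = 500, seed = 3)
  expect_null(attr(one, "search"))
  space <- fapargap:::hyperparameter_space()$et
  got <- tune_hyperparameters(toy$x, toy$y, locations = toy$locations,
                              learner = "et", n_candidates = 4,
                              max_resource = 500, seed = 3)
  for (nm in names(space)) {
    expect_gte(got[[nm]], space[[nm]][1])
    expect_lte(got[[nm]], space[[nm]][2])
  }
  expect_identical(
    got,
    tune_hyperparameters(toy$x, toy$y, locations = toy$locations,
                         learner = "et", n_candidates = 4,
                         max_resource = 500, seed = 3))
})
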