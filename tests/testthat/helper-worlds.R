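# shared fixtures: small worlds and fast hyperparameter sets

tiny_world <- function(..., seed = 11) {
  generate_world(world_config(grid_rows = 16, grid_cols = 16, n_years = 3,
                              seed = seed, ...))
}

clean_world <- function(..., seed = 11) {
  # all perturbations off: composites equal the true potential
  tiny_world(suppression_delta = 0, trend_slope = 0, noise_sd = 0,
             missing_rate = 0, seed = seed, ...)
}

fast_hyperparameters <- function() {
  hp <- default_hyperparameters()
  hp$et$n_trees <- 10
  hp$xgb$n_estimators <- 15
  hp$ann$epochs <- 2
  hp$meta$stack_folds <- 2
  hp
}

# small regression problem with location structure
toy_regression <- function(n_loc = 30, per_loc = 10, p = 4, noise = 0.02,
                           seed = 5) {
  set.seed(seed)
  n <- n_loc * per_loc
  x <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- clip01(0.2 + 0.4 * x[, 1] + 0.2 * x[, 2] + rnorm(n, 0, noise))
  list(x = x, y = y, locations = rep(seq_len(n_loc), each = per_loc))
}
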