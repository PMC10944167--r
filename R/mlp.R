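# Small feed-forward regression network used as the third base learner:
# ReLU hidden layers with inverted dropout, sigmoid output, Adam on a
# (weighted) squared-error loss. Inputs are standardized internally.
# Deterministic for a fixed seed; single-threaded BLAS matrix ops.

mlp_fit <- function(x, y, weights = NULL, epochs = 10, batch_size = 256,
                    learning_rate = 5e-4, n_hidden = 4, units = 128,
                    dropout = 0.15, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  w_norm <- weights / mean(weights)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  set.seed(seed)
  sizes <- c(p, rep(units, n_hidden), 1L)
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(m) m * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  L <- length(W)

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      m_b <- length(idx)
      A <- xs[idx, , drop = FALSE]
      acts <- vector("list", L + 1); acts[[1]] <- A
      masks <- vector("list", L)
      for (l in seq_len(L - 1)) {
        Z <- A %*% W[[l]]
        Z <- Z + rep(b[[l]], each = m_b)
        A <- Z * (Z > 0)
        if (dropout > 0) {
          keep <- matrix(stats::runif(length(A)) >= dropout,
                         nrow(A), ncol(A))
          A <- A * keep / (1 - dropout)
          masks[[l]] <- keep
        }
        acts[[l + 1]] <- A
      }
      Zo <- A %*% W[[L]] + rep(b[[L]], each = m_b)
      yhat <- stats::plogis(Zo)

      wb <- w_norm[idx]
      delta <- (yhat - y[idx]) * yhat * (1 - yhat) * (2 * wb / m_b)
      grads_W <- vector("list", L); grads_b <- vector("list", L)
      for (l in L:1) {
        grads_W[[l]] <- crossprod(acts[[l]], delta)
        grads_b[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          if (dropout > 0) delta <- delta * masks[[l - 1]] / (1 - dropout)
          delta <- delta * (acts[[l]] > 0)
        }
      }
      step <- step + 1
      corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * grads_W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * grads_W[[l]]^2
        W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * grads_b[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * grads_b[[l]]^2
        b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  }
  structure(list(W = W, b = b, center = center, scale = scale,
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate,
                               n_hidden = n_hidden, units = units,
                               dropout = dropout, seed = seed)),
            class = "fg_mlp")
}

mlp_predict <- function(model, x) {
  A <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  L <- length(model$W)
  for (l in seq_len(L - 1)) {
    Z <- A %*% model$W[[l]]
    Z <- Z + rep(model$b[[l]], each = nrow(Z))
    A <- Z * (Z > 0)
  }
  as.vector(stats::plogis(A %*% model$W[[L]] +
                            rep(model$b[[L]], each = nrow(A))))
}
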