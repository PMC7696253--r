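# Shared test helpers.

# one-input, two-rule, order-0 model with MFs (0,0,1) and (0,1,1) and
# consequents c(c1, c2) -- small enough to verify by hand
hand_model <- function(consequents = c(0, 1)) {
  m <- build_anfis(anfis_config(n_inputs = 1, mfs_per_input = 2,
                                consequent_order = 0))
  m$consequents <- matrix(consequents, 2, 1)
  m
}

# independent least-squares oracle: explicit normal equations on the
# layer-4 design matrix, assembled from first principles (memberships and
# products recomputed here, not through the package's weight code)
normal_equations_fit <- function(model, X, y, ridge = 0) {
  tri <- function(x, a, b, c) {
    mu <- numeric(length(x))
    if (b > a) { i <- x >= a & x < b; mu[i] <- (x[i] - a) / (b - a) }
    if (c > b) { i <- x > b & x <= c; mu[i] <- (c - x[i]) / (c - b) }
    mu[x == b] <- 1
    mu
  }
  n <- nrow(X); R <- nrow(model$rules); d <- model$config$n_inputs
  W <- matrix(1, n, R)
  for (r in seq_len(R)) {
    for (j in seq_len(d)) {
      mf <- model$premise[[j]][[model$rules[r, j]]]
      W[, r] <- W[, r] * tri(X[, j], mf$a, mf$b, mf$c)
    }
  }
  Wn <- W / rowSums(W)
  if (model$config$consequent_order == 1) {
    A <- do.call(cbind, lapply(seq_len(R), function(r) {
      cbind(Wn[, r] * X, Wn[, r])
    }))
  } else {
    A <- Wn
  }
  solve(t(A) %*% A + ridge * diag(ncol(A)), t(A) %*% y)
}

# noiseless samples of the normalized multiplicative magnitude surface on
# the continuous unit cube
magnitude_surface_sample <- function(n, seed) {
  set.seed(seed)
  X <- matrix(stats::runif(4 * n), n, 4)
  y <- (apply(1 + 8 * X, 1, prod) - 1) / 6560
  list(X = X, y = y)
}
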