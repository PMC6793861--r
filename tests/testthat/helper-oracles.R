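# Independent oracles and small fixture builders shared across tests.

make_normal_pm <- function(n_vox, n_stim, seed, normalise = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(n_vox * n_stim), n_vox, n_stim)
  pm <- pattern_matrix(m)
  if (normalise) znormalise(pm) else pm
}

# The penalised ridge objective of Eq-style form ||MX - Y||_F^2 + l ||M||_F^2.
ridge_objective <- function(M, X, Y, lambda) {
  sum((M %*% unclass(X) - unclass(Y))^2) + lambda * sum(M^2)
}

# Explicit leave-one-stimulus-out loop: refit with stimulus i held out and
# accumulate the squared prediction residual on it.
loo_explicit <- function(X, Y, alpha) {
  X <- unclass(X); Y <- unclass(Y)
  total <- 0
  for (i in seq_len(ncol(X))) {
    That <- estimate_transform(X[, -i, drop = FALSE], Y[, -i, drop = FALSE],
                               alpha)
    total <- total + sum((That %*% X[, i] - Y[, i])^2)
  }
  total
}

# Brute-force 2-D grid search oracle for the exponential decay fit.
grid_exp_fit <- function(xs, ys, a_range, b_range, n = 201) {
  as_grid <- seq(a_range[1], a_range[2], length.out = n)
  bs_grid <- seq(b_range[1], b_range[2], length.out = n)
  best <- c(a = NA, b = NA, sse = Inf)
  for (b in bs_grid) {
    e <- exp(b * xs)
    sse <- vapply(as_grid, function(a) sum((ys - a * e)^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < best["sse"]) best <- c(a = as_grid[i], b = b, sse = sse[i])
  }
  best
}

# Two-sided Fisher p-value by direct hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum <- function(counts) {
  m <- counts[1, 1] + counts[1, 2]   # class-1 total
  n <- counts[2, 1] + counts[2, 2]
  k <- counts[1, 1] + counts[2, 1]   # column-1 total
  x <- counts[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}
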