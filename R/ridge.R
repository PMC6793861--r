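#' Default candidate grid for the regularisation parameter
#'
#' Log-spaced candidates spanning `[1e-2, 1e4]`, the envelope within which
#' selected optima are expected to fall for z-normalised pattern data. The
#' selection functions warn when the argmin lands on an endpoint, which
#' signals the grid should be widened.
#'
#' @param lower,upper Positive range limits.
#' @param n Number of candidates (log-spaced).
#' @return Numeric vector of length `n`.
#' @export
default_lambda_grid <- function(lower = 1e-2, upper = 1e4, n = 61) {
  stopifnot(lower > 0, upper > lower, n >= 2)
  10^seq(log10(lower), log10(upper), length.out = n)
}

# Thin SVD of the input patterns, reused across all lambda-grid work.
# X = U diag(d) V' with numerically zero singular values dropped.
ridge_svd <- function(X) {
  s <- svd(unclass(X))
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1L]
  r <- sum(s$d > tol)
  list(u = s$u[, seq_len(r), drop = FALSE], d = s$d[seq_len(r)],
       v = s$v[, seq_len(r), drop = FALSE], rank = r)
}

check_conformable <- function(X, Y) {
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must share the stimulus dimension (columns): ",
         ncol(X), " vs ", ncol(Y), call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(colnames(Y)) &&
      !identical(colnames(X), colnames(Y))) {
    stop("stimulus identifiers of X and Y do not match", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ridge estimate of the voxel-to-voxel transformation
#'
#' Solves `argmin_M ||M X - Y||_F^2 + lambda ||M||_F^2`, whose unique
#' solution is `Y X' (X X' + lambda I)^{-1}`. The solve goes through a
#' Cholesky factorisation of the (symmetric positive-definite) regularised
#' Gram matrix rather than an explicit inverse. `lambda = 0` is accepted
#' only when `X X'` is invertible.
#'
#' @param X Input-region patterns (`N_X` voxels x `N_s` stimuli), normalised.
#' @param Y Output-region patterns (`N_Y` voxels x `N_s` stimuli), normalised.
#' @param lambda Non-negative regularisation weight.
#' @return Numeric matrix `N_Y x N_X` mapping input patterns to predicted
#'   output patterns.
#' @examples
#' X <- znormalise(matrix(rnorm(6 * 5), 6, 5))
#' Y <- znormalise(matrix(rnorm(4 * 5), 4, 5))
#' That <- estimate_transform(X, Y, lambda = 1)
#' @export
estimate_transform <- function(X, Y, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  check_conformable(X, Y)
  X <- unclass(X); Y <- unclass(Y)
  A <- tcrossprod(X) + diag(lambda, nrow(X))
  R <- tryCatch(chol(A), error = function(e) {
    stop("X X' + lambda I is singular (lambda = 0 with rank-deficient X?)",
         call. = FALSE)
  })
  # T' = A^{-1} X Y'
  Tt <- backsolve(R, forwardsolve(R, X %*% t(Y), upper.tri = TRUE,
                                  transpose = TRUE))
  t(Tt)
}

# Ridge estimate from a precomputed SVD of X: T = Y V diag(d/(d^2+lambda)) U'.
estimate_transform_svd <- function(sv, Y, lambda) {
  w <- sv$d / (sv$d^2 + lambda)
  (unclass(Y) %*% sweep(sv$v, 2L, w, `*`)) %*% t(sv$u)
}

# Leverage-corrected leave-one-stimulus-out residuals for one candidate
# alpha, from a precomputed SVD of X and precomputed crossprod(V, t(Y)).
# Returns the summed objective and the per-stimulus squared residuals.
loocv_components <- function(sv, Yt, VtYt, alpha) {
  w <- sv$d^2 / (sv$d^2 + alpha)
  h <- as.vector((sv$v^2) %*% w)
  if (any(h >= 1 - 1e-12)) {
    stop("leverage h_ii >= 1: alpha too small for the rank of X",
         call. = FALSE)
  }
  resid <- Yt - sv$v %*% (VtYt * w)   # (I - H(alpha)) Y'
  per_stim <- rowSums(resid^2) / (1 - h)^2
  list(objective = sum(per_stim), per_stimulus = per_stim, leverage = h)
}

#' Leave-one-stimulus-out objective via the hat-matrix shortcut
#'
#' Computes `Lambda(alpha) = || A(alpha) (I - H(alpha)) Y' ||_F^2`, where
#' `H(alpha) = X'(XX' + alpha I)^{-1} X` is the stimulus-space hat matrix
#' and `A(alpha)` the diagonal of leverage corrections `1/(1 - h_ii)`. This
#' equals the sum over stimuli of the squared prediction residual of a ridge
#' fit trained with that stimulus held out — without refitting — and is the
#' quantity whose grid argmin defines the selected regularisation parameter.
#' (The identity inside the norm is the `N_s x N_s` one, the only
#' dimensionally consistent reading.)
#'
#' @inheritParams estimate_transform
#' @param alpha Positive candidate regularisation weight.
#' @return Non-negative scalar, the summed leverage-corrected squared
#'   leave-one-out residuals.
#' @export
loocv_objective <- function(X, Y, alpha) {
  check_conformable(X, Y)
  sv <- ridge_svd(X)
  Yt <- t(unclass(Y))
  loocv_components(sv, Yt, crossprod(sv$v, Yt), alpha)$objective
}

#' Select the ridge parameter by leave-one-stimulus-out cross-validation
#'
#' Evaluates the shortcut objective on a candidate grid and returns the
#' argmin together with the full curve. Exact ties break towards the
#' smallest candidate (less shrinkage at equal cross-validation error); an
#' argmin on a grid endpoint raises a warning since the true optimum may lie
#' outside the searched range.
#'
#' @inheritParams estimate_transform
#' @param grid Positive candidate values; default [default_lambda_grid()].
#' @return A list with `lambda` (selected value), `grid`, and `curve`
#'   (the objective per candidate).
#' @export
select_lambda <- function(X, Y, grid = default_lambda_grid()) {
  stopifnot(length(grid) >= 2L, all(grid > 0))
  check_conformable(X, Y)
  grid <- sort(grid)
  sv <- ridge_svd(X)
  Yt <- t(unclass(Y))
  VtYt <- crossprod(sv$v, Yt)
  curve <- vapply(grid, function(a)
    loocv_components(sv, Yt, VtYt, a)$objective, numeric(1L))
  idx <- which.min(curve)   # first minimum = smallest lambda among ties
  if (idx == 1L || idx == length(grid)) {
    warning("selected lambda is a grid endpoint (", signif(grid[idx], 4),
            "); consider widening the grid", call. = FALSE)
  }
  list(lambda = grid[idx], grid = grid, curve = curve)
}

#' Select the ridge parameter by k-fold cross-validation
#'
#' Alternative to [select_lambda()]: stimuli are partitioned into `k`
#' seeded folds; for each candidate the summed held-out squared residuals
#' over the folds are accumulated and the grid argmin returned. `k` equal to
#' the number of stimuli reproduces the leave-one-out selection.
#'
#' @inheritParams select_lambda
#' @param k Number of folds, `2 <= k <= N_s`.
#' @param seed Integer seed for the fold assignment.
#' @return A list with `lambda`, `grid`, `curve`, and `folds` (the fold
#'   index per stimulus).
#' @export
select_lambda_kfold <- function(X, Y, grid = default_lambda_grid(), k = 10,
                                seed = 1L) {
  check_conformable(X, Y)
  n_s <- ncol(X)
  if (k > n_s) stop("k = ", k, " exceeds the number of stimuli (", n_s, ")",
                    call. = FALSE)
  stopifnot(k >= 2L, length(grid) >= 2L, all(grid > 0))
  grid <- sort(grid)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n_s)))
  X <- unclass(X); Y <- unclass(Y)
  curve <- numeric(length(grid))
  for (f in seq_len(k)) {
    te <- folds == f
    sv <- ridge_svd(X[, !te, drop = FALSE])
    Ytr <- Y[, !te, drop = FALSE]
    for (g in seq_along(grid)) {
      That <- estimate_transform_svd(sv, Ytr, grid[g])
      curve[g] <- curve[g] +
        sum((That %*% X[, te, drop = FALSE] - Y[, te, drop = FALSE])^2)
    }
  }
  idx <- which.min(curve)
  if (idx == 1L || idx == length(grid)) {
    warning("selected lambda is a grid endpoint (", signif(grid[idx], 4),
            "); consider widening the grid", call. = FALSE)
  }
  list(lambda = grid[idx], grid = grid, curve = curve, folds = folds)
}

#' Cross-validated percentage goodness-of-fit
#'
#' `GOF = 100 (1 - Lambda(lambda) / (N_Y N_s))`: the percentage of
#' output-pattern variance explained by the ridge mapping under
#' leave-one-stimulus-out cross-validation, exploiting that each normalised
#' output column has squared norm `N_Y`. 100 is a perfect linear mapping;
#' values near 0 indicate no (linear) dependency. Negative values are
#' reported as-is — a cross-validated fit genuinely worse than predicting
#' zero — rather than clipped.
#'
#' @inheritParams estimate_transform
#' @param lambda Positive regularisation weight (typically the selected one).
#' @return A list with `gof_percent`, `per_stimulus_gof` (length `N_s`,
#'   `100 (1 - r_i / N_Y)`), and `per_stimulus_sq_residual`.
#' @export
compute_gof <- function(X, Y, lambda) {
  check_conformable(X, Y)
  if (!is_normalised(Y)) {
    warning("Y is not flagged as z-normalised; GOF assumes column norms N_Y",
            call. = FALSE)
  }
  sv <- ridge_svd(X)
  Yt <- t(unclass(Y))
  comp <- loocv_components(sv, Yt, crossprod(sv$v, Yt), lambda)
  n_y <- nrow(Y)
  per_stim <- setNames(comp$per_stimulus, colnames(Y))
  list(gof_percent = 100 * (1 - comp$objective / (n_y * ncol(Y))),
       per_stimulus_gof = 100 * (1 - per_stim / n_y),
       per_stimulus_sq_residual = per_stim)
}

#' Stimulus-space hat matrix diagnostics
#'
#' Returns `H(alpha) = X'(XX' + alpha I)^{-1} X`, its leverages `h_ii`, and
#' the leverage-correction weights `1/(1 - h_ii)` used by the
#' leave-one-out shortcut.
#'
#' @inheritParams loocv_objective
#' @return List with `H` (`N_s x N_s`, symmetric), `leverage`, `weights`.
#' @export
hat_diagnostics <- function(X, alpha) {
  sv <- ridge_svd(X)
  w <- sv$d^2 / (sv$d^2 + alpha)
  H <- sv$v %*% (t(sv$v) * w)
  h <- diag(H)
  if (any(h >= 1 - 1e-12)) {
    stop("leverage h_ii >= 1: alpha too small for the rank of X",
         call. = FALSE)
  }
  list(H = H, leverage = h, weights = 1 / (1 - h))
}

#' Fit a pattern transformation with cross-validated regularisation
#'
#' One-stop estimation: selects the ridge parameter on a candidate grid
#' (leave-one-stimulus-out by default, k-fold optionally), estimates the
#' transformation at the selected value, and computes the cross-validated
#' goodness-of-fit. Inputs are z-normalised first unless already flagged.
#'
#' @inheritParams estimate_transform
#' @param grid Candidate regularisation values.
#' @param method `"loocv"` (default) or `"kfold"`.
#' @param k,seed Fold count and seed, used when `method = "kfold"`.
#' @return A `transform_fit` object: list with elements `t_hat`, `lambda`,
#'   `gof_percent`, `per_stimulus_gof`, `per_stimulus_sq_residual`,
#'   `lambda_grid`, `cv_curve`, `method`, and the problem dimensions.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_region_pair(n_in = 20, n_out = 15, n_stimuli = 24,
#'                             sparsity = 80, gamma = 0.2, seed = 7)
#' fit <- fit_transform(sim$x[[1]], sim$y[[1]])
#' glance(fit)
#' @export
fit_transform <- function(X, Y, grid = default_lambda_grid(),
                          method = c("loocv", "kfold"), k = 10, seed = 1L) {
  method <- match.arg(method)
  if (!is_normalised(X)) X <- znormalise(X)
  if (!is_normalised(Y)) Y <- znormalise(Y)
  check_conformable(X, Y)
  sel <- if (method == "loocv") select_lambda(X, Y, grid)
         else select_lambda_kfold(X, Y, grid, k = k, seed = seed)
  gof <- compute_gof(X, Y, sel$lambda)
  structure(list(
    t_hat = estimate_transform(X, Y, sel$lambda),
    lambda = sel$lambda,
    gof_percent = gof$gof_percent,
    per_stimulus_gof = gof$per_stimulus_gof,
    per_stimulus_sq_residual = gof$per_stimulus_sq_residual,
    stimulus_ids = colnames(X),
    lambda_grid = sel$grid,
    cv_curve = sel$curve,
    method = method,
    n_in = nrow(X), n_out = nrow(Y), n_stimuli = ncol(X)
  ), class = "transform_fit")
}

#' @export
print.transform_fit <- function(x, ...) {
  cat(sprintf(
    "<transform_fit> %d -> %d voxels, %d stimuli\n  lambda = %.4g (%s), GOF = %.2f%%\n",
    x$n_in, x$n_out, x$n_stimuli, x$lambda, x$method, x$gof_percent))
  invisible(x)
}
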