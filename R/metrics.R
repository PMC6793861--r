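#' Density curve of a thresholded transformation
#'
#' The estimated transformation is first normalised by its maximum absolute
#' entry; the density `d(P)` is then the fraction of entries whose absolute
#' value strictly exceeds the threshold `P`. For a matrix with no exact
#' zeros, `d(0) = 1` and `d(1) = 0`; `d` is non-increasing in `P`. Because
#' the inequality is strict, exact zeros never count, so `d(0) < 1` flags
#' their presence. The decay rate of this curve is the sparsity signature:
#' ridge estimates of genuinely sparse mappings never contain exact zeros,
#' but their density drops much faster.
#'
#' @param t_hat Numeric matrix, the estimated transformation (not all zero).
#' @param thresholds Sorted thresholds in `[0, 1]`; default 101 evenly
#'   spaced points.
#' @return A `density_curve` tibble with columns `threshold`, `density`.
#' @examples
#' density_curve(diag(4))
#' @export
density_curve <- function(t_hat, thresholds = seq(0, 1, by = 0.01)) {
  t_hat <- unclass(as.matrix(t_hat))
  stopifnot(all(is.finite(t_hat)))
  if (all(t_hat == 0)) stop("all-zero matrix: max-abs normalisation undefined",
                            call. = FALSE)
  if (is.unsorted(thresholds) || any(thresholds < 0) || any(thresholds > 1)) {
    stop("thresholds must be sorted within [0, 1]", call. = FALSE)
  }
  a <- sort(abs(t_hat) / max(abs(t_hat)))
  n <- length(a)
  # strict inequality: count(|t| > P) = n - count(|t| <= P)
  dens <- (n - findInterval(thresholds, a)) / n
  structure(tibble::tibble(threshold = as.numeric(thresholds),
                           density = dens),
            class = c("density_curve", class(tibble::tibble())))
}

#' Fit an exponential decay a*exp(b*x) by least squares
#'
#' Deterministic nonlinear least squares for the two-parameter exponential:
#' for any decay rate `b` the optimal amplitude has the closed form
#' `a(b) = sum(y e^{bx}) / sum(e^{2bx})`, so the fit reduces to a
#' one-dimensional profiled search over `b` (coarse grid, then bounded
#' refinement), which cannot fail to converge — including on exactly flat
#' data, where it returns `b = 0` and `a` equal to the common value.
#'
#' @param xs Abscissae (at least 3 distinct points).
#' @param ys Non-negative ordinates, not all zero.
#' @param b_range Search range for the decay rate.
#' @return A `decay_fit` list with `a`, `b`, and `fit_residual` (the
#'   residual sum of squares at the optimum). Supports [glance()].
#' @examples
#' fit_exp_decay(seq(0, 1, 0.05), exp(-2 * seq(0, 1, 0.05)))
#' @export
fit_exp_decay <- function(xs, ys, b_range = c(-80, 10)) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L,
            all(is.finite(xs)), all(is.finite(ys)))
  if (any(ys < 0)) stop("ys must be non-negative", call. = FALSE)
  if (all(ys == 0)) stop("ys are all zero: amplitude undefined", call. = FALSE)
  sse <- function(b) {
    e <- exp(b * xs)
    a <- sum(ys * e) / sum(e * e)
    sum((ys - a * e)^2)
  }
  bs <- seq(b_range[1L], b_range[2L], length.out = 181L)
  vals <- vapply(bs, sse, numeric(1L))
  i <- which.min(vals)
  lo <- bs[max(1L, i - 1L)]
  hi <- bs[min(length(bs), i + 1L)]
  opt <- optimize(sse, c(lo, hi), tol = 1e-12)
  b <- opt$minimum
  # polish flat optima towards exact zero (constant data)
  if (sse(0) <= opt$objective + 1e-15) b <- 0
  e <- exp(b * xs)
  a <- sum(ys * e) / sum(e * e)
  structure(list(a = a, b = b, fit_residual = sum((ys - a * e)^2)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> a = %.4g, b = %.4g (RSS %.3g)\n",
              x$a, x$b, x$fit_residual))
  invisible(x)
}

#' Rate of decay of the density curve (RDD)
#'
#' Composes [density_curve()] and [fit_exp_decay()] and returns the decay
#' exponent `b`. More negative values indicate a sparser underlying
#' transformation; values near 0 a dense one. Invariant to scalar rescaling
#' of the matrix (the curve is built after max-abs normalisation).
#'
#' @inheritParams density_curve
#' @return Scalar decay rate `b` (<= 0 in practice).
#' @export
rdd <- function(t_hat, thresholds = seq(0, 1, by = 0.01)) {
  dc <- density_curve(t_hat, thresholds)
  fit_exp_decay(dc$threshold, dc$density)$b
}

#' Singular value spectrum of a transformation
#'
#' The top `min(rank_x, rank_y)` singular values, descending. The singular
#' values are the scaling deformation factors of the mapping: a flat
#' spectrum means every input direction is amplified equally (a
#' rotation/reflection up to scale), a fast-decaying one means the mapping
#' is sensitive to few input patterns only.
#'
#' @param t_hat Numeric matrix.
#' @param rank_x,rank_y Ranks of the input and output pattern matrices that
#'   produced the estimate; default to the matrix dimensions (keep all).
#' @return An `sv_spectrum` numeric vector, sorted descending.
#' @export
singular_spectrum <- function(t_hat, rank_x = ncol(t_hat),
                              rank_y = nrow(t_hat)) {
  t_hat <- unclass(as.matrix(t_hat))
  stopifnot(all(is.finite(t_hat)))
  p <- min(rank_x, rank_y, dim(t_hat))
  structure(svd(t_hat, nu = 0, nv = 0)$d[seq_len(p)], class = "sv_spectrum")
}

#' Rate of decay of the singular value spectrum (RDSV)
#'
#' Fits `a*exp(b*k)` to the singular values ordered by their integer index
#' `k = 1..P` and returns `b`. 0 means a flat spectrum (uniform
#' deformation); larger magnitudes mean stronger asymmetric
#' amplification/compression of input patterns. The abscissa is the raw
#' index, so `b` is a per-component rate; rescale the abscissa if a
#' size-free rate is wanted.
#'
#' @inheritParams singular_spectrum
#' @param spectrum Optionally, a precomputed [singular_spectrum()] (then
#'   `t_hat` is ignored).
#' @return Scalar decay rate `b`.
#' @export
rdsv <- function(t_hat, rank_x = ncol(t_hat), rank_y = nrow(t_hat),
                 spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- singular_spectrum(t_hat, rank_x, rank_y)
  fit_exp_decay(seq_along(spectrum), as.numeric(spectrum))$b
}

#' Polar decomposition of a square transformation
#'
#' Factorises `T = P1 R = R P2` with `R` orthogonal and `P1`, `P2`
#' symmetric positive-semidefinite — the rotation/reflection part and the
#' pre-/post-rotation scaling parts of the mapping. Built from the SVD
#' `T = U D V'`: `R = U V'`, `P1 = U D U'` (the symmetric square root of
#' `T T'`), `P2 = V D V'`. The eigenvalues of `P1` and `P2` are the
#' singular values of `T`. A verification diagnostic, not part of the main
#' metric pipeline.
#'
#' @param t_mat Square numeric matrix.
#' @return A `polar_parts` list with `R`, `P1`, `P2`.
#' @export
polar_decompose <- function(t_mat) {
  t_mat <- unclass(as.matrix(t_mat))
  if (nrow(t_mat) != ncol(t_mat)) stop("polar decomposition requires a square matrix",
                                       call. = FALSE)
  s <- svd(t_mat)
  structure(list(R = s$u %*% t(s$v),
                 P1 = s$u %*% (t(s$u) * s$d),
                 P2 = s$v %*% (t(s$v) * s$d)),
            class = "polar_parts")
}
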