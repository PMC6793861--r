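#' Simulate a sparse ground-truth transformation
#'
#' Draws an `n_out x n_in` matrix whose non-zero entries are i.i.d. standard
#' normal, with exactly `round(sparsity_percent/100 * n_out * n_in)` zero
#' entries at uniformly random positions. Uses the current RNG state; call
#' `set.seed()` (or use the seeded drivers) for reproducibility.
#'
#' @param n_out,n_in Output and input dimensions (voxels).
#' @param sparsity_percent Percentage of exactly-zero entries, in `[0, 100)`.
#' @return Numeric matrix `n_out x n_in`.
#' @export
simulate_sparse_transform <- function(n_out, n_in, sparsity_percent) {
  stopifnot(sparsity_percent >= 0, sparsity_percent < 100)
  n <- n_out * n_in
  t_mat <- matrix(rnorm(n), n_out, n_in)
  n_zero <- round(sparsity_percent * n / 100)
  if (n_zero > 0) t_mat[sample.int(n, n_zero)] <- 0
  t_mat
}

#' Simulate a transformation with an exponential singular value spectrum
#'
#' Builds `T = U S_b V'` where `U` and `V` are orthonormal factors from the
#' SVD of a standard-normal matrix and `S_b` is diagonal with entries
#' `exp(b * k)`, `k = 1..min(n_out, n_in)`. The singular values of the
#' result follow the prescribed decay exactly; `b = 0` gives a flat
#' spectrum, i.e. an orthogonal transformation up to scale.
#'
#' @param n_out,n_in Output and input dimensions (voxels).
#' @param b Decay rate (<= 0).
#' @return Numeric matrix `n_out x n_in`.
#' @export
simulate_decay_transform <- function(n_out, n_in, b) {
  stopifnot(b <= 0)
  s <- svd(matrix(rnorm(n_out * n_in), n_out, n_in))
  k <- seq_along(s$d)
  s$u %*% (t(s$v) * exp(b * k))
}

#' Mix signal and noise into a simulated output pattern
#'
#' Forms `(1 - gamma) TX / ||TX||_F + gamma E / ||E||_F` with `E` an
#' independent standard-normal matrix, then demeans and standardises each
#' stimulus column (population convention). `gamma` is the relative noise
#' strength: 0 gives a noise-free linear image of `X`, values near 1 bury
#' it.
#'
#' @param t_mat Ground-truth transformation (`n_out x n_in`).
#' @param X Input patterns (`n_in` voxels x `n_s` stimuli).
#' @param gamma Noise fraction in `[0, 1)`.
#' @return A z-normalised [pattern_matrix()] of simulated output patterns.
#' @export
mix_noise <- function(t_mat, X, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  signal <- t_mat %*% unclass(X)
  nrm <- frobenius(signal)
  if (nrm == 0) stop("T X is identically zero: signal undefined", call. = FALSE)
  noise <- matrix(rnorm(length(signal)), nrow(signal), ncol(signal))
  y <- (1 - gamma) * signal / nrm + gamma * noise / frobenius(noise)
  znormalise(pattern_matrix(y, stimulus_ids = colnames(X)))
}

#' Simulate a coupled pair of region pattern matrices
#'
#' Generates ground truth for the whole pipeline: a latent input pattern
#' matrix (standard normal), a ground-truth transformation (sparse or
#' SV-decay flavoured), and per-session observed input/output matrices.
#' Each session's input is the latent input mixed with fresh noise at
#' fraction `gamma`, and its output is the transformed latent input mixed
#' with fresh independent noise at the same fraction, both z-normalised —
#' so the two sessions are noisy realisations of one underlying mapping, as
#' in an across-sessions design.
#'
#' @param n_in,n_out Voxel counts of input and output regions.
#' @param n_stimuli Number of stimuli (columns).
#' @param sparsity Sparsity percentage for the ground-truth transformation
#'   (used unless `decay` is given).
#' @param decay SV decay rate `b`; if non-`NULL`, the transformation is
#'   generated by [simulate_decay_transform()] instead.
#' @param gamma Noise fraction in `[0, 1)` for both regions.
#' @param n_sessions Number of sessions to simulate.
#' @param seed Integer seed (local; the caller's RNG state is untouched).
#' @return A list with `x` and `y` (lists of `pattern_matrix`, one per
#'   session), `t_true`, and the generating parameters.
#' @export
simulate_region_pair <- function(n_in, n_out, n_stimuli, sparsity = 80,
                                 decay = NULL, gamma = 0.3, n_sessions = 2,
                                 seed = 1L) {
  with_seed(seed, {
    t_true <- if (is.null(decay)) {
      simulate_sparse_transform(n_out, n_in, sparsity)
    } else {
      simulate_decay_transform(n_out, n_in, decay)
    }
    x0 <- matrix(rnorm(n_in * n_stimuli), n_in, n_stimuli,
                 dimnames = list(NULL, sprintf("s%03d", seq_len(n_stimuli))))
    xs <- vector("list", n_sessions)
    ys <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      xn <- matrix(rnorm(length(x0)), n_in, n_stimuli)
      x_obs <- (1 - gamma) * x0 / frobenius(x0) + gamma * xn / frobenius(xn)
      xs[[s]] <- znormalise(pattern_matrix(x_obs, stimulus_ids = colnames(x0)))
      ys[[s]] <- mix_noise(t_true, x0, gamma)
    }
    list(x = xs, y = ys, t_true = t_true,
         params = list(n_in = n_in, n_out = n_out, n_stimuli = n_stimuli,
                       sparsity = if (is.null(decay)) sparsity else NA_real_,
                       decay = decay, gamma = gamma, seed = seed))
  })
}

#' Example stimulus annotation table
#'
#' A 96-stimulus table mirroring a classic object-vision design: 24 faces,
#' 8 places and 64 other objects, with the first 48 stimuli animate (faces,
#' bodies, animals) and the last 48 inanimate (places and artificial or
#' natural objects).
#'
#' @param n_stimuli Total number of stimuli (default 96; faces/places are
#'   scaled proportionally for other sizes).
#' @return A tibble with columns `stimulus_id`, `category`, `animacy`.
#' @export
make_stimulus_table <- function(n_stimuli = 96) {
  n_face <- round(n_stimuli * 24 / 96)
  n_place <- round(n_stimuli * 8 / 96)
  n_half <- floor(n_stimuli / 2)
  category <- rep("object", n_stimuli)
  category[seq_len(n_face)] <- "face"                       # animate half
  category[n_half + seq_len(n_place)] <- "place"            # inanimate half
  animacy <- rep(c("animate", "inanimate"),
                 c(n_half, n_stimuli - n_half))
  tibble::tibble(stimulus_id = sprintf("s%03d", seq_len(n_stimuli)),
                 category = category, animacy = animacy)
}
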