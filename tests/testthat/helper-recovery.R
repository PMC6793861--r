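# Parameter-recovery experiment: build a calibration grid at a lambda taken
# from a reference fit (mid-grid condition), then, for each true level x
# noise fraction and each seed, simulate a small 4-subject study, bracket
# the across-subject mean (decay, GOF) point, and record whether the
# bracket contains the true level. Problem size follows the toy-simulation
# scale (T 128 x 128, 96 stimuli).
recovery_rates <- function(kind, true_levels, gammas,
                           n_seeds = 20, n_subjects = 4, n_sims = 200,
                           n_in = 128, n_out = 128, n_s = 96) {
  with_seed <- patrans:::with_seed
  derive_seed <- patrans:::derive_seed
  X <- with_seed(20240101L,
                 znormalise(matrix(rnorm(n_in * n_s), n_in, n_s)))
  draw_t <- function(level) {
    if (kind == "sparsity") simulate_sparse_transform(n_out, n_in, level)
    else simulate_decay_transform(n_out, n_in, level)
  }
  ref_level <- if (kind == "sparsity") 80 else -0.1
  y_ref <- with_seed(20240102L, mix_noise(draw_t(ref_level), X, 0.3))
  lam <- suppressWarnings(select_lambda(X, y_ref))$lambda
  grid <- calibrate(kind, X = X, lambda = lam, n_out = n_out,
                    config = simulation_config(n_sims = n_sims,
                                               seed = 20240103L))
  cells <- expand.grid(level = true_levels, gamma = gammas)
  cells$hit_rate <- NA_real_
  for (r in seq_len(nrow(cells))) {
    hits <- logical(n_seeds)
    for (s in seq_len(n_seeds)) {
      ms <- vapply(seq_len(n_subjects), function(subj) {
        obs <- with_seed(derive_seed(777L, r * 100000 + s * 100 + subj),
                         mix_noise(draw_t(cells$level[r]), X, cells$gamma[r]))
        unlist(suppressWarnings(
          metrics_at_lambda(X, obs, lam, kind)))
      }, numeric(2))
      br <- suppressWarnings(
        bracket_estimate(grid, mean(ms["decay", ]), mean(ms["gof", ])))
      hits[s] <- patrans:::bracket_contains(br, cells$level[r])
    }
    cells$hit_rate[r] <- mean(hits)
  }
  cells
}
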