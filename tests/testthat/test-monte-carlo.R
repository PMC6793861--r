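test_that("sparse transforms have exactly the requested number of zeros", {
  set.seed(1)
  t90 <- simulate_sparse_transform(100, 100, 90)
  expect_equal(sum(t90 == 0), 9000L)
  t0 <- simulate_sparse_transform(50, 40, 0)
  expect_equal(sum(t0 == 0), 0L)
  t_half <- simulate_sparse_transform(30, 30, 50)
  expect_equal(sum(t_half == 0), 450L)
})

test_that("nonzero entries of a sparse transform are standard normal", {
  set.seed(2)
  t_mat <- simulate_sparse_transform(500, 400, 50)
  nz <- t_mat[t_mat != 0]
  n <- length(nz)
  expect_lt(abs(mean(nz)), 3 / sqrt(n))
  expect_lt(abs(var(nz) - 1), 3 * sqrt(2 / n))
})

test_that("decay transforms carry an exactly exponential singular spectrum", {
  set.seed(3)
  t_mat <- simulate_decay_transform(10, 10, -1)
  expect_lt(max(abs(svd(t_mat)$d - exp(-(1:10)))), 1e-8)
  t_flat <- simulate_decay_transform(12, 8, 0)
  d <- svd(t_flat)$d
  expect_lt(max(abs(d - 1)), 1e-8)   # b = 0: orthogonal up to scale
  t_rect <- simulate_decay_transform(9, 14, -0.1)
  expect_lt(max(abs(svd(t_rect)$d - exp(-0.1 * (1:9)))), 1e-8)
})

test_that("noise mixing preserves the signal at gamma 0 and degrades the fit as gamma grows", {
  set.seed(4)
  X <- znormalise(matrix(rnorm(20 * 16), 20, 16))
  t_mat <- simulate_sparse_transform(15, 20, 50)
  y0 <- mix_noise(t_mat, X, 0)
  signal <- znormalise(t_mat %*% unclass(X))
  expect_lt(max(abs(unclass(y0) - unclass(signal))), 1e-10)
  gof_by_gamma <- vapply(1:4, function(seed) {
    set.seed(100 + seed)
    c(compute_gof(X, mix_noise(t_mat, X, 0), 1)$gof_percent,
      compute_gof(X, mix_noise(t_mat, X, 0.9), 1)$gof_percent)
  }, numeric(2))
  expect_true(all(gof_by_gamma[2, ] < gof_by_gamma[1, ]))
  expect_error(mix_noise(matrix(0, 3, 5), matrix(rnorm(20), 5, 4), 0.2),
               "zero")
})

test_that("a smoke calibration returns a complete, finite, reproducible grid", {
  X <- make_normal_pm(24, 20, seed = 5)
  cfg <- simulation_config(sparsity_levels = c(50, 90),
                           gamma_levels = c(0, 0.4), n_sims = 2, seed = 11)
  g1 <- calibrate("sparsity", X = X, lambda = 5, n_out = 18, config = cfg)
  expect_equal(nrow(g1), 4L)
  expect_true(all(g1$n == 2L))
  expect_true(all(is.finite(g1$mean_decay)))
  expect_true(all(is.finite(g1$mean_gof)))
  g2 <- calibrate("sparsity", X = X, lambda = 5, n_out = 18, config = cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  gd <- calibrate("deformation", X = X, lambda = 5, n_out = 18,
                  config = simulation_config(decay_levels = c(0, -1),
                                             gamma_levels = c(0, 0.4),
                                             n_sims = 2, seed = 11))
  expect_equal(nrow(gd), 4L)
  expect_identical(attr(gd, "kind"), "deformation")
})

test_that("calibration means order by sparsity level and degrade with noise", {
  X <- make_normal_pm(40, 32, seed = 6)
  cfg <- simulation_config(gamma_levels = c(0, 0.3, 0.6), n_sims = 10,
                           seed = 21)
  g <- calibrate("sparsity", X = X, lambda = 20, n_out = 40, config = cfg)
  at_g0 <- g[g$gamma == 0, ]
  at_g0 <- at_g0[order(at_g0$level), ]
  expect_true(all(diff(at_g0$mean_decay) < 0))  # sparser => steeper decay
  for (lv in unique(g$level)) {
    cur <- g[g$level == lv, ]
    expect_true(all(diff(cur$mean_gof[order(cur$gamma)]) < 0))
  }
})

test_that("bracketing interpolates the calibration curves correctly", {
  grid <- structure(
    tibble::tibble(
      level = rep(c(50, 60, 70), each = 2),
      gamma = rep(c(0, 0.5), 3),
      mean_decay = c(-2, -1, -4, -2, -8, -4),
      sd_decay = 0.1, mean_gof = rep(c(60, 20), 3), sd_gof = 1, n = 10L),
    kind = "sparsity", class = c("calibration_grid", class(tibble::tibble())))
  # interpolated decays at GOF 40: -1.5 (50), -3 (60), -6 (70)
  br <- bracket_estimate(grid, observed_decay = -2, observed_gof = 40)
  expect_equal(c(br$lower_level, br$upper_level), c(50, 60))
  # exactly on a curve: degenerate bracket
  br_tie <- bracket_estimate(grid, observed_decay = -3, observed_gof = 40)
  expect_equal(c(br_tie$lower_level, br_tie$upper_level), c(60, 60))
  # shallower than every curve: not sparse
  br_ns <- bracket_estimate(grid, observed_decay = -0.5, observed_gof = 40)
  expect_true(br_ns$not_sparse)
  expect_equal(br_ns$upper_level, 50)
  expect_true(is.na(br_ns$lower_level))
  # steeper than every curve: open upper bracket
  br_hi <- bracket_estimate(grid, observed_decay = -10, observed_gof = 40)
  expect_equal(br_hi$lower_level, 70)
  expect_true(is.na(br_hi$upper_level))
  # GOF outside the simulated range warns
  w <- capture_warnings(bracket_estimate(grid, -2, 80))
  expect_true(any(grepl("outside", w)))
})

test_that("bracketing orients open ends correctly for decay-rate levels", {
  grid <- structure(
    tibble::tibble(
      level = rep(c(0, -0.1, -1), each = 2),
      gamma = rep(c(0, 0.5), 3),
      mean_decay = c(-0.05, -0.02, -0.3, -0.1, -2, -0.8),
      sd_decay = 0.01, mean_gof = rep(c(60, 20), 3), sd_gof = 1, n = 10L),
    kind = "deformation",
    class = c("calibration_grid", class(tibble::tibble())))
  br <- bracket_estimate(grid, observed_decay = -0.1, observed_gof = 40)
  expect_equal(c(br$lower_level, br$upper_level), c(-0.1, 0))
  # shallower than the flat-spectrum curve: open towards b > 0
  br_flat <- bracket_estimate(grid, observed_decay = -0.01, observed_gof = 40)
  expect_equal(br_flat$lower_level, 0)
  expect_true(is.na(br_flat$upper_level))
  expect_false(br_flat$not_sparse)
  # steeper than the steepest curve: true decay beyond -1
  br_deep <- bracket_estimate(grid, observed_decay = -5, observed_gof = 40)
  expect_equal(br_deep$upper_level, -1)
  expect_true(is.na(br_deep$lower_level))
})

test_that("region-pair simulation is reproducible and correctly shaped", {
  sim <- simulate_region_pair(15, 12, 10, sparsity = 60, gamma = 0.3, seed = 9)
  expect_length(sim$x, 2L)
  expect_equal(dim(sim$x[[1]]), c(15L, 10L))
  expect_equal(dim(sim$y[[2]]), c(12L, 10L))
  expect_equal(sum(sim$t_true == 0), round(0.6 * 15 * 12))
  expect_true(attr(sim$y[[1]], "normalised"))
  sim2 <- simulate_region_pair(15, 12, 10, sparsity = 60, gamma = 0.3,
                               seed = 9)
  expect_identical(sim$t_true, sim2$t_true)
  expect_identical(unclass(sim$y[[2]]), unclass(sim2$y[[2]]))
  # sessions differ (independent noise) but share the ground truth
  expect_gt(max(abs(unclass(sim$x[[1]]) - unclass(sim$x[[2]]))), 0.01)
})
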