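test_that("ridge solution recovers identity and shrinks to zero at the extremes", {
  set.seed(21)
  X <- matrix(rnorm(36), 6, 6)   # full rank, unnormalised on purpose
  That <- estimate_transform(X, X, 1e-10)
  expect_lt(max(abs(That - diag(6))), 1e-6)
  Y <- matrix(rnorm(36), 6, 6)
  expect_lt(max(abs(estimate_transform(X, Y, 1e12))), 1e-6)
})

test_that("lambda = 0 with rank-deficient Gram matrix is a singularity error", {
  X <- znormalise(make_normal_pm(6, 4, seed = 2, normalise = FALSE))
  # column-centred X has rank <= min(N_x - 1, N_s) < N_x, so XX' is singular
  expect_error(estimate_transform(X, make_normal_pm(3, 4, seed = 3), 0),
               "singular")
})

test_that("the closed-form estimate minimises the penalised objective", {
  for (seed in 1:5) {
    X <- make_normal_pm(6, 5, seed = seed)
    Y <- make_normal_pm(4, 5, seed = seed + 100)
    That <- estimate_transform(X, Y, 1)
    obj_hat <- ridge_objective(That, X, Y, 1)
    # generic numerical minimiser reaches the same objective value
    opt <- optim(rep(0, length(That)), function(v)
      ridge_objective(matrix(v, nrow(Y), nrow(X)), X, Y, 1),
      gr = function(v) {
        M <- matrix(v, nrow(Y), nrow(X))
        as.vector(2 * (M %*% unclass(X) - unclass(Y)) %*% t(unclass(X)) + 2 * M)
      }, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    expect_lt(abs(obj_hat - opt$value), 1e-6)
    # random perturbations never decrease the objective
    for (k in 1:10) {
      eps <- matrix(rnorm(length(That), sd = 1e-3), nrow(That), ncol(That))
      expect_gte(ridge_objective(That + eps, X, Y, 1), obj_hat)
    }
  }
})

test_that("the hat-matrix shortcut equals the explicit leave-one-stimulus-out loop", {
  for (seed in 1:6) {
    X <- make_normal_pm(10, 8, seed = seed)
    Y <- make_normal_pm(7, 8, seed = seed + 50)
    for (alpha in c(0.05, 1, 20, 500)) {
      expect_lt(abs(loocv_objective(X, Y, alpha) - loo_explicit(X, Y, alpha)),
                1e-8)
    }
  }
})

test_that("leverage failure is reported when alpha is too small for the data rank", {
  set.seed(4)
  X <- matrix(rnorm(12 * 4), 12, 4)  # rank = N_s, leverages -> 1 as alpha -> 0
  Y <- matrix(rnorm(5 * 4), 5, 4)
  expect_error(loocv_objective(X, Y, 0), "leverage")
})

test_that("the cross-validation curve is finite across the candidate envelope", {
  X <- make_normal_pm(20, 16, seed = 8)
  Y <- make_normal_pm(15, 16, seed = 9)
  sel <- suppressWarnings(select_lambda(X, Y))
  expect_equal(range(sel$grid), c(1e-2, 1e4))
  expect_true(all(is.finite(sel$curve)))
  expect_equal(min(sel$curve), sel$curve[match(sel$lambda, sel$grid)])
})

test_that("grid selection agrees with the explicit leave-one-out loop argmin", {
  X <- make_normal_pm(9, 7, seed = 31)
  Y <- make_normal_pm(6, 7, seed = 32)
  grid <- 10^seq(-2, 3, length.out = 12)
  sel <- suppressWarnings(select_lambda(X, Y, grid))
  explicit <- vapply(grid, function(a) loo_explicit(X, Y, a), numeric(1))
  expect_equal(sel$lambda, grid[which.min(explicit)])
  expect_equal(sel$curve, explicit, tolerance = 1e-10)
})

test_that("noise shifts the selected regularisation upward", {
  lams <- vapply(1:5, function(seed) {
    clean <- simulate_region_pair(40, 30, 24, sparsity = 0, gamma = 0,
                                  seed = seed)
    noisy <- simulate_region_pair(40, 30, 24, sparsity = 0, gamma = 0.9,
                                  seed = seed)
    c(suppressWarnings(select_lambda(clean$x[[1]], clean$y[[1]]))$lambda,
      suppressWarnings(select_lambda(noisy$x[[1]], noisy$y[[1]]))$lambda)
  }, numeric(2))
  expect_true(all(lams[2, ] > lams[1, ]))
})

test_that("GOF is high for an exact linear mapping and matches the explicit ratio form", {
  set.seed(41)
  X <- znormalise(matrix(rnorm(8 * 40), 8, 40))
  T_true <- matrix(rnorm(100 * 8), 100, 8)
  Y <- znormalise(T_true %*% unclass(X))
  gof <- compute_gof(X, Y, 1e-4)
  expect_gt(gof$gof_percent, 99)
  # explicit per-stimulus form: 100 (1 - mean_i r_i / ||Y_i||^2), ||Y_i||^2 = N_Y
  explicit <- vapply(seq_len(ncol(X)), function(i) {
    That <- estimate_transform(unclass(X)[, -i], unclass(Y)[, -i], 1e-4)
    sum((That %*% unclass(X)[, i] - unclass(Y)[, i])^2) / nrow(Y)
  }, numeric(1))
  expect_lt(abs(gof$gof_percent - 100 * (1 - mean(explicit))), 1e-8)
  expect_equal(mean(gof$per_stimulus_gof), gof$gof_percent, tolerance = 1e-10)
})

test_that("GOF of statistically independent regions is near zero and unclipped", {
  X <- make_normal_pm(60, 48, seed = 51)
  Y <- make_normal_pm(50, 48, seed = 52)
  gof <- compute_gof(X, Y, 1e6)$gof_percent
  expect_lt(abs(gof), 3)
  # small lambda on independent data overfits: negative GOF is reported as-is
  expect_lt(compute_gof(X, Y, 0.01)$gof_percent, 0)
})

test_that("k-fold selection with k = N_s reproduces leave-one-out and is seeded", {
  X <- make_normal_pm(10, 9, seed = 61)
  Y <- make_normal_pm(8, 9, seed = 62)
  grid <- 10^seq(-1, 3, length.out = 9)
  loo <- suppressWarnings(select_lambda(X, Y, grid))
  kf <- suppressWarnings(select_lambda_kfold(X, Y, grid, k = 9, seed = 1))
  expect_equal(kf$lambda, loo$lambda)
  expect_equal(kf$curve, loo$curve, tolerance = 1e-8)
  kf2 <- suppressWarnings(select_lambda_kfold(X, Y, grid, k = 3, seed = 7))
  kf3 <- suppressWarnings(select_lambda_kfold(X, Y, grid, k = 3, seed = 7))
  expect_identical(kf2$lambda, kf3$lambda)
  expect_identical(kf2$folds, kf3$folds)
  expect_error(select_lambda_kfold(X, Y, grid, k = 10), "exceeds")
})

test_that("k-fold and leave-one-out selections give similar GOF on strong signal", {
  sim <- simulate_region_pair(30, 25, 40, sparsity = 50, gamma = 0.2, seed = 71)
  f_loo <- fit_transform(sim$x[[1]], sim$y[[1]])
  f_kf <- fit_transform(sim$x[[1]], sim$y[[1]], method = "kfold", k = 10,
                        seed = 3)
  expect_lt(abs(f_loo$gof_percent - f_kf$gof_percent), 5)
})

test_that("shrinkage is monotone and stimulus order is irrelevant", {
  X <- make_normal_pm(14, 12, seed = 81)
  Y <- make_normal_pm(11, 12, seed = 82)
  grid <- 10^seq(-2, 4, length.out = 10)
  norms <- vapply(grid, function(l) sqrt(sum(estimate_transform(X, Y, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  perm <- sample(12)
  Xp <- pattern_matrix(unclass(X)[, perm], normalised = TRUE)
  Yp <- pattern_matrix(unclass(Y)[, perm], normalised = TRUE)
  sel <- suppressWarnings(select_lambda(X, Y, grid))
  selp <- suppressWarnings(select_lambda(Xp, Yp, grid))
  expect_equal(selp$lambda, sel$lambda)
  expect_equal(compute_gof(Xp, Yp, sel$lambda)$gof_percent,
               compute_gof(X, Y, sel$lambda)$gof_percent, tolerance = 1e-10)
})

test_that("an argmin on the grid edge raises an endpoint warning", {
  X <- make_normal_pm(30, 20, seed = 91)
  Y <- make_normal_pm(25, 20, seed = 92)   # independent: wants huge lambda
  expect_warning(select_lambda(X, Y, 10^seq(-2, 1, length.out = 5)),
                 "endpoint")
})
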