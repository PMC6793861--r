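#' Monte Carlo simulation configuration
#'
#' Bundles the simulated levels and noise grid for [calibrate()]. Defaults
#' follow the reference protocol: sparsity levels 50/60/70/80/90/99 percent,
#' singular-value decay levels 0, -0.01, -0.1, -1, noise fractions 0 to 0.9
#' in steps of 0.1, and 1000 simulations per (level, gamma) cell. A reduced
#' `n_sims` (e.g. 25) gives a fast smoke profile for interactive use.
#'
#' @param sparsity_levels Percentages of exact zeros to simulate.
#' @param decay_levels Singular-value decay rates `b` to simulate (<= 0).
#' @param gamma_levels Noise fractions, each in `[0, 1)`.
#' @param n_sims Simulations per cell.
#' @param seed Root seed; each (level, gamma) cell draws from its own
#'   deterministic stream so results do not depend on execution order.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sparsity_levels = c(50, 60, 70, 80, 90, 99),
                              decay_levels = c(0, -0.01, -0.1, -1),
                              gamma_levels = seq(0, 0.9, by = 0.1),
                              n_sims = 1000, seed = 1L) {
  stopifnot(all(gamma_levels >= 0), all(gamma_levels < 1),
            all(sparsity_levels >= 0), all(sparsity_levels < 100),
            all(decay_levels <= 0), n_sims >= 1)
  structure(list(sparsity_levels = sort(sparsity_levels),
                 decay_levels = sort(decay_levels, decreasing = TRUE),
                 gamma_levels = sort(gamma_levels),
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "simulation_config")
}

# Precomputed fixed-lambda machinery shared by every simulation in a grid:
# ridge factor (so That = Ytilde %*% proj %*% t(u)), and the hat/leverage
# pieces of the cross-validated objective.
ridge_at_lambda <- function(X, lambda) {
  sv <- ridge_svd(unclass(X))
  w_fit <- sv$d / (sv$d^2 + lambda)
  w_hat <- sv$d^2 / (sv$d^2 + lambda)
  h <- as.vector((sv$v^2) %*% w_hat)
  if (any(h >= 1 - 1e-12)) stop("leverage h_ii >= 1 at this lambda",
                                call. = FALSE)
  list(sv = sv, proj = sweep(sv$v, 2L, w_fit, `*`), w_hat = w_hat,
       h = h, lambda = lambda)
}

gof_at_lambda <- function(pre, Y) {
  Yt <- t(unclass(Y))
  resid <- Yt - pre$sv$v %*% (crossprod(pre$sv$v, Yt) * pre$w_hat)
  obj <- sum(rowSums(resid^2) / (1 - pre$h)^2)
  100 * (1 - obj / (nrow(Y) * ncol(Y)))
}

#' Decay metric and goodness-of-fit at a fixed regularisation weight
#'
#' Computes the (RDD or RDSV, GOF) coordinate pair used to place an
#' observation in a calibration plane: the transformation is estimated at
#' the supplied `lambda` (not re-selected) and the requested decay metric
#' and the cross-validated GOF at that `lambda` are returned.
#'
#' @inheritParams estimate_transform
#' @param lambda Positive regularisation weight (typically from the
#'   real-data fit).
#' @param kind `"sparsity"` (decay = RDD) or `"deformation"` (decay = RDSV).
#' @return A one-row tibble with columns `decay` and `gof`.
#' @export
metrics_at_lambda <- function(X, Y, lambda,
                              kind = c("sparsity", "deformation")) {
  kind <- match.arg(kind)
  if (!is_normalised(X)) X <- znormalise(X)
  if (!is_normalised(Y)) Y <- znormalise(Y)
  check_conformable(X, Y)
  pre <- ridge_at_lambda(X, lambda)
  b_mat <- unclass(Y) %*% pre$proj
  decay <- if (kind == "sparsity") {
    rdd(b_mat %*% t(pre$sv$u))
  } else {
    p <- min(pre$sv$rank, nrow(Y) - 1L, ncol(Y))
    rdsv(spectrum = svd(b_mat, nu = 0, nv = 0)$d[seq_len(p)])
  }
  tibble::tibble(decay = decay, gof = gof_at_lambda(pre, Y))
}

#' Build a Monte Carlo calibration grid
#'
#' For each simulated level (sparsity percentage or SV decay rate) and each
#' noise fraction gamma, repeatedly: draw a ground-truth transformation,
#' form the noisy simulated output `(1-gamma) TX/||TX||_F + gamma E/||E||_F`
#' from the supplied input patterns, re-estimate the transformation by ridge
#' at the fixed `lambda` (the one obtained on the data under study), and
#' record the decay metric (RDD or RDSV) and the GOF. Cell means and
#' standard deviations form the calibration curves in the (GOF, decay)
#' plane against which an observed estimate is bracketed with
#' [bracket_estimate()].
#'
#' @param kind `"sparsity"` or `"deformation"`.
#' @param X Input-region patterns to drive the simulations (z-normalised if
#'   not already); `NULL` draws a standard-normal input of size
#'   `n_in x n_stimuli`.
#' @param lambda Fixed positive regularisation weight from the data fit.
#' @param n_out Output-region voxel count to simulate.
#' @param config A [simulation_config()].
#' @param n_in,n_stimuli Input dimensions, used only when `X` is `NULL`.
#' @return A `calibration_grid` tibble with columns `level`, `gamma`,
#'   `mean_decay`, `sd_decay`, `mean_gof`, `sd_gof`, `n`; attributes record
#'   `kind`, `lambda` and the problem dimensions. Supports [autoplot()].
#' @export
calibrate <- function(kind = c("sparsity", "deformation"), X = NULL, lambda,
                      n_out, config = simulation_config(),
                      n_in = NULL, n_stimuli = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "simulation_config"), lambda > 0, n_out >= 2)
  if (is.null(X)) {
    stopifnot(!is.null(n_in), !is.null(n_stimuli))
    X <- with_seed(derive_seed(config$seed, 0L),
                   matrix(rnorm(n_in * n_stimuli), n_in, n_stimuli))
  }
  X <- if (is_normalised(X)) X else znormalise(X)
  pre <- ridge_at_lambda(X, lambda)
  levels <- if (kind == "sparsity") config$sparsity_levels else config$decay_levels
  n_in <- nrow(X); n_s <- ncol(X)
  p_sv <- min(pre$sv$rank, n_out - 1L, n_s)
  cells <- expand.grid(gamma = config$gamma_levels, level = levels)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    level <- cells$level[ci]; gam <- cells$gamma[ci]
    res[[ci]] <- with_seed(derive_seed(config$seed, ci), {
      decays <- numeric(config$n_sims)
      gofs <- numeric(config$n_sims)
      for (s in seq_len(config$n_sims)) {
        t_true <- if (kind == "sparsity") {
          simulate_sparse_transform(n_out, n_in, level)
        } else {
          simulate_decay_transform(n_out, n_in, level)
        }
        y_sim <- mix_noise(t_true, X, gam)
        b_mat <- unclass(y_sim) %*% pre$proj
        decays[s] <- if (kind == "sparsity") {
          rdd(b_mat %*% t(pre$sv$u))
        } else {
          rdsv(spectrum = svd(b_mat, nu = 0, nv = 0)$d[seq_len(p_sv)])
        }
        gofs[s] <- gof_at_lambda(pre, y_sim)
      }
      tibble::tibble(level = level, gamma = gam,
                     mean_decay = mean(decays), sd_decay = sd(decays),
                     mean_gof = mean(gofs), sd_gof = sd(gofs),
                     n = config$n_sims)
    })
  }
  out <- dplyr::bind_rows(res)
  structure(out, kind = kind, lambda = lambda,
            n_in = n_in, n_out = n_out, n_stimuli = n_s,
            seed = config$seed,
            class = c("calibration_grid", class(out)))
}

#' Bracket an observed estimate between calibration curves
#'
#' Each simulated level traces a mean-decay-versus-mean-GOF curve across the
#' noise fractions. The curve is linearly interpolated at the observed GOF,
#' and the two adjacent levels whose interpolated decays enclose the
#' observed decay form the bracket — the Monte-Carlo estimate of the true
#' level as an interval. An observed decay shallower than the least extreme
#' simulated curve yields an open lower bracket (for sparsity: the
#' "not sparse" verdict, below the smallest simulated percentage); one
#' steeper than the most extreme curve yields an open upper bracket. An
#' observed GOF outside a curve's simulated range triggers an extrapolation
#' warning (the curve is clamped at its end).
#'
#' @param grid A [calibrate()] result.
#' @param observed_decay,observed_gof Coordinates of the observation, e.g.
#'   from [metrics_at_lambda()] or averaged across subjects.
#' @return A `bracket_estimate` list with `lower_level`, `upper_level`
#'   (`NA` when open), `not_sparse`, the observation, and the per-level
#'   interpolated decays.
#' @export
bracket_estimate <- function(grid, observed_decay, observed_gof) {
  stopifnot(inherits(grid, "calibration_grid"))
  kind <- attr(grid, "kind")
  levels <- unique(grid$level)
  interp <- vapply(levels, function(lv) {
    cur <- grid[grid$level == lv, ]
    cur <- cur[order(cur$mean_gof), ]
    if (observed_gof < min(cur$mean_gof) || observed_gof > max(cur$mean_gof)) {
      warning("observed GOF ", signif(observed_gof, 4),
              " outside the simulated range of level ", lv,
              "; extrapolating from the curve end", call. = FALSE)
    }
    if (nrow(cur) < 2L) return(cur$mean_decay[1L])
    approx(cur$mean_gof, cur$mean_decay, xout = observed_gof,
           rule = 2, ties = mean)$y
  }, numeric(1L))
  ord <- order(interp, decreasing = TRUE)  # least steep curve first
  levels <- levels[ord]; interp <- interp[ord]
  k <- length(levels)
  # does the level axis increase with curve steepness (sparsity %) or
  # decrease with it (SV decay rate b)?
  steeper_is_larger <- levels[k] > levels[1L]
  lower <- upper <- NA_real_
  not_sparse <- FALSE
  on_curve <- which(observed_decay == interp)
  if (length(on_curve)) {
    lower <- upper <- levels[on_curve[1L]]
  } else if (observed_decay > interp[1L]) {
    # shallower than every simulated curve
    if (steeper_is_larger) upper <- levels[1L] else lower <- levels[1L]
    not_sparse <- identical(kind, "sparsity")
  } else if (observed_decay < interp[k]) {
    # steeper than every simulated curve
    if (steeper_is_larger) lower <- levels[k] else upper <- levels[k]
  } else {
    i <- max(which(interp > observed_decay))
    lower <- min(levels[i], levels[i + 1L])
    upper <- max(levels[i], levels[i + 1L])
  }
  structure(list(kind = kind, lower_level = lower, upper_level = upper,
                 not_sparse = not_sparse,
                 observed_decay = observed_decay, observed_gof = observed_gof,
                 interpolated = tibble::tibble(level = levels,
                                               decay_at_gof = interp)),
            class = "bracket_estimate")
}

#' @export
print.bracket_estimate <- function(x, ...) {
  lab <- if (isTRUE(x$not_sparse)) {
    sprintf("not sparse (< %s%%)", format(x$upper_level))
  } else if (is.na(x$lower_level)) {
    sprintf("above %s (open bracket)", format(x$upper_level))
  } else if (is.na(x$upper_level)) {
    sprintf("beyond %s (open bracket)", format(x$lower_level))
  } else if (x$lower_level == x$upper_level) {
    sprintf("on the %s curve", format(x$lower_level))
  } else {
    sprintf("%s to %s", format(x$lower_level), format(x$upper_level))
  }
  cat(sprintf("<bracket_estimate> %s level: %s\n  observed decay %.4g at GOF %.2f%%\n",
              x$kind, lab, x$observed_decay, x$observed_gof))
  invisible(x)
}

# Does the bracket interval (closed at finite ends) contain a level?
bracket_contains <- function(br, level) {
  (is.na(br$lower_level) || level >= br$lower_level) &&
    (is.na(br$upper_level) || level <= br$upper_level)
}
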