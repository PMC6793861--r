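#' Across-sessions transformation metrics
#'
#' Estimates the mapping twice — input patterns of session 1 with output
#' patterns of session 2, and vice versa — and averages the three metrics
#' (GOF, RDD, RDSV) over the two directions. Crossing sessions suppresses
#' stimulus-unrelated intrinsic fluctuations shared between the regions
#' within a session, which would otherwise inflate the apparent coupling.
#'
#' @param x1,x2 Input-region patterns for sessions 1 and 2.
#' @param y1,y2 Output-region patterns for sessions 1 and 2.
#' @param grid Candidate regularisation values for the per-direction fits.
#' @return A `cross_session_result`: list with session-averaged `gof`,
#'   `rdd`, `rdsv`, a `directions` tibble holding the per-direction values
#'   and selected lambdas, and the two `transform_fit` objects. Supports
#'   [tidy()] and [glance()].
#' @export
cross_session_metrics <- function(x1, y1, x2, y2,
                                  grid = default_lambda_grid()) {
  mats <- list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  mats <- lapply(mats, function(m) if (is_normalised(m)) m else znormalise(m))
  ids <- lapply(mats, colnames)
  if (length(unique(ids)) != 1L) {
    stop("all four matrices must share the same stimulus identifiers",
         call. = FALSE)
  }
  one_direction <- function(X, Y) {
    fit <- fit_transform(X, Y, grid = grid)
    rx <- ridge_svd(unclass(X))$rank
    ry <- ridge_svd(unclass(Y))$rank
    list(fit = fit,
         row = tibble::tibble(lambda = fit$lambda, gof = fit$gof_percent,
                              rdd = rdd(fit$t_hat),
                              rdsv = rdsv(fit$t_hat, rank_x = rx, rank_y = ry)))
  }
  d12 <- one_direction(mats$x1, mats$y2)
  d21 <- one_direction(mats$x2, mats$y1)
  directions <- dplyr::bind_rows(
    dplyr::mutate(d12$row, direction = "1->2", .before = 1L),
    dplyr::mutate(d21$row, direction = "2->1", .before = 1L))
  structure(list(gof = mean(directions$gof),
                 rdd = mean(directions$rdd),
                 rdsv = mean(directions$rdsv),
                 directions = directions,
                 fits = list(`1->2` = d12$fit, `2->1` = d21$fit)),
            class = "cross_session_result")
}

#' @export
print.cross_session_result <- function(x, ...) {
  cat(sprintf(
    "<cross_session_result> GOF = %.2f%%, RDD = %.3g, RDSV = %.3g (mean of both directions)\n",
    x$gof, x$rdd, x$rdsv))
  print(x$directions, ...)
  invisible(x)
}

#' Permutation test of the goodness-of-fit
#'
#' Builds a null distribution of GOF values by shuffling the stimulus
#' columns of each input-region matrix (breaking the stimulus
#' correspondence while preserving both marginal pattern structures) and
#' refitting. By default the regularisation parameter is re-selected inside
#' every permutation — the honest null — with a faster option that fixes it
#' at the observed value. The observed per-subject GOF distribution is
#' compared to the pooled null with a two-sample Kolmogorov-Smirnov test;
#' because that comparison rests on few observed values, the empirical null
#' percentile of each observed GOF is also reported.
#'
#' @param pairs List of subject data, each element a list with components
#'   `x` and `y` (pattern matrices sharing stimuli).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param grid Candidate regularisation values.
#' @param reselect_lambda Re-select lambda per permutation (default) or
#'   reuse each subject's observed lambda.
#' @return A list with `observed` (tibble: subject, lambda, gof,
#'   null_percentile), `null_gofs` (length `n_perm * length(pairs)`),
#'   `p_value` (K-S), and `n_perm`.
#' @export
permutation_test_gof <- function(pairs, n_perm = 10000, seed = 1L,
                                 grid = default_lambda_grid(),
                                 reselect_lambda = TRUE) {
  stopifnot(length(pairs) >= 1L, n_perm >= 1L)
  prep <- lapply(pairs, function(p) {
    X <- if (is_normalised(p$x)) p$x else znormalise(p$x)
    Y <- if (is_normalised(p$y)) p$y else znormalise(p$y)
    check_conformable(X, Y)
    sv <- ridge_svd(unclass(X))
    Yt <- t(unclass(Y))
    sel <- suppressWarnings(select_lambda(X, Y, grid))
    gof <- compute_gof(X, Y, sel$lambda)
    list(sv = sv, Yt = Yt, n_y = nrow(Y), n_s = ncol(Y),
         lambda = sel$lambda, gof = gof$gof_percent)
  })
  grid <- sort(grid)
  null_gofs <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, length(prep))
    for (b in seq_len(n_perm)) {
      for (j in seq_along(prep)) {
        pr <- prep[[j]]
        perm <- sample.int(pr$n_s)
        sv_p <- list(u = pr$sv$u, d = pr$sv$d,
                     v = pr$sv$v[perm, , drop = FALSE], rank = pr$sv$rank)
        VtYt <- crossprod(sv_p$v, pr$Yt)
        obj <- if (reselect_lambda) {
          min(vapply(grid, function(a)
            loocv_components(sv_p, pr$Yt, VtYt, a)$objective, numeric(1L)))
        } else {
          loocv_components(sv_p, pr$Yt, VtYt, pr$lambda)$objective
        }
        out[b, j] <- 100 * (1 - obj / (pr$n_y * pr$n_s))
      }
    }
    as.vector(out)
  })
  observed <- tibble::tibble(
    subject = seq_along(prep),
    lambda = vapply(prep, `[[`, numeric(1L), "lambda"),
    gof = vapply(prep, `[[`, numeric(1L), "gof"))
  observed$null_percentile <- vapply(observed$gof, function(g)
    100 * mean(null_gofs < g), numeric(1L))
  ks <- suppressWarnings(ks.test(observed$gof, null_gofs))
  list(observed = observed, null_gofs = null_gofs,
       p_value = unname(ks$p.value), n_perm = n_perm)
}

#' Representational dissimilarity matrix
#'
#' Pairwise correlation distances (`1 - Pearson r` across voxels) between
#' the stimulus patterns of one region: symmetric, zero diagonal, entries
#' in `[0, 2]`.
#'
#' @param m A pattern matrix (voxels x stimuli), at least 3 stimuli.
#' @return An `rdm` matrix (`N_s x N_s`).
#' @export
rdm <- function(m) {
  m <- unclass(as_pattern_matrix(m, normalised = is_normalised(m)))
  if (ncol(m) < 3L) stop("need at least 3 stimuli for an RDM", call. = FALSE)
  if (any(apply(m, 2L, sd) == 0)) {
    stop("constant stimulus pattern: correlation distance undefined",
         call. = FALSE)
  }
  d <- 1 - cor(m)
  diag(d) <- 0
  structure(d, class = c("rdm", "matrix", "array"))
}

#' Linearly predicted representational dissimilarity (LPRD)
#'
#' Correlation between the lower-triangular parts of the RDM of the actual
#' output patterns and the RDM of the linearly predicted output patterns
#' `Y_hat = T_hat X`. An RDM-level alternative to the GOF: how much of the
#' representational geometry survives the linear mapping.
#'
#' @param y Actual output patterns (voxels x stimuli).
#' @param y_pred Predicted output patterns of the same dimensions.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Scalar correlation.
#' @export
lprd <- function(y, y_pred, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  r1 <- unclass(rdm(y))
  r2 <- unclass(rdm(y_pred))
  stopifnot(identical(dim(r1), dim(r2)))
  lt <- lower.tri(r1)
  cor(r1[lt], r2[lt], method = method)
}

#' Animacy-by-fit contingency analysis of per-stimulus GOF
#'
#' Splits stimuli at the arithmetic mean of the per-stimulus GOF values and
#' cross-tabulates above-mean fit against an annotation class (animacy by
#' default), testing the association with a two-sided Fisher exact
#' (hypergeometric) test. Ties at the mean count as "not above".
#'
#' @param per_stimulus_gof Named numeric vector of per-stimulus GOF values
#'   (names are stimulus ids), e.g. from [fit_transform()].
#' @param stimuli Stimulus table covering those ids.
#' @param by Annotation column to split on, `"animacy"` or `"category"`.
#' @return A list with `counts` (classes x above/not-above matrix) and
#'   `p_value`.
#' @export
gof_category_contingency <- function(per_stimulus_gof, stimuli,
                                     by = c("animacy", "category")) {
  by <- match.arg(by)
  stimuli <- as.data.frame(stimuli)
  ids <- names(per_stimulus_gof)
  if (is.null(ids)) stop("per_stimulus_gof must be named by stimulus id",
                         call. = FALSE)
  idx <- match(ids, stimuli$stimulus_id)
  if (anyNA(idx)) stop("stimulus table does not annotate all stimuli",
                       call. = FALSE)
  cls <- stimuli[[by]][idx]
  keep <- !cls %in% c("unknown", "other")
  cls <- cls[keep]
  gof <- per_stimulus_gof[keep]
  if (length(unique(cls)) < 2L) {
    stop("need at least two non-empty classes for the contingency test",
         call. = FALSE)
  }
  above <- factor(gof > mean(per_stimulus_gof),
                  levels = c(TRUE, FALSE),
                  labels = c("above_mean", "not_above"))
  counts <- table(class = cls, fit = above)
  if (any(rowSums(counts) == 0)) stop("empty class in contingency table",
                                      call. = FALSE)
  list(counts = unclass(counts),
       p_value = fisher.test(counts, alternative = "two.sided")$p.value)
}
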