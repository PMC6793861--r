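#' Tidy a fitted pattern transformation
#'
#' One row per stimulus: the cross-validated squared residual and the
#' per-stimulus GOF (`100 (1 - r_i / N_Y)`), whose mean equals the overall
#' GOF.
#'
#' @param x A `transform_fit` from [fit_transform()].
#' @param ... Unused.
#' @return A tibble with columns `stimulus_id`, `sq_residual`, `gof`.
#' @method tidy transform_fit
#' @export
tidy.transform_fit <- function(x, ...) {
  tibble::tibble(
    stimulus_id = x$stimulus_ids %||% paste0("s", seq_len(x$n_stimuli)),
    sq_residual = unname(x$per_stimulus_sq_residual),
    gof = unname(x$per_stimulus_gof))
}

#' Summarise a fitted pattern transformation in one row
#'
#' @inheritParams tidy.transform_fit
#' @return A one-row tibble: `lambda`, `gof`, `n_in`, `n_out`, `n_stimuli`,
#'   `method`.
#' @method glance transform_fit
#' @export
glance.transform_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, gof = x$gof_percent,
                 n_in = x$n_in, n_out = x$n_out,
                 n_stimuli = x$n_stimuli, method = x$method)
}

#' @rdname tidy.transform_fit
#' @method tidy cross_session_result
#' @export
tidy.cross_session_result <- function(x, ...) {
  dplyr::bind_rows(
    x$directions,
    tibble::tibble(direction = "mean", lambda = NA_real_,
                   gof = x$gof, rdd = x$rdd, rdsv = x$rdsv))
}

#' @rdname glance.transform_fit
#' @method glance cross_session_result
#' @export
glance.cross_session_result <- function(x, ...) {
  tibble::tibble(gof = x$gof, rdd = x$rdd, rdsv = x$rdsv)
}

#' @rdname glance.transform_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, fit_residual = x$fit_residual)
}
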