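#' Plot a density curve
#'
#' Density of the max-abs-normalised transformation against the threshold;
#' steeper decay indicates a sparser underlying mapping.
#'
#' @param object A [density_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_curve
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold P", y = "density d(P)") +
    ggplot2::theme_minimal()
}

#' Plot calibration curves in the (GOF, decay) plane
#'
#' One curve per simulated level, traced across the noise fractions;
#' optionally overlays an observed (GOF, decay) point to show where it
#' falls between curves.
#'
#' @param object A [calibrate()] grid.
#' @param observed Optional one-row data frame with columns `gof`, `decay`
#'   (e.g. from [metrics_at_lambda()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_grid
#' @export
autoplot.calibration_grid <- function(object, observed = NULL, ...) {
  kind <- attr(object, "kind")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$mean_gof, y = .data$mean_decay,
                                    colour = factor(.data$level),
                                    group = factor(.data$level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "mean GOF (%)",
                  y = if (identical(kind, "sparsity")) "mean RDD" else "mean RDSV",
                  colour = if (identical(kind, "sparsity")) "sparsity (%)" else "SV decay b") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = as.data.frame(observed),
                                 ggplot2::aes(x = .data$gof, y = .data$decay),
                                 inherit.aes = FALSE, shape = 15, size = 3)
  }
  p
}

#' Plot per-stimulus goodness-of-fit
#'
#' @param object A `transform_fit`.
#' @param ... Unused.
#' @return A ggplot of per-stimulus GOF with the overall GOF as a reference
#'   line.
#' @method autoplot transform_fit
#' @export
autoplot.transform_fit <- function(object, ...) {
  td <- tidy(object)
  td$stimulus <- seq_len(nrow(td))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$stimulus, y = .data$gof)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = object$gof_percent, linetype = 2) +
    ggplot2::labs(x = "stimulus", y = "per-stimulus GOF (%)") +
    ggplot2::theme_minimal()
}

#' Plot a representational dissimilarity matrix
#'
#' @param object An [rdm()] matrix.
#' @param ... Unused.
#' @return A ggplot tile map of correlation distances.
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$distance <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r") +
    ggplot2::theme_minimal()
}
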