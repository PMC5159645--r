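# ggplot2 views of the result objects.

#' Density plot of held-out predictions
#'
#' @param object An `rnasa_cv` result.
#' @param n_bins Bins per axis (default 40).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rnasa_cv <- function(object, n_bins = 40, ...) {
  d <- density_table(object$predictions, n_bins = n_bins)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$actual_mid, y = .data$pred_mid,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "actual ASA (normalized)", y = "predicted ASA (normalized)",
      title = sprintf("Held-out predictions, pooled r = %.3f", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Bin-mean association plot
#'
#' @param object An `rnasa_maf` result.
#' @param ... Unused.
#' @return A ggplot of mean log10(MAF) against mean predicted ASA per bin.
#' @export
autoplot.rnasa_maf <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mean_pred, y = .data$mean_log_maf)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "mean predicted ASA (bin)", y = "mean log10 MAF (bin)",
      title = sprintf("MAF-bin association, r = %.3f", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Transcript boundary profile plot
#'
#' @param object An `rnasa_boundary` result.
#' @param ... Unused.
#' @return A ggplot of mean ASA against offset, faceted by boundary type.
#' @export
autoplot.rnasa_boundary <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset, y = .data$mean_asa)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = -0.5, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~boundary) +
    ggplot2::labs(x = "offset from boundary (bases)", y = "mean predicted ASA") +
    ggplot2::theme_minimal()
}
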