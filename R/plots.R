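# ggplot2 views of the pipeline's result objects.

#' @method autoplot wavemics_eval_grid
#' @export
autoplot.wavemics_eval_grid <- function(object, metric = "auc", ...) {
  g <- object[object$bank != "none", ]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$classifier, y = .data$bank,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "classifier", y = "filter bank",
                  title = sprintf("Mean %s over repeated CV", metric)) +
    ggplot2::theme_minimal()
}

#' @method autoplot wavemics_icc
#' @export
autoplot.wavemics_icc <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.75
  long <- tidyr::pivot_longer(object, c("icc_intra", "icc_inter"),
                              names_to = "type", values_to = "icc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$icc, fill = .data$type)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "ICC(2,1)", y = "features",
                  title = "Feature reliability across repeated segmentations") +
    ggplot2::theme_minimal()
}

#' Plot per-classifier wavelet-vs-plain comparison
#'
#' @param comparison A tibble from [comparison_table()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, c("wavelet", "plain"),
                              names_to = "model", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "classifier", y = "metric",
                  title = "Best wavelet model vs plain radiomics model") +
    ggplot2::theme_minimal()
}
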