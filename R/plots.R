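#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation sweep result
#'
#' Boxplots of per-replicate AUROC against the swept condition (series
#' length or sampling interval), one panel per measure.
#'
#' @param object a `sweep_result` from [run_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  xlab <- if (object$mode[1] == "length") {
    "series length (timepoints)"
  } else {
    "sampling interval"
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$value), y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = xlab, y = "AUROC") +
    ggplot2::theme_bw()
}

#' Plot benchmark results by measure
#'
#' AUROC distributions across datasets for each measure, coloured by
#' filter, faceted by network and association mode.
#'
#' @param object a `benchmark_result` from [run_benchmark()].
#' @param metric column to plot (default `"auroc"`).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_result <- function(object, metric = "auroc", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$measure, y = .data[[metric]],
                               fill = .data$filter)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = if (metric == "auroc") 0.5 else 0,
                        linetype = 2, colour = "red3") +
    ggplot2::facet_grid(network ~ mode) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a permutation null distribution
#'
#' @param object a `perm_result` from [permutation_pvalue()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(auc = object$null_aucs),
                  ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red3") +
    ggplot2::labs(x = "null AUROC",
                  subtitle = paste0("p = ", object$p_value)) +
    ggplot2::theme_bw()
}
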