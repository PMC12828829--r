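# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot
#'
#' @param object A `lipid_volcano` object.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 p with the fold-change and
#'   significance guide lines.
#' @exportS3Method
autoplot.lipid_volcano <- function(object, ...) {
  d <- object$results[!is.na(object$results$p), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p),
                                  colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "flagged") +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `lipid_pca` object.
#' @param colour Optional vector (named by sample id) used to colour points.
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @exportS3Method
autoplot.lipid_pca <- function(object, colour = NULL, ...) {
  s <- object$scores
  pcs <- setdiff(names(s), "sample_id")[1:2]
  if (!is.null(colour)) s$colour <- unname(colour[s$sample_id])
  p <- ggplot2::ggplot(s, ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]]))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2) +
      ggplot2::labs(colour = "group")
  }
  p +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * object$explained_variance[1]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * object$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}

#' Hydrolysis time-course plot
#'
#' @param normalized Output of [normalize_baseline()] over
#'   [hydrolysis_ratios()] (columns `pair`, `time_min`, `normalized_pct`).
#' @return A ggplot of normalized ratios over storage time, one panel per
#'   degradation/precursor pair, with the 100% baseline marked.
#' @export
plot_timecourse <- function(normalized) {
  ggplot2::ggplot(normalized,
                  ggplot2::aes(.data$time_min, .data$normalized_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted") +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "storage time (min)", y = "normalized ratio (%)") +
    ggplot2::theme_minimal()
}

#' Partition fraction plot
#'
#' @param fractions Output of [partition_fractions()].
#' @return A ggplot of MeOH-rich phase fractions vs water content per class.
#' @export
plot_partition <- function(fractions) {
  d <- fractions[!is.na(fractions$fraction_meoh), ]
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$water_pct), .data$fraction_meoh)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::facet_wrap(~class_label) +
    ggplot2::labs(x = "water in MeOH (% v/v)", y = "MeOH-rich phase fraction") +
    ggplot2::theme_minimal()
}
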