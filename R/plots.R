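# ggplot2 diagnostics for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a window enrichment scan
#'
#' -log10 Q-value per window along each scaffold, enriched windows
#' highlighted.
#'
#' @param object A `window_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_enrichment <- function(object, ...) {
  df <- tidy(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid / 1e6,
                                   -log10(pmax(.data$qvalue, 1e-300)),
                                   color = .data$enriched)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = "-log10 Q",
                  color = "enriched",
                  title = paste0("Window enrichment (",
                                 attr(object, "sex") %||% "?", ")"))
}

#' Plot classified coverage bins
#'
#' Per-bin male vs female mean normalized coverage, colored by class.
#'
#' @param object A `coverage_class`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_class <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$mean_M, .data$mean_F,
                               color = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "male mean normalized coverage",
                  y = "female mean normalized coverage", color = "class")
}

#' Plot a bidirectional YGS scan
#'
#' Per-contig P_VSC_UK in the XY direction against the ZW direction, with
#' the flagging threshold and the ~50% anomaly band.
#'
#' @param object A `ygs_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ygs_scan <- function(object, ...) {
  df <- tidy(object)
  thr <- attr(object$xy, "threshold")
  band <- object$bidir$band
  ggplot2::ggplot(df, ggplot2::aes(.data$p_xy, .data$p_zw)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = band[1], ymax = band[2],
                      alpha = 0.15, fill = "orange") +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged_xy |
                                       .data$flagged_zw)) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::labs(x = "P_VSC_UK, XY direction (%)",
                  y = "P_VSC_UK, ZW direction (%)", color = "flagged")
}

#' Plot sample PCA coordinates
#'
#' @param object A `pca_profiles`.
#' @param sex Optional named `"M"`/`"F"` vector to color samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_profiles <- function(object, sex = NULL, ...) {
  df <- object$scores
  df$sex <- if (is.null(sex)) "sample" else unname(sex[df$sample_id])
  ev <- round(100 * object$explained_variance, 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   color = .data$sex)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)"))
}
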