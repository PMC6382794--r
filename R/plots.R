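#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an aligned landmark set
#'
#' Scatter of all aligned configurations with the consensus shape overlaid.
#'
#' @param object A `gpa_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble::tibble(landmark = seq_len(nrow(object$consensus)),
                         x = object$consensus[, 1L], y = object$consensus[, 2L])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned configurations",
                  subtitle = "red: consensus shape") +
    ggplot2::theme_minimal()
}

#' Morphospace scatter with group hulls
#'
#' Scores of the first two principal components, with per-group convex hulls
#' when the PCA was fitted with groups.
#'
#' @param object A `shape_pca`.
#' @param axes Which two axes to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pca <- function(object, axes = c(1L, 2L), ...) {
  df <- tibble::tibble(
    PC1 = object$scores[, axes[1L]], PC2 = object$scores[, axes[2L]],
    group = if (is.null(object$groups)) "all" else as.character(object$groups))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", axes[1L], object$percent_variance[axes[1L]]),
      y = sprintf("PC%d (%.1f%%)", axes[2L], object$percent_variance[axes[2L]])) +
    ggplot2::theme_minimal()
  if (!is.null(object$hulls) && identical(axes, c(1L, 2L))) {
    p <- p + ggplot2::geom_polygon(
      data = object$hulls,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group,
                   group = .data$group),
      fill = NA, linewidth = 0.4)
  }
  p
}

#' Paired PLS axis scores
#'
#' @param object A `shape_pls`.
#' @param axis Which axis pair to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pls <- function(object, axis = 1L, ...) {
  df <- tibble::tibble(block1 = object$scores1[, axis],
                       block2 = object$scores2[, axis])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block1, y = .data$block2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Block 1, PLS%d", axis), y = sprintf("Block 2, PLS%d", axis),
      title = sprintf("PLS axis %d: %.1f%% of covariance (RV = %.3f)",
                      axis, object$percent_covariance[axis], object$rv)) +
    ggplot2::theme_minimal()
}

#' Modularity null distribution
#'
#' Histogram of the RVs of alternative landmark partitions with the observed
#' RV marked; modularity is supported when the observed value falls in the
#' lower tail.
#'
#' @param object A `modularity_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.modularity_test <- function(object, ...) {
  df <- tibble::tibble(rv = object$alternatives)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_rv, colour = "firebrick") +
    ggplot2::labs(
      x = "RV of alternative partitions",
      title = sprintf("Observed RV = %.3f; proportion <= observed: %.3f",
                      object$observed_rv, object$proportion_leq)) +
    ggplot2::theme_minimal()
}

#' Shape-change vectors along a direction
#'
#' Displacement vectors from the consensus along a loading/regression
#' direction, the numeric substitute for warped-outline graphics.
#'
#' @param consensus k x 2 consensus shape.
#' @param direction Length-2k direction (e.g. a PCA loading column).
#' @param magnitude Score magnitude at which to draw the displacement.
#' @return A ggplot.
#' @export
plot_shape_change <- function(consensus, direction, magnitude = 0.1) {
  d <- unflatten_config(direction * magnitude)
  df <- tibble::tibble(x = consensus[, 1L], y = consensus[, 2L],
                       xend = consensus[, 1L] + d[, 1L],
                       yend = consensus[, 2L] + d[, 2L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Shape change at score %+g", magnitude)) +
    ggplot2::theme_minimal()
}
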