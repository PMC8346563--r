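#' Plot a fundus sample with its ground truth and detections
#'
#' Renders the image as a raster with the ground-truth object boxes (solid)
#' and, optionally, detection boxes (dashed, coloured by confidence).
#'
#' @param sample A `fundus_sample` (or a list with `image` and `mask`).
#' @param detections Optional detection tibble in image coordinates.
#' @return A ggplot object.
#' @export
plot_fundus <- function(sample, detections = NULL) {
  img <- sample$image / 255
  h <- dim(img)[1]; w <- dim(img)[2]
  raster <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(raster) <- c(h, w)
  gt <- mask_to_objects(sample$mask)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (nrow(gt) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gt, colour = "yellow", fill = NA, linewidth = 0.4,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = -.data$y1, ymax = -.data$y0))
  }
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_rect(
      data = detections, fill = NA, linetype = "dashed", linewidth = 0.4,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = -.data$y1, ymax = -.data$y0,
                   colour = .data$score)) +
      ggplot2::scale_colour_gradient(low = "red", high = "cyan",
                                     limits = c(0, 1))
  }
  p
}

#' Plot an ROC curve from image scores
#'
#' @param scores Numeric per-image scores.
#' @param labels Logical per-image labels.
#' @return A ggplot object; the AUC is shown in the subtitle.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  auc <- roc_auc(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Image-level ROC",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated metrics for a pipeline run
#'
#' @param object An `exu_cv_run`.
#' @param ... Unused.
#' @return A ggplot object: per-metric mean with +/- 1 sd error bars at
#'   both evaluation levels.
#' @export
autoplot.exu_cv_run <- function(object, ...) {
  df <- bind_rows(mutate(object$exudate_summary, level = "exudate"),
                  mutate(object$image_summary, level = "image"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = NULL, y = "mean over folds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
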