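# ggplot2 views of the main result types.

#' Plot a rendered pill with its ground-truth character boxes
#'
#' @param object A `pill_render`.
#' @param boxes Overlay the ground-truth character boxes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pill_render
#' @export
autoplot.pill_render <- function(object, boxes = TRUE, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  raster <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(raster) <- c(h, w)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = 1, ymin = 0, ymax = 1) +
    ggplot2::coord_fixed(ratio = h / w, xlim = c(0, 1), ylim = c(0, 1),
                         expand = FALSE) +
    ggplot2::labs(title = paste0(object$record$shape, " ",
                                 object$record$color, " ",
                                 object$record$form, "  '",
                                 object$record$imprint, "'")) +
    ggplot2::theme_void()
  if (boxes && nrow(object$boxes) > 0) {
    b <- object$boxes
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(b),
      ggplot2::aes(xmin = .data$x_center - .data$width / 2,
                   xmax = .data$x_center + .data$width / 2,
                   ymin = 1 - (.data$y_center + .data$height / 2),
                   ymax = 1 - (.data$y_center - .data$height / 2)),
      fill = NA, colour = "red", linewidth = 0.3)
  }
  p
}

#' Plot a ranking as stacked similarity terms
#'
#' One bar per candidate, stacked by the five similarity terms, so the
#' score composition of each ranked pill is visible at a glance.
#'
#' @param object A `pill_ranking` tibble from [rank_database()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pill_ranking
#' @export
autoplot.pill_ranking <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object)[, c("pill_id", "shape_term", "color_term",
                              "form_term", "edit_sim", "overlap_sim")],
    -"pill_id", names_to = "term", values_to = "value")
  df$term <- factor(df$term, levels = c("overlap_sim", "edit_sim",
                                        "form_term", "color_term",
                                        "shape_term"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pill_id,
                                                      .data$value,
                                                      function(v) -sum(v)),
                                   y = .data$value, fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "candidate", y = "similarity score", fill = "term") +
    ggplot2::theme_minimal()
}

#' Plot a training-loss curve
#'
#' @param object A fitted `detector_model`, `feature_model` or
#'   `corrector_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot corrector_model
#' @export
autoplot.corrector_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.corrector_model
#' @method autoplot detector_model
#' @export
autoplot.detector_model <- autoplot.corrector_model

#' @rdname autoplot.corrector_model
#' @method autoplot feature_model
#' @export
autoplot.feature_model <- autoplot.corrector_model

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
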