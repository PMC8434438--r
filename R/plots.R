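#' Plot a recognized action timeline
#'
#' Scatter of frame index against action code, optionally overlaying the
#' ground-truth labels, in the style used to inspect continuous recognition
#' results.
#'
#' @param result An `action_recognition` object (or a tibble with `frame`
#'   and `label` columns).
#' @param truth Optional integer vector of ground-truth labels.
#' @return A ggplot object.
#' @export
plot_action_timeline <- function(result, truth = NULL) {
  df <- if (inherits(result, "action_recognition")) result$frames else result
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$label)) +
    ggplot2::geom_point(ggplot2::aes(colour = "predicted"),
                        size = 0.8, na.rm = TRUE)
  if (!is.null(truth)) {
    tdf <- tibble::tibble(frame = seq_along(truth), label = truth)
    p <- p + ggplot2::geom_point(data = tdf,
                                 ggplot2::aes(colour = "truth"),
                                 size = 0.8, shape = 3, na.rm = TRUE)
  }
  p +
    ggplot2::scale_y_continuous(breaks = 0:7,
                                labels = paste(0:7, names(action_labels()))) +
    ggplot2::scale_colour_manual(NULL,
                                 values = c(predicted = "red", truth = "darkgreen")) +
    ggplot2::labs(x = "frame (s at 1 fps)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @rdname plot_action_timeline
#' @param object,... `autoplot` method arguments.
autoplot.action_recognition <- function(object, truth = NULL, ...) {
  plot_action_timeline(object, truth = truth)
}

#' Plot a region map
#'
#' Raster view of the floor / bed / ignored partition.
#'
#' @param regions A `region_map`.
#' @return A ggplot object.
#' @export
plot_region_map <- function(regions) {
  lab <- regions$labels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    region = as.vector(lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(floor = "#4daf4a", bed = "#377eb8",
                                          ignored = "grey80")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @rdname plot_region_map
#' @param object,... `autoplot` method arguments.
autoplot.region_map <- function(object, ...) plot_region_map(object)

#' Plot a depth frame
#'
#' Raster view of one depth frame (blue near, red far), matching the usual
#' colour convention of depth-camera viewers.
#'
#' @param frame Depth matrix.
#' @return A ggplot object.
#' @export
plot_depth_frame <- function(frame) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(frame)), ncol(frame)),
    col = rep(seq_len(ncol(frame)), each = nrow(frame)),
    depth = as.vector(frame))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colours = c("navy", "cyan", "yellow", "red"),
                                  name = "depth (m)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
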