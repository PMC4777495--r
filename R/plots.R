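#' Plot a motion trace with its reference points
#'
#' Draws the 2D path of a motion trace in image coordinates (y axis
#' reversed so the figure appears upright). When a segmentation is given,
#' the chain of reference points is overlaid, making the detected
#' direction-change units visible.
#'
#' @param trace Tibble `frame, x, y`.
#' @param segments Optional result of [segment_maxima()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, segments = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey50", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    ref_frames <- c(segments$ref_frame[1], segments$max_frame)
    refs <- trace[match(ref_frames, trace$frame), ]
    p <- p +
      ggplot2::geom_path(data = refs, colour = "firebrick", linewidth = 0.6) +
      ggplot2::geom_point(data = refs, colour = "firebrick", size = 1.5)
  }
  p
}

#' Plot the distribution of motion features across stimuli
#'
#' One panel per measure; useful for eyeballing a generated stimulus set
#' before planting ratings or choices on it.
#'
#' @param features Tibble from [extract_features()].
#' @return A ggplot object.
#' @export
plot_features <- function(features) {
  long <- tidyr::pivot_longer(
    features,
    dplyr::any_of(c("n_maxima", "avg_velocity", "avg_turn_angle", "avg_bodypart_angle")),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "stimuli") +
    ggplot2::theme_minimal()
}

#' @rdname analyze_choices
#' @param object An `angulate_choices` table.
#' @param ... Unused.
#' @export
autoplot.angulate_choices <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$p_hat)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.15
    ) +
    ggplot2::geom_hline(yintercept = df$p0[1], linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"), limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion consistent with prediction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
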