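#' Plot methods
#'
#' `autoplot()` methods give a quick look at each result type: the phase
#' ribbon of a timeline, the channel traces of a recording, the
#' row-normalized confusion heatmap of an evaluation, and the per-dataset
#' precision of a benchmark.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gait_plots
NULL

#' @rdname gait_plots
#' @export
autoplot.gait_timeline <- function(object, ...) {
  df <- tibble::tibble(time = object$time, phase = object$phase,
                       body_x = object$body_x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_tile(ggplot2::aes(y = 0.5, fill = .data$phase), height = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$body_x), linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "body x (normalized)",
                  fill = "phase") +
    ggplot2::theme_minimal()
}

#' @param channels Channel names to show (default: first four).
#' @rdname gait_plots
#' @export
autoplot.gait_recording <- function(object, channels = NULL, ...) {
  if (is.null(channels)) channels <- head(recording_channels(object), 4)
  df <- tidyr::pivot_longer(
    as.data.frame(object)[, c("time", channels)],
    -"time", names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname gait_plots
#' @export
autoplot.gait_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion_rownorm)
  names(df) <- c("truth", "predicted", "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true label", fill = "rate") +
    ggplot2::theme_minimal()
}

#' @rdname gait_plots
#' @export
autoplot.gait_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$precision,
                  ggplot2::aes(.data$dataset, .data$macro_precision,
                               fill = .data$algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "macro precision") +
    ggplot2::theme_minimal()
}
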