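# ggplot2 methods for the package's result types.

#' Plot a collar acceleration signal
#'
#' Tri-axial acceleration traces over time, one panel per axis, optionally
#' shaded by behavior bout.
#'
#' @param object A `signal_frame`.
#' @param bouts Optional bout tibble used to shade behaviors.
#' @param animal Animal to plot; defaults to the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_frame <- function(object, bouts = NULL, animal = NULL, ...) {
  animal <- animal %||% object$animal_id[1L]
  df <- object[object$animal_id == animal, , drop = FALSE] |>
    tidyr::pivot_longer(c("ax", "ay", "az"), names_to = "axis", values_to = "g")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$g))
  if (!is.null(bouts)) {
    bb <- bouts[bouts$animal_id == animal, , drop = FALSE]
    p <- p + ggplot2::geom_rect(
      data = bb, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_utc, xmax = .data$end_utc,
                   ymin = -Inf, ymax = Inf, fill = .data$behavior),
      alpha = 0.25)
  }
  p + ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s, UTC)", y = "acceleration (g)",
                  title = paste("Collar acceleration:", animal)) +
    ggplot2::theme_minimal()
}

#' Plot an experiment curve
#'
#' Mean line with a +/- sd ribbon against window size or data proportion,
#' faceted by metric.
#'
#' @param object An `experiment_curve`.
#' @param metric Metrics to show (default overall accuracy).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_curve <- function(object, metric = "accuracy", ...) {
  df <- object[object$metric %in% metric, , drop = FALSE]
  df$series <- ifelse(is.na(df$class), df$metric, paste(df$metric, df$class, sep = ": "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean,
                                   color = .data$series, fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = if (all(df$experiment == "data_reduction"))
      "proportion of data retained" else "smoothing window (s)",
      y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot behavior composition
#'
#' Bar chart of per-behavior time shares from [summarize_ethogram()].
#'
#' @param shares Tibble from [summarize_ethogram()] or [behavior_shares()].
#' @return A ggplot object.
#' @export
plot_ethogram <- function(shares) {
  if (!("source" %in% names(shares))) shares$source <- "all"
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$behavior, y = .data$share_pct,
                                       fill = .data$behavior)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(x = NULL, y = "share of observed time (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Accuracy %.3f (n = %d)", object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}
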