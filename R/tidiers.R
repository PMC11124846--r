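# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a behavior classifier
#'
#' One row per feature with its impurity importance (when available) or the
#' feature schema order otherwise.
#'
#' @param x A `behavior_classifier`.
#' @param ... Unused.
#' @return A tibble: `feature`, `importance`.
#' @export
tidy.behavior_classifier <- function(x, ...) {
  imp <- x$fit$variable.importance
  tibble::tibble(feature = x$schema,
                 importance = if (is.null(imp)) NA_real_ else unname(imp[x$schema]))
}

#' Glance at a behavior classifier
#'
#' @param x A `behavior_classifier`.
#' @param ... Unused.
#' @return One-row tibble: trees, features, classes, out-of-bag error.
#' @export
glance.behavior_classifier <- function(x, ...) {
  tibble::tibble(num_trees = x$num_trees,
                 n_features = length(x$schema),
                 n_classes = length(x$classes),
                 oob_error = x$fit$prediction.error)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class metric tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' Glance at a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with `n` and overall `accuracy`.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy)
}
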