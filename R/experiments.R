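# Experiment drivers: smoothing-window sweep, structured data-reduction
# bootstrap, and observation-source comparison.

new_experiment_curve <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- c("experiment_curve", class(out))
  out
}

# One split/train/evaluate replicate; returns a long tibble of metrics.
fit_and_score <- function(table, seed, num_trees = 150, train_fraction = 0.7,
                          stratify_by = c("animal_id", "behavior")) {
  sp <- split_train_test(table, train_fraction = train_fraction,
                         stratify_by = stratify_by, seed = seed)
  if (length(unique(sp$train$behavior)) < 2) return(NULL)
  m <- train_classifier(sp$train, num_trees = num_trees, seed = seed)
  rep_ <- evaluate_classifier(m, sp$test)
  dplyr::bind_rows(
    tibble::tibble(metric = "accuracy", class = NA_character_, value = rep_$accuracy),
    rep_$per_class |>
      tidyr::pivot_longer(c("sensitivity", "specificity", "precision"),
                          names_to = "metric", values_to = "value") |>
      dplyr::select("metric", "class", "value"))
}

summarise_replicates <- function(reps, experiment, x, scheme, seed) {
  reps |>
    dplyr::group_by(.data$metric, .data$class) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value, na.rm = TRUE) else 0,
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(experiment = experiment, x = x, scheme = scheme,
                  stderr = .data$sd / sqrt(.data$n_replicates), seed = seed) |>
    dplyr::select("experiment", "x", "metric", "class", "scheme",
                  "mean", "sd", "stderr", "n_replicates", "seed")
}

#' Precompute feature tables for several smoothing windows
#'
#' @param frame A `signal_frame`.
#' @param epochs Labeled epoch tibble.
#' @param windows Integer vector of window sizes, seconds.
#' @param ... Passed to [window_features()].
#' @return Named list of labeled feature tibbles, one per window.
#' @export
features_by_window <- function(frame, epochs, windows = c(1, 2, 5, 10, 15, 20, 30, 60), ...) {
  stats::setNames(
    lapply(windows, function(w) extract_features(frame, epochs, window_s = w, ...)),
    as.character(windows))
}

#' Smoothing-window sweep
#'
#' For each smoothing window size: extract features, then repeatedly split
#' 70/30, train and evaluate; curves of mean +/- sd accuracy and per-class
#' sensitivity/specificity/precision against window size.
#'
#' @param frame A `signal_frame`; ignored when `feature_tables` is given.
#' @param epochs Labeled epoch tibble; ignored when `feature_tables` is given.
#' @param windows Window sizes to sweep, seconds.
#' @param scheme Label grouping scheme (see [grouping_scheme()]).
#' @param n_seeds Replicate splits per window.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param num_trees Trees per forest (default 150; see the methods vignette).
#' @param feature_tables Optional precomputed output of [features_by_window()]
#'   so several sweeps can share one extraction pass.
#' @param ... Passed to [window_features()].
#' @return An `experiment_curve` tibble.
#' @export
window_sweep <- function(frame = NULL, epochs = NULL,
                         windows = c(1, 2, 5, 10, 15, 20, 30, 60),
                         scheme = "full", n_seeds = 10, seed = 1L,
                         num_trees = 150, feature_tables = NULL, ...) {
  if (is.null(feature_tables)) {
    feature_tables <- features_by_window(frame, epochs, windows, ...)
  }
  purrr::map_dfr(names(feature_tables), function(wname) {
    tab <- group_labels(feature_tables[[wname]], scheme)
    if (nrow(tab) == 0 || length(unique(tab$behavior)) < 2) {
      warning("window ", wname, " produced an unusable feature table; skipped")
      return(NULL)
    }
    reps <- purrr::map_dfr(seq_len(n_seeds), function(r) {
      fit_and_score(tab, seed = child_seed(seed, r), num_trees = num_trees)
    })
    summarise_replicates(reps, "window_sweep", as.numeric(wname), scheme, seed)
  }) |>
    new_experiment_curve()
}

#' Structured subsample of a feature table
#'
#' Retains a proportion `p` of rows within every (animal, behavior) cell
#' (rounded half up), sampling without replacement, so the subsample
#' preserves each animal's behavior composition.
#'
#' @param table Labeled feature tibble.
#' @param p Proportion to retain, in (0, 1]. `p = 1` returns the table
#'   unchanged.
#' @param seed Integer seed.
#' @return Subsampled tibble.
#' @export
structured_subsample <- function(table, p, seed = 1L) {
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (p == 1) return(table)
  withr::with_seed(seed, {
    table |>
      dplyr::group_by(.data$animal_id, .data$behavior) |>
      dplyr::group_modify(function(df, key) {
        n_keep <- round_half_up(p * nrow(df))
        if (n_keep == 0) return(df[0, , drop = FALSE])
        df[sort(sample.int(nrow(df), n_keep)), , drop = FALSE]
      }) |>
      dplyr::ungroup()
  })
}

#' Structured data-reduction bootstrap
#'
#' For each retention proportion, runs `B` replicates of
#' subsample -> 70/30 split -> train -> evaluate, yielding learning curves of
#' mean +/- sd (and standard error) for accuracy and per-class metrics. The
#' full replicate table is attached as the `"replicates"` attribute.
#'
#' @param table Labeled feature tibble (one window size).
#' @param proportions Retention grid in (0, 1].
#' @param B Bootstrap replicates per proportion.
#' @param scheme Label grouping scheme.
#' @param seed Base seed.
#' @param num_trees Trees per forest.
#' @return An `experiment_curve` tibble.
#' @export
data_reduction_experiment <- function(table,
                                      proportions = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                                      B = 25, scheme = "full", seed = 1L,
                                      num_trees = 150) {
  stopifnot(all(proportions > 0 & proportions <= 1), B >= 1)
  tab <- group_labels(table, scheme)
  all_reps <- list()
  curve <- purrr::map_dfr(proportions, function(p) {
    reps <- purrr::map_dfr(seq_len(B), function(b) {
      s <- child_seed(seed, round(p * 1000) * 1000L + b)
      sub <- structured_subsample(tab, p, seed = s)
      if (length(unique(sub$behavior)) < 2) return(NULL)
      out <- fit_and_score(sub, seed = s, num_trees = num_trees)
      if (is.null(out)) return(NULL)
      dplyr::mutate(out, p = p, replicate = b)
    })
    if (nrow(reps) == 0) {
      warning("proportion ", p, " yields fewer than 2 classes; skipped")
      return(NULL)
    }
    all_reps[[length(all_reps) + 1L]] <<- reps
    summarise_replicates(dplyr::select(reps, -"p", -"replicate"),
                         "data_reduction", p, scheme, seed)
  })
  out <- new_experiment_curve(curve)
  attr(out, "replicates") <- dplyr::bind_rows(all_reps)
  out
}

#' Compare observation sources on size-matched data
#'
#' Trains and evaluates a classifier separately per observation source
#' (in-pasture vs. collar video) on subsets matched to the smaller source's
#' per-behavior counts, and reports per-source metrics and their differences.
#'
#' @param table Labeled feature tibble with a `source` column covering both
#'   sources.
#' @param scheme Label grouping scheme.
#' @param n_reps Replicates (size-matching resample + split seeds).
#' @param seed Base seed.
#' @param num_trees Trees per forest.
#' @return A tibble of per-source mean/sd metrics, with a `delta` block
#'   (first source minus second) in the `"deltas"` attribute.
#' @export
compare_sources <- function(table, scheme = "full", n_reps = 10, seed = 1L,
                            num_trees = 150) {
  tab <- group_labels(table, scheme)
  sources <- sort(unique(tab$source))
  if (length(sources) < 2) stop("both observation sources must be present", call. = FALSE)
  # per-behavior size matching target: the smaller source's counts
  target <- tab |>
    dplyr::count(.data$source, .data$behavior) |>
    dplyr::group_by(.data$behavior) |>
    dplyr::summarise(n_target = min(.data$n), .groups = "drop")
  per_source <- purrr::map_dfr(sources, function(src) {
    sub_all <- dplyr::filter(tab, .data$source == src)
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- child_seed(seed, r)
      matched <- withr::with_seed(s, {
        sub_all |>
          dplyr::inner_join(target, by = "behavior") |>
          dplyr::group_by(.data$behavior) |>
          dplyr::group_modify(function(df, key) {
            df[sample.int(nrow(df), min(nrow(df), df$n_target[1L])), , drop = FALSE]
          }) |>
          dplyr::ungroup() |>
          dplyr::select(-"n_target")
      })
      fit_and_score(matched, seed = s, num_trees = num_trees)
    })
    dplyr::mutate(
      summarise_replicates(reps, "compare_sources", NA_real_, scheme, seed),
      source = src)
  })
  deltas <- per_source |>
    dplyr::select("metric", "class", "source", "mean") |>
    tidyr::pivot_wider(names_from = "source", values_from = "mean") |>
    dplyr::mutate(delta = .data[[sources[1L]]] - .data[[sources[2L]]])
  attr(per_source, "deltas") <- deltas
  per_source
}

#' Locate the plateau of a performance curve
#'
#' The plateau is the smallest `x` whose mean metric is within `rel_tol`
#' (relative) of the curve's maximum.
#'
#' @param curve An `experiment_curve` (or any tibble with `x`, `metric`,
#'   `class`, `mean`).
#' @param metric Metric to inspect (default overall `"accuracy"`).
#' @param class For per-class metrics, the class to inspect.
#' @param rel_tol Relative tolerance (default 0.01).
#' @return The plateau `x` (e.g. window size in seconds).
#' @export
plateau_detect <- function(curve, metric = "accuracy", class = NULL, rel_tol = 0.01) {
  rows <- curve[curve$metric == metric, , drop = FALSE]
  if (!is.null(class)) rows <- rows[!is.na(rows$class) & rows$class == class, , drop = FALSE]
  rows <- rows[order(rows$x), , drop = FALSE]
  if (nrow(rows) == 0) stop("empty curve for metric ", metric, call. = FALSE)
  thr <- (1 - rel_tol) * max(rows$mean)
  rows$x[which(rows$mean >= thr)[1L]]
}

#' Write an experiment curve to CSV
#'
#' Columns `experiment,x,metric,class,scheme,mean,sd,stderr,n_replicates,seed`.
#'
#' @param curve An `experiment_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}
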