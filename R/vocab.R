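#' Behavior vocabulary
#'
#' The closed set of behaviors in the grazing-cattle ethogram: grazing,
#' walking, resting, ruminating, and grooming.
#'
#' @return Character vector of the five behavior labels.
#' @export
behavior_levels <- function() {
  c("grazing", "walking", "resting", "ruminating", "grooming")
}

#' Normalize behavior labels to the ethogram vocabulary
#'
#' Trims whitespace and lower-cases labels, then validates them against
#' [behavior_levels()]. Unknown labels raise an error naming the offenders.
#'
#' @param x Character vector of raw behavior labels.
#' @return Character vector of normalized labels.
#' @export
normalize_behavior <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(out[!is.na(out)]), behavior_levels())
  if (length(bad) > 0) {
    stop("Unknown behavior label(s): ", paste(shQuote(bad), collapse = ", "),
         ". Vocabulary: ", paste(behavior_levels(), collapse = ", "), call. = FALSE)
  }
  out
}

#' Label grouping schemes
#'
#' Returns the label mapping for a grouping scheme:
#' * `full` — the identity mapping over the five-behavior ethogram.
#' * `full4` — the four-behavior ethogram; grooming is dropped (mapped to `NA`).
#' * `activity` — grazing and walking become `active`; resting, ruminating and
#'   grooming become `inactive`.
#' * `grazing_binary` — grazing vs. `non_grazing`.
#'
#' @param name One of `"full"`, `"full4"`, `"activity"`, `"grazing_binary"`.
#' @return Named character vector mapping each behavior to its group
#'   (`NA` marks behaviors excluded by the scheme).
#' @export
grouping_scheme <- function(name = c("full", "full4", "activity", "grazing_binary")) {
  name <- match.arg(name)
  lv <- behavior_levels()
  map <- switch(name,
    full = stats::setNames(lv, lv),
    full4 = stats::setNames(c("grazing", "walking", "resting", "ruminating", NA), lv),
    activity = stats::setNames(
      c("active", "active", "inactive", "inactive", "inactive"), lv),
    grazing_binary = stats::setNames(
      c("grazing", rep("non_grazing", 4)), lv)
  )
  map
}

#' Group behavior labels
#'
#' Relabels the `behavior` column of an epoch or feature table according to a
#' grouping scheme. Rows whose behavior is excluded by the scheme (grooming
#' under `full4`) are dropped.
#'
#' @param data A data frame with a `behavior` column in the ethogram vocabulary.
#' @param scheme Scheme name passed to [grouping_scheme()], or a named
#'   character mapping.
#' @return A tibble with `behavior` replaced by its group label.
#' @export
group_labels <- function(data, scheme = "full") {
  stopifnot(is.data.frame(data), "behavior" %in% names(data))
  map <- if (is.character(scheme) && length(scheme) == 1L && is.null(names(scheme))) {
    grouping_scheme(scheme)
  } else {
    scheme
  }
  missing <- setdiff(unique(data$behavior), names(map))
  if (length(missing) > 0) {
    stop("Behavior label(s) missing from the grouping mapping: ",
         paste(shQuote(missing), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(data),
                       behavior = unname(map[.data$behavior]))
  dplyr::filter(out, !is.na(.data$behavior))
}
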