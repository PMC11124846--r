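# Reading, cleaning and time-aligning observed behavior and sensor data.

# Epoch origin used when serializing numeric seconds to ISO-8601 UTC.
utc_origin <- function() as.POSIXct("1970-01-01", tz = "UTC")

to_utc_seconds <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (is.character(x)) {
    if (all(grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", x[!is.na(x)]))) {
      return(as.numeric(x))
    }
    out <- as.numeric(as.POSIXct(x, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")))
    if (anyNA(out)) stop("Unparseable timestamp(s), e.g. ", x[which(is.na(out))[1L]], call. = FALSE)
    return(out)
  }
  as.numeric(x)
}

format_utc <- function(t) {
  format(utc_origin() + t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

#' Read a collar acceleration CSV
#'
#' Expects columns `animal_id,timestamp_utc,ax_g,ay_g,az_g` (optionally
#' `mx,my,mz`); timestamps either ISO-8601 UTC strings or numeric seconds.
#' Rows are sorted by time per animal; duplicated or non-monotone timestamps
#' raise an error naming the offending row. Recording gaps longer than two
#' sample intervals split the data into separate frames.
#'
#' @param path CSV file path.
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the median
#'   timestamp step.
#' @return A list of `signal_frame` tibbles (one per gap-free segment).
#' @export
read_signal_csv <- function(path, sample_rate = NULL) {
  req <- c("animal_id", "timestamp_utc", "ax_g", "ay_g", "az_g")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(animal_id = "c", timestamp_utc = "c",
                                                .default = "d"))
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) stop("Missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df$t <- to_utc_seconds(df$timestamp_utc)
  frames <- list()
  for (sub in split(df, df$animal_id)) {
    ord <- order(sub$t)
    sub <- sub[ord, ]
    dt <- diff(sub$t)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1L] + 1L
      stop("Non-monotone or duplicated timestamp at row ", bad,
           " for animal ", sub$animal_id[1L], call. = FALSE)
    }
    sr <- sample_rate %||% round(1 / stats::median(dt))
    seg <- cumsum(c(0, dt > 2 / sr))
    for (sg in split(sub, seg)) {
      fr <- tibble::tibble(animal_id = sg$animal_id, t = sg$t,
                           ax = sg$ax_g, ay = sg$ay_g, az = sg$az_g)
      for (m in intersect(c("mx", "my", "mz"), names(sg))) fr[[m]] <- sg[[m]]
      frames[[length(frames) + 1L]] <- new_signal_frame(fr, sr)
    }
  }
  frames
}

#' Write a signal frame to CSV
#'
#' Columns `animal_id,timestamp_utc,ax_g,ay_g,az_g[,mx,my,mz]` with ISO-8601
#' UTC timestamps at millisecond precision.
#'
#' @param frame A `signal_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(frame, path) {
  out <- tibble::tibble(animal_id = frame$animal_id,
                        timestamp_utc = format_utc(frame$t),
                        ax_g = frame$ax, ay_g = frame$ay, az_g = frame$az)
  for (m in intersect(c("mx", "my", "mz"), names(frame))) out[[m]] <- frame[[m]]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read observed behavior bouts
#'
#' Expects columns `animal_id,start_utc,end_utc,behavior,source[,clip_id]`.
#' Labels are normalized against the ethogram vocabulary; bouts are sorted per
#' animal; overlapping bouts for one animal are a validation error.
#'
#' @param path CSV path.
#' @return A tibble of bouts.
#' @export
read_observations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (nrow(df) == 0) {
    return(tibble::tibble(animal_id = character(), start_utc = numeric(),
                          end_utc = numeric(), behavior = character(),
                          source = character()))
  }
  req <- c("animal_id", "start_utc", "end_utc", "behavior")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) stop("Missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(animal_id = df$animal_id,
                        start_utc = to_utc_seconds(df$start_utc),
                        end_utc = to_utc_seconds(df$end_utc),
                        behavior = normalize_behavior(df$behavior),
                        source = if ("clip_id" %in% names(df) || "source" %in% names(df))
                          df$source %||% "in_pasture" else "in_pasture")
  if ("clip_id" %in% names(df)) out$clip_id <- df$clip_id
  if (any(out$end_utc <= out$start_utc)) stop("bout with end_utc <= start_utc", call. = FALSE)
  out <- dplyr::arrange(out, .data$animal_id, .data$start_utc)
  for (sub in split(out, out$animal_id)) {
    if (nrow(sub) > 1L && any(sub$start_utc[-1L] < sub$end_utc[-nrow(sub)] - 1e-9)) {
      stop("Overlapping bouts for animal ", sub$animal_id[1L], call. = FALSE)
    }
  }
  out
}

#' Remove collar-video clips containing a behavior switch
#'
#' A 15-s collar-video clip is only usable for training when the animal held
#' one behavior for the whole clip; clips with a behavior switch are removed
#' entirely. Clips are identified by a `clip_id` column when present,
#' otherwise by contiguity: consecutive collar-video bouts with no time gap
#' belong to the same clip. In-pasture bouts are never touched.
#'
#' @param bouts Bout tibble (see [read_observations()]).
#' @return A list with `kept`, `removed` (both bout tibbles) and
#'   `n_removed_clips`.
#' @export
filter_video_clips <- function(bouts) {
  if (nrow(bouts) == 0) return(list(kept = bouts, removed = bouts[0, ], n_removed_clips = 0L))
  src <- bouts$source %||% rep("in_pasture", nrow(bouts))
  video <- bouts[src == "collar_video", , drop = FALSE]
  other <- bouts[src != "collar_video", , drop = FALSE]
  if (nrow(video) == 0) return(list(kept = bouts, removed = bouts[0, ], n_removed_clips = 0L))
  video <- dplyr::arrange(video, .data$animal_id, .data$start_utc)
  if (!("clip_id" %in% names(video)) || anyNA(video$clip_id)) {
    video <- video |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::mutate(clip_id = paste(.data$animal_id,
        cumsum(c(TRUE, abs(.data$start_utc[-1L] - .data$end_utc[-dplyr::n()]) > 1e-9)),
        sep = "_")) |>
      dplyr::ungroup()
  }
  mixed <- video |>
    dplyr::group_by(.data$animal_id, .data$clip_id) |>
    dplyr::summarise(mixed = dplyr::n_distinct(.data$behavior) > 1L, .groups = "drop")
  video <- dplyr::left_join(video, mixed, by = c("animal_id", "clip_id"))
  removed <- dplyr::select(dplyr::filter(video, .data$mixed), -"mixed")
  kept_video <- dplyr::select(dplyr::filter(video, !.data$mixed), -"mixed")
  kept <- dplyr::bind_rows(other, kept_video)
  kept <- dplyr::arrange(kept, .data$animal_id, .data$start_utc)
  list(kept = kept, removed = removed,
       n_removed_clips = dplyr::n_distinct(removed$clip_id))
}

# Integer seconds fully recorded by a frame (all sample slots present).
complete_seconds <- function(frame) {
  sr <- sample_rate(frame)
  secs <- floor(frame$t)
  tab <- table(secs)
  as.numeric(names(tab)[tab == sr])
}

#' Label 1-s epochs of a signal with observed behavior
#'
#' Each integer second fully covered by both the signal and a behavior bout
#' becomes one labeled epoch. Bouts are half-open intervals `[start, end)`, so
#' boundary seconds are never double-labeled. Seconds with signal but no
#' observation are excluded.
#'
#' @param frame A `signal_frame` (may contain several animals).
#' @param bouts Bout tibble.
#' @return A tibble of epochs: `animal_id`, `epoch_utc` (integer second),
#'   `behavior`, `source`.
#' @export
join_labels <- function(frame, bouts) {
  out <- purrr::map_dfr(split(as.data.frame(frame), frame$animal_id), function(sub) {
    sub_b <- bouts[bouts$animal_id == sub$animal_id[1L], , drop = FALSE]
    if (nrow(sub_b) == 0) return(NULL)
    fr <- new_signal_frame(sub, attr(frame, "sample_rate"))
    secs <- complete_seconds(fr)
    if (length(secs) == 0) return(NULL)
    sub_b <- sub_b[order(sub_b$start_utc), , drop = FALSE]
    idx <- findInterval(secs, sub_b$start_utc)
    ok <- idx >= 1L & secs >= sub_b$start_utc[pmax(idx, 1L)] &
      (secs + 1) <= sub_b$end_utc[pmax(idx, 1L)] + 1e-9
    if (!any(ok)) return(NULL)
    tibble::tibble(animal_id = sub$animal_id[1L], epoch_utc = secs[ok],
                   behavior = sub_b$behavior[idx[ok]],
                   source = (sub_b$source %||% rep("in_pasture", nrow(sub_b)))[idx[ok]])
  })
  if (nrow(out) == 0) warning("no temporal overlap between signal and bouts")
  out
}

#' Default signal-verification rules
#'
#' Rule-based stand-in for manual signal verification: a labeled epoch is
#' excluded when its windowed signal statistics contradict the label.
#'
#' @param grazing_static_x_min Minimum windowed mean static X (g) a grazing
#'   epoch must show (head-down posture); default 0.3.
#' @param resting_vedba_max Maximum windowed mean VeDBA (g) a resting epoch
#'   may show; default 0.2.
#' @param window_s Trailing window length for the check, seconds.
#' @param span_s Static/dynamic separation span, seconds.
#' @param enabled Master switch; `FALSE` flags nothing.
#' @return A `mismatch_rules` list.
#' @export
mismatch_rules <- function(grazing_static_x_min = 0.3, resting_vedba_max = 0.2,
                           window_s = 10, span_s = 2, enabled = TRUE) {
  structure(list(grazing_static_x_min = grazing_static_x_min,
                 resting_vedba_max = resting_vedba_max,
                 window_s = window_s, span_s = span_s, enabled = enabled),
            class = "mismatch_rules")
}

#' Flag epochs whose signal contradicts the observed label
#'
#' Applies [mismatch_rules()] to windowed statistics of the static and
#' dynamic signal components: grazing epochs without a head-down static-X
#' signature, and resting epochs with high VeDBA, are flagged for exclusion.
#'
#' @param frame A `signal_frame`.
#' @param epochs Labeled epoch tibble from [join_labels()].
#' @param rules A [mismatch_rules()] object.
#' @return `epochs` with logical `flagged` and character `flag_reason` columns.
#' @export
flag_signal_mismatch <- function(frame, epochs, rules = mismatch_rules()) {
  out <- dplyr::mutate(epochs, flagged = FALSE, flag_reason = NA_character_)
  if (!rules$enabled || nrow(epochs) == 0) return(out)
  for (id in unique(epochs$animal_id)) {
    fr <- frame[frame$animal_id == id, , drop = FALSE]
    if (nrow(fr) == 0) next
    sd_split <- static_dynamic_split(fr, span_s = rules$span_s)
    dba <- compute_odba_vedba(sd_split$dyn_ax, sd_split$dyn_ay, sd_split$dyn_az)
    # windowed trailing means at epoch seconds
    sel <- out$animal_id == id
    ep <- out$epoch_utc[sel]
    w <- rules$window_s
    mean_over <- function(x, e) {
      lo <- e - w + 1
      m <- numeric(length(e))
      for (i in seq_along(e)) {
        take <- fr$t >= lo[i] & fr$t < e[i] + 1
        m[i] <- mean(x[take])
      }
      m
    }
    static_x <- mean_over(sd_split$static_ax, ep)
    vedba_m <- mean_over(dba$vedba, ep)
    beh <- out$behavior[sel]
    fl <- rep(FALSE, length(ep)); rs <- rep(NA_character_, length(ep))
    g <- beh == "grazing" & !is.na(static_x) & static_x < rules$grazing_static_x_min
    r <- beh == "resting" & !is.na(vedba_m) & vedba_m > rules$resting_vedba_max
    fl[g] <- TRUE; rs[g] <- "grazing_without_head_down"
    fl[r] <- TRUE; rs[r] <- "resting_with_high_vedba"
    out$flagged[sel] <- fl; out$flag_reason[sel] <- rs
  }
  out
}

#' Annotate bouts with the nearest-in-time GPS fix
#'
#' Each bout is matched to the fix minimizing the absolute offset between the
#' fix time and the bout midpoint; ties go to the earlier fix. `fix_dt`
#' records the signed offset (fix time minus midpoint).
#'
#' @param bouts Bout tibble.
#' @param fixes GPS fix tibble: `animal_id`, `t`, `lon`, `lat`.
#' @return `bouts` with `lon`, `lat`, `fix_dt` columns.
#' @export
nearest_gps_join <- function(bouts, fixes) {
  missing <- setdiff(unique(bouts$animal_id), unique(fixes$animal_id))
  if (length(missing) > 0) {
    stop("No GPS fixes for animal(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(split(bouts, bouts$animal_id), function(sub) {
    fx <- fixes[fixes$animal_id == sub$animal_id[1L], , drop = FALSE]
    fx <- fx[order(fx$t), , drop = FALSE]
    mid <- (sub$start_utc + sub$end_utc) / 2
    lo <- findInterval(mid, fx$t)
    pick <- integer(length(mid))
    for (i in seq_along(mid)) {
      cand <- unique(pmin(pmax(c(lo[i], lo[i] + 1L), 1L), nrow(fx)))
      d <- abs(fx$t[cand] - mid[i])
      # tie -> earlier fix (candidates are in time order)
      pick[i] <- cand[which(d <= min(d) + 1e-12)[1L]]
    }
    dplyr::mutate(sub, lon = fx$lon[pick], lat = fx$lat[pick],
                  fix_dt = fx$t[pick] - mid)
  })
}

#' Per-behavior time shares
#'
#' Converts per-behavior second counts into percentage shares at one decimal
#' (rounded half away from zero). The denominator defaults to the sum of the
#' counts but can be given explicitly, e.g. to reproduce shares quoted
#' against a reported total.
#'
#' @param counts Named numeric vector of seconds per behavior.
#' @param total Denominator in seconds; defaults to `sum(counts)`.
#' @return A tibble: `behavior`, `n_s`, `share_pct`.
#' @export
behavior_shares <- function(counts, total = sum(counts)) {
  if (length(counts) == 0 || total <= 0) stop("empty counts", call. = FALSE)
  tibble::tibble(behavior = names(counts), n_s = as.numeric(counts),
                 share_pct = round_half_up(100 * as.numeric(counts) / total, 1))
}

#' Summarize an ethogram from labeled epochs
#'
#' Second counts and percentage shares per behavior, overall and per
#' observation source.
#'
#' @param epochs Labeled epoch tibble.
#' @return A tibble: `source` (`"all"` plus each source), `behavior`, `n_s`,
#'   `share_pct` (share within that source, one decimal).
#' @export
summarize_ethogram <- function(epochs) {
  if (nrow(epochs) == 0) stop("empty epoch table", call. = FALSE)
  per_source <- epochs |>
    dplyr::count(.data$source, .data$behavior, name = "n_s") |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(share_pct = round_half_up(100 * .data$n_s / sum(.data$n_s), 1)) |>
    dplyr::ungroup()
  overall <- epochs |>
    dplyr::count(.data$behavior, name = "n_s") |>
    dplyr::mutate(source = "all",
                  share_pct = round_half_up(100 * .data$n_s / sum(.data$n_s), 1))
  dplyr::bind_rows(overall, per_source) |>
    dplyr::select("source", "behavior", "n_s", "share_pct") |>
    dplyr::arrange(.data$source, dplyr::desc(.data$n_s))
}

#' Convert seconds to hours at one decimal
#'
#' @param seconds Duration in seconds.
#' @param digits Decimal places (default 1).
#' @return Hours, rounded half away from zero.
#' @export
seconds_to_hours <- function(seconds, digits = 1) {
  round_half_up(seconds / 3600, digits)
}

#' Read an epoch exclusion list
#'
#' A plain CSV of epochs to exclude from analysis (e.g. a manually curated
#' signal-verification list): columns `animal_id,epoch_utc[,reason]`.
#'
#' @param path CSV path.
#' @return A tibble: `animal_id`, `epoch_utc`, `reason`.
#' @export
read_exclusion_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(animal_id = "c", epoch_utc = "d",
                                                .default = "c"))
  missing <- setdiff(c("animal_id", "epoch_utc"), names(df))
  if (length(missing) > 0) stop("Missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (!("reason" %in% names(df))) df$reason <- NA_character_
  tibble::as_tibble(df[c("animal_id", "epoch_utc", "reason")])
}

#' Apply exclusions to a labeled epoch table
#'
#' Drops epochs listed in an exclusion table (from [read_exclusion_csv()]) or
#' flagged by [flag_signal_mismatch()].
#'
#' @param epochs Labeled epoch tibble; may carry a `flagged` column.
#' @param exclusions Optional exclusion tibble (`animal_id`, `epoch_utc`).
#' @return The epoch tibble without excluded or flagged rows.
#' @export
apply_exclusions <- function(epochs, exclusions = NULL) {
  out <- epochs
  if ("flagged" %in% names(out)) {
    out <- dplyr::select(dplyr::filter(out, !.data$flagged), -"flagged",
                         -dplyr::any_of("flag_reason"))
  }
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    out <- dplyr::anti_join(out, exclusions, by = c("animal_id", "epoch_utc"))
  }
  out
}
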