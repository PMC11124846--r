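# Windowed feature extraction: static/dynamic decomposition, ODBA/VeDBA,
# Butterworth filtering, magnetometry resampling, and per-epoch statistics.

#' Split acceleration into static and dynamic components
#'
#' Static acceleration is the centered running mean of each axis over
#' `span_s` seconds (an odd sample count, shrinking to the available samples
#' at the edges); dynamic acceleration is raw minus static, so the two sum to
#' the raw signal exactly.
#'
#' @param frame A `signal_frame` for a single animal.
#' @param span_s Running-mean span in seconds (default 2).
#' @return `frame` with added columns `static_ax/ay/az` and `dyn_ax/ay/az`.
#' @export
static_dynamic_split <- function(frame, span_s = 2) {
  sr <- sample_rate(frame)
  k <- round(span_s * sr)
  if (k < 2) stop("span_s must cover at least 2 samples", call. = FALSE)
  if (k %% 2 == 0) k <- k + 1L  # centered window needs odd length
  out <- frame
  for (a in c("ax", "ay", "az")) {
    st <- running_mean_centered(frame[[a]], k)
    out[[paste0("static_", a)]] <- st
    out[[paste0("dyn_", a)]] <- frame[[a]] - st
  }
  out
}

#' Zero-phase Butterworth filter
#'
#' Forward–backward (zero-phase) Butterworth filtering of one channel; the
#' effective gain is the squared magnitude response of the one-pass filter.
#'
#' @param x Numeric signal.
#' @param kind `"low"` or `"high"`.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @param sample_rate Sampling rate, Hz.
#' @param order Filter order (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_filter <- function(x, kind = c("low", "high"), cutoff_hz,
                               sample_rate, order = 2) {
  kind <- match.arg(kind)
  nyq <- sample_rate / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stop("cutoff_hz must lie in (0, Nyquist = ", nyq, ")", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = kind)
  # odd-reflection padding suppresses the edge transients of filtfilt
  n <- length(x)
  np <- min(n - 1L, ceiling(6 * sample_rate / cutoff_hz))
  if (np > 0) {
    left <- 2 * x[1L] - x[(np + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - np)]
    y <- signal::filtfilt(bf, c(left, x, right))
    as.numeric(y[(np + 1L):(np + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Overall and vectorial dynamic body acceleration
#'
#' ODBA is the sum of absolute dynamic accelerations across axes;
#' VeDBA is their Euclidean norm. Both are energy-expenditure proxies;
#' at every sample `VeDBA <= ODBA <= sqrt(3) * VeDBA`.
#'
#' @param dx,dy,dz Dynamic acceleration per axis (g).
#' @return A tibble with `odba` and `vedba`.
#' @export
compute_odba_vedba <- function(dx, dy, dz) {
  tibble::tibble(odba = abs(dx) + abs(dy) + abs(dz),
                 vedba = sqrt(dx^2 + dy^2 + dz^2))
}

#' Resample magnetometry onto the acceleration time base
#'
#' Linear interpolation of each magnetometer axis onto the target times;
#' values beyond the recorded range are clamped to the end samples rather
#' than extrapolated.
#'
#' @param mag Tibble with `t`, `mx`, `my`, `mz` for one animal.
#' @param target_t Numeric vector of target times (seconds).
#' @return Tibble `t`, `mx`, `my`, `mz` at `target_t`.
#' @export
resample_magnetometry <- function(mag, target_t) {
  if (min(target_t) > max(mag$t) || max(target_t) < min(mag$t)) {
    stop("magnetometry and target time ranges are disjoint", call. = FALSE)
  }
  tibble::tibble(
    t = target_t,
    mx = stats::approx(mag$t, mag$mx, xout = target_t, rule = 2)$y,
    my = stats::approx(mag$t, mag$my, xout = target_t, rule = 2)$y,
    mz = stats::approx(mag$t, mag$mz, xout = target_t, rule = 2)$y)
}

# Per-second summary building blocks for one channel: x reshaped so that each
# complete second contributes `sr` consecutive samples.
second_blocks <- function(x, sr, n_sec) {
  m <- matrix(x[seq_len(sr * n_sec)], nrow = sr)
  list(sum = colSums(m), sumsq = colSums(m^2),
       min = apply(m, 2L, min), max = apply(m, 2L, max),
       last = m[sr, ])
}

# Windowed stats (trailing w seconds ending at each kept epoch) for one
# channel, from per-second blocks plus the raw samples (for the median).
window_stats_channel <- function(x, blocks, sr, w, epoch_idx) {
  n_samp <- w * sr
  csum <- c(0, cumsum(blocks$sum))
  csq <- c(0, cumsum(blocks$sumsq))
  s <- csum[epoch_idx + 1L] - csum[epoch_idx + 1L - w]
  sq <- csq[epoch_idx + 1L] - csq[epoch_idx + 1L - w]
  mu <- s / n_samp
  va <- pmax(sq / n_samp - mu^2, 0)  # population variance
  mins <- roll_extreme(blocks$min, w, pmin)[epoch_idx - w + 1L]
  maxs <- roll_extreme(blocks$max, w, pmax)[epoch_idx - w + 1L]
  med <- vapply(epoch_idx, function(i) {
    a <- (i - w) * sr + 1L
    stats::median.default(x[a:(i * sr)])
  }, numeric(1))
  list(mean = mu, median = med, sd = sqrt(va), min = mins, max = maxs)
}

#' Per-epoch windowed features for one smoothing window size
#'
#' Computes, at every 1-s epoch, the feature set used for behavior
#' classification: the raw-axis snapshot at the epoch, windowed
#' mean/median/sd/min/max per axis, the dynamic-axis snapshot, instantaneous
#' ODBA and VeDBA, windowed statistics of ODBA and VeDBA, and (optionally)
#' raw and windowed magnetometry. Standard deviations use the population
#' divisor N. Epochs whose smoothing window extends beyond the recorded
#' signal are dropped, so every feature is computed from a full window of
#' `window_s * sample_rate` samples.
#'
#' @param frame A `signal_frame` (one or more animals).
#' @param window_s Smoothing window length in whole seconds, 1–60.
#' @param alignment `"trailing"` (window ends at the epoch; default) or
#'   `"centered"`.
#' @param span_s Static/dynamic separation span, seconds.
#' @param mag Optional magnetometry tibble (`animal_id`, `t`, `mx`, `my`,
#'   `mz`); resampled onto the acceleration time base.
#' @param butterworth If `TRUE`, adds zero-phase Butterworth low- and
#'   high-pass snapshots per axis (illustrative channels, off by default).
#' @param bw_cutoff_hz,bw_order Butterworth cutoff and order.
#' @return A tibble with key columns `animal_id`, `epoch_utc`, `window_s`
#'   followed by feature columns.
#' @export
window_features <- function(frame, window_s = 10,
                            alignment = c("trailing", "centered"),
                            span_s = 2, mag = NULL, butterworth = FALSE,
                            bw_cutoff_hz = 0.3, bw_order = 2) {
  alignment <- match.arg(alignment)
  stopifnot(window_s >= 1, window_s <= 60, window_s == round(window_s))
  w <- as.integer(window_s)
  sr <- sample_rate(frame)
  purrr::map_dfr(split(as.data.frame(frame), frame$animal_id), function(sub) {
    fr <- new_signal_frame(sub, sr)
    secs <- complete_seconds(fr)
    n_sec <- length(secs)
    if (n_sec < w) {
      warning("window (", w, " s) longer than frame (", n_sec, " s); no epochs")
      return(NULL)
    }
    # keep only samples belonging to complete seconds, in second order
    keep <- floor(fr$t) %in% secs
    fr <- fr[keep, , drop = FALSE]
    ord <- order(fr$t)
    fr <- fr[ord, , drop = FALSE]

    sd_split <- static_dynamic_split(new_signal_frame(fr, sr), span_s = span_s)
    dba <- compute_odba_vedba(sd_split$dyn_ax, sd_split$dyn_ay, sd_split$dyn_az)

    # epoch_idx is the index of each window's LAST second; the epoch second is
    # the window end (trailing) or its middle second (centered, rounding the
    # center toward the later second for even windows).
    epoch_idx <- seq.int(w, n_sec)
    epoch_sec <- if (alignment == "trailing") secs[epoch_idx] else secs[epoch_idx - (w - 1L) %/% 2L]

    chans <- list(ax = fr$ax, ay = fr$ay, az = fr$az,
                  odba = dba$odba, vedba = dba$vedba)
    out <- tibble::tibble(animal_id = fr$animal_id[1L],
                          epoch_utc = epoch_sec, window_s = w)
    # raw snapshots at the epoch second's last sample
    snap_idx <- match(epoch_sec, secs) * sr
    out$ax_g <- fr$ax[snap_idx]; out$ay_g <- fr$ay[snap_idx]; out$az_g <- fr$az[snap_idx]
    stat_names <- c("mean", "median", "sd", "min", "max")
    for (a in c("ax", "ay", "az")) {
      blocks <- second_blocks(chans[[a]], sr, n_sec)
      st <- window_stats_channel(chans[[a]], blocks, sr, w, epoch_idx)
      for (s in stat_names) out[[paste0(s, "_", a, "_g")]] <- st[[s]]
    }
    out$dyn_ax_g <- sd_split$dyn_ax[snap_idx]
    out$dyn_ay_g <- sd_split$dyn_ay[snap_idx]
    out$dyn_az_g <- sd_split$dyn_az[snap_idx]
    out$odba <- dba$odba[snap_idx]
    out$vedba <- dba$vedba[snap_idx]
    for (a in c("odba", "vedba")) {
      blocks <- second_blocks(chans[[a]], sr, n_sec)
      st <- window_stats_channel(chans[[a]], blocks, sr, w, epoch_idx)
      for (s in stat_names) out[[paste0(s, "_", a)]] <- st[[s]]
    }
    if (butterworth) {
      for (a in c("ax", "ay", "az")) {
        lo <- butterworth_filter(chans[[a]], "low", bw_cutoff_hz, sr, bw_order)
        hi <- butterworth_filter(chans[[a]], "high", bw_cutoff_hz, sr, bw_order)
        out[[paste0("bw_low_", a, "_g")]] <- lo[snap_idx]
        out[[paste0("bw_high_", a, "_g")]] <- hi[snap_idx]
      }
    }
    if (!is.null(mag)) {
      mg <- mag[mag$animal_id == fr$animal_id[1L], , drop = FALSE]
      if (nrow(mg) > 0) {
        rm40 <- resample_magnetometry(mg, fr$t)
        out$mx <- rm40$mx[snap_idx]; out$my <- rm40$my[snap_idx]; out$mz <- rm40$mz[snap_idx]
        for (a in c("mx", "my", "mz")) {
          blocks <- second_blocks(rm40[[a]], sr, n_sec)
          st <- window_stats_channel(rm40[[a]], blocks, sr, w, epoch_idx)
          for (s in stat_names) out[[paste0(s, "_", a)]] <- st[[s]]
        }
      }
    }
    out
  })
}

#' Extract labeled per-epoch features
#'
#' Runs [window_features()] and inner-joins the labeled epochs, producing the
#' table used to train and evaluate classifiers.
#'
#' @inheritParams window_features
#' @param epochs Labeled epoch tibble from [join_labels()]; if `NULL` the
#'   features are returned unlabeled.
#' @param ... Passed to [window_features()].
#' @return Feature tibble with `behavior` and `source` columns appended.
#' @export
extract_features <- function(frame, epochs = NULL, window_s = 10, ...) {
  ft <- window_features(frame, window_s = window_s, ...)
  if (is.null(epochs)) return(ft)
  dplyr::inner_join(ft, epochs, by = c("animal_id", "epoch_utc"))
}

# Columns that identify rather than describe an epoch.
feature_key_cols <- function() c("animal_id", "epoch_utc", "window_s", "behavior", "source")

#' Write a feature table with a sidecar JSON schema
#'
#' @param table Feature tibble.
#' @param path Output CSV path; the schema is written to `paste0(path, ".schema.json")`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  readr::write_csv(table, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    schema <- list(window_s = unique(table$window_s), columns = names(table))
    jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE)
  }
  invisible(path)
}
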