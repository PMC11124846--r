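#' Configuration for a synthetic behavior-bout schedule
#'
#' Defines the herd, recording duration, long-run behavior time shares and
#' mean bout durations used by [make_bout_schedule()]. Defaults emulate the
#' behavior composition of extensively grazed steers: resting and grazing
#' dominate, walking is minor, and grooming is rare.
#'
#' @param animal_ids Character vector of animal identifiers.
#' @param total_duration Recording duration per animal, seconds.
#' @param target_proportions Named numeric vector of long-run time shares per
#'   behavior; must sum to 1 within 1e-9.
#' @param mean_bout_duration Named numeric vector of mean bout durations
#'   (seconds) per behavior; all positive.
#' @param seed Integer seed; schedules are a pure function of (config, seed).
#' @return A `bout_schedule_config` list.
#' @export
bout_schedule_config <- function(animal_ids = sprintf("steer_%02d", 1:8),
                                 total_duration = 2500,
                                 target_proportions = c(
                                   resting = 0.355, grazing = 0.335,
                                   ruminating = 0.215, walking = 0.094,
                                   grooming = 0.001),
                                 mean_bout_duration = c(
                                   grazing = 300, walking = 30, resting = 120,
                                   ruminating = 120, grooming = 15),
                                 seed = 1L) {
  stopifnot(length(animal_ids) >= 1, total_duration > 0)
  props <- target_proportions[target_proportions > 0]
  if (abs(sum(props) - 1) > 1e-9) {
    stop("target_proportions must sum to 1 (got ", sum(props), ")", call. = FALSE)
  }
  bad <- setdiff(names(props), behavior_levels())
  if (length(bad) > 0) stop("Unknown behaviors in proportions: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(mean_bout_duration[names(props)] <= 0) || anyNA(mean_bout_duration[names(props)])) {
    stop("mean_bout_duration must be positive for every behavior with nonzero share", call. = FALSE)
  }
  structure(list(animal_ids = as.character(animal_ids),
                 total_duration = total_duration,
                 target_proportions = props,
                 mean_bout_duration = mean_bout_duration[names(props)],
                 seed = as.integer(seed)),
            class = "bout_schedule_config")
}

#' Generate a behavior bout schedule
#'
#' Draws a semi-Markov bout sequence per animal: bout durations are
#' exponential with the per-behavior mean, and behaviors are drawn with
#' probability proportional to `target_proportion / mean_bout_duration`, so
#' that long-run time shares converge to the targets. Bouts tile
#' `[0, total_duration]` exactly; adjacent bouts with the same behavior are
#' merged, and the final bout is truncated at the total duration.
#'
#' @param config A [bout_schedule_config()].
#' @return A tibble of bouts: `animal_id`, `start_utc`, `end_utc` (seconds),
#'   `behavior`, `source` (`"in_pasture"`).
#' @export
make_bout_schedule <- function(config = bout_schedule_config()) {
  stopifnot(inherits(config, "bout_schedule_config"))
  props <- config$target_proportions
  means <- config$mean_bout_duration
  # Selection weights so that E[time share] = p_b under exponential durations.
  wts <- props / means
  wts <- wts / sum(wts)
  behaviors <- names(props)
  withr::with_seed(config$seed, {
    purrr::map_dfr(config$animal_ids, function(id) {
      starts <- numeric(0); labs <- character(0); t <- 0
      while (t < config$total_duration) {
        b <- sample(behaviors, 1L, prob = wts)
        d <- stats::rexp(1L, rate = 1 / means[[b]])
        starts <- c(starts, t); labs <- c(labs, b)
        t <- t + d
      }
      ends <- c(starts[-1L], config$total_duration)
      keep <- starts < config$total_duration
      sched <- tibble::tibble(animal_id = id, start_utc = starts[keep],
                              end_utc = pmin(ends[keep], config$total_duration),
                              behavior = labs[keep])
      # merge adjacent identical labels so bouts are maximal
      run <- cumsum(c(TRUE, sched$behavior[-1L] != sched$behavior[-nrow(sched)]))
      sched |>
        dplyr::group_by(run = run, .data$animal_id, .data$behavior) |>
        dplyr::summarise(start_utc = min(.data$start_utc),
                         end_utc = max(.data$end_utc), .groups = "drop") |>
        dplyr::arrange(.data$start_utc) |>
        dplyr::select("animal_id", "start_utc", "end_utc", "behavior")
    }) |>
      dplyr::mutate(source = "in_pasture")
  })
}

#' Behavior-specific signal signature parameters
#'
#' One row per behavior describing the deterministic and stochastic structure
#' of its collar acceleration signature:
#' * `gravity_pitch_deg` — head-down pitch of the collar about the Y-axis.
#'   0 puts +1 g on the +Z (down) axis; 90 transfers gravity to +X (forward),
#'   the grazing posture.
#' * `periodic_freq_hz`, `periodic_amp_g` — a locomotor/chewing sinusoid
#'   (walking gait near 2 Hz; rumination chewing near 1 Hz).
#' * `noise_sd_g` — Gaussian dynamic noise per axis; grazing is noisiest
#'   (biting and tearing forage), resting and ruminating quietest.
#' * `mag_heading_drift_dps` — heading random-walk rate (degrees/s) used by
#'   the magnetometer simulator.
#'
#' @param overrides Optional data frame of rows to replace defaults (matched
#'   by `behavior`).
#' @return A tibble with one row per behavior.
#' @export
signature_params <- function(overrides = NULL) {
  p <- tibble::tribble(
    ~behavior,    ~gravity_pitch_deg, ~periodic_freq_hz, ~periodic_amp_g, ~noise_sd_g, ~mag_heading_drift_dps,
    "grazing",     90,                 1.0,               0.10,            0.25,        4,
    "walking",      0,                 2.0,               0.30,            0.15,        8,
    "resting",      0,                 0.0,               0.00,            0.05,        0.5,
    "ruminating",   0,                 1.0,               0.05,            0.05,        0.5,
    "grooming",    30,                 0.0,               0.00,            0.30,        4
  )
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "behavior" %in% names(overrides))
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$behavior[i], p$behavior)
      for (cl in intersect(names(overrides), names(p))) p[j, cl] <- overrides[i, cl]
    }
  }
  if (any(p$noise_sd_g < 0) || any(p$gravity_pitch_deg < 0 | p$gravity_pitch_deg > 180)) {
    stop("Invalid signature parameters: noise_sd_g >= 0 and 0 <= gravity_pitch_deg <= 180 required", call. = FALSE)
  }
  p
}

# Deterministic (noise-free) signature of one behavior at global times t.
# Gravity is rotated about Y: pitch 0 -> (0, 0, 1) g, pitch 90 -> (1, 0, 0) g.
signature_deterministic <- function(t, pars) {
  th <- pars$gravity_pitch_deg * pi / 180
  f <- pars$periodic_freq_hz
  a <- pars$periodic_amp_g
  per_x <- if (f > 0 && a > 0) a * sin(2 * pi * f * t) else 0
  per_y <- if (f > 0 && a > 0) 0.5 * a * sin(2 * pi * f * t + 2 * pi / 3) else 0
  per_z <- if (f > 0 && a > 0) a * cos(2 * pi * f * t) else 0
  list(ax = sin(th) + per_x, ay = 0 + per_y, az = cos(th) + per_z)
}

#' Synthesize a tri-axial collar acceleration signal from a bout schedule
#'
#' Each sample is the behavior's rotated gravity vector plus its locomotor
#' sinusoid plus Gaussian noise, in units of g. Axis convention: +X forward,
#' +Y right, +Z down, so a resting (pitch 0) animal reads (0, 0, 1) g and a
#' grazing (pitch 90) animal reads (1, 0, 0) g. Transitions between bouts are
#' blended with a cosine ramp so bout boundaries are not trivially sharp.
#'
#' @param schedule Bout tibble from [make_bout_schedule()]; must be contiguous
#'   per animal.
#' @param params Signature table from [signature_params()].
#' @param sample_rate Samples per second (default 40).
#' @param seed Integer seed; output is a pure function of inputs and seed.
#' @param ramp_s Cosine blend duration at bout transitions, seconds.
#' @return A `signal_frame` tibble: `animal_id`, `t` (seconds, uniform grid),
#'   `ax`, `ay`, `az` (g), with a `sample_rate` attribute.
#' @export
synthesize_signal <- function(schedule, params = signature_params(),
                              sample_rate = 40, seed = 1L, ramp_s = 0.5) {
  validate_schedule(schedule)
  if (2 * max(params$periodic_freq_hz) >= sample_rate) {
    stop("sample_rate must exceed twice the fastest periodic_freq_hz", call. = FALSE)
  }
  out <- withr::with_seed(seed, {
    purrr::map_dfr(split(schedule, schedule$animal_id), function(sch) {
      sch <- dplyr::arrange(sch, .data$start_utc)
      t0 <- sch$start_utc[1L]
      dur <- sch$end_utc[nrow(sch)] - t0
      n <- round(dur * sample_rate)
      t <- t0 + (seq_len(n) - 1L) / sample_rate
      bi <- findInterval(t, sch$start_utc)  # bout index per sample
      pars_by <- split(params, params$behavior)
      det <- list(ax = numeric(n), ay = numeric(n), az = numeric(n))
      noise_sd <- numeric(n)
      for (i in seq_len(nrow(sch))) {
        sel <- bi == i
        if (!any(sel)) next
        p <- pars_by[[sch$behavior[i]]]
        d <- signature_deterministic(t[sel], p)
        det$ax[sel] <- d$ax; det$ay[sel] <- d$ay; det$az[sel] <- d$az
        noise_sd[sel] <- p$noise_sd_g
      }
      # cosine ramp into each new bout: blend previous bout's deterministic part
      if (ramp_s > 0 && nrow(sch) > 1L) {
        for (i in 2:nrow(sch)) {
          tb <- sch$start_utc[i]
          sel <- t >= tb & t < tb + ramp_s
          if (!any(sel)) next
          w <- 0.5 - 0.5 * cos(pi * (t[sel] - tb) / ramp_s)
          p_prev <- pars_by[[sch$behavior[i - 1L]]]
          d_prev <- signature_deterministic(t[sel], p_prev)
          det$ax[sel] <- (1 - w) * d_prev$ax + w * det$ax[sel]
          det$ay[sel] <- (1 - w) * d_prev$ay + w * det$ay[sel]
          det$az[sel] <- (1 - w) * d_prev$az + w * det$az[sel]
        }
      }
      tibble::tibble(
        animal_id = sch$animal_id[1L], t = t,
        ax = det$ax + stats::rnorm(n, 0, noise_sd),
        ay = det$ay + stats::rnorm(n, 0, noise_sd),
        az = det$az + stats::rnorm(n, 0, noise_sd))
    })
  })
  new_signal_frame(out, sample_rate)
}

new_signal_frame <- function(df, sample_rate) {
  out <- tibble::as_tibble(df)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("signal_frame", class(out))
  out
}

#' @export
`[.signal_frame` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) attr(out, "sample_rate") <- attr(x, "sample_rate")
  out
}

#' Sampling rate of a signal frame
#' @param frame A `signal_frame`.
#' @return Samples per second.
#' @export
sample_rate <- function(frame) {
  sr <- attr(frame, "sample_rate")
  if (is.null(sr)) {
    dt <- stats::median(diff(frame$t[frame$animal_id == frame$animal_id[1L]]))
    sr <- round(1 / dt)
  }
  sr
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("animal_id", "start_utc", "end_utc", "behavior") %in% names(schedule)))
  if (nrow(schedule) == 0) stop("empty schedule", call. = FALSE)
  for (sch in split(schedule, schedule$animal_id)) {
    sch <- sch[order(sch$start_utc), ]
    if (any(sch$end_utc <= sch$start_utc)) stop("bout with end <= start", call. = FALSE)
    if (nrow(sch) > 1L && any(abs(sch$start_utc[-1L] - sch$end_utc[-nrow(sch)]) > 1e-9)) {
      stop("schedule is not contiguous for animal ", sch$animal_id[1L], call. = FALSE)
    }
  }
  invisible(schedule)
}

#' Synthesize collar magnetometry from a bout schedule
#'
#' The heading (yaw) follows a Gaussian random walk whose increment standard
#' deviation is `mag_heading_drift_dps * sqrt(dt)`, so yaw variance grows as
#' rate^2 * t. A fixed geomagnetic field with 60 degrees inclination is
#' projected through the heading onto the three collar axes.
#'
#' @inheritParams synthesize_signal
#' @param sample_rate Samples per second (default 10).
#' @return A tibble `animal_id`, `t`, `mx`, `my`, `mz` (arbitrary units), with
#'   a `sample_rate` attribute.
#' @export
synthesize_magnetometer <- function(schedule, params = signature_params(),
                                    sample_rate = 10, seed = 1L) {
  validate_schedule(schedule)
  incl <- 60 * pi / 180
  out <- withr::with_seed(seed, {
    purrr::map_dfr(split(schedule, schedule$animal_id), function(sch) {
      sch <- dplyr::arrange(sch, .data$start_utc)
      t0 <- sch$start_utc[1L]
      dur <- sch$end_utc[nrow(sch)] - t0
      n <- round(dur * sample_rate)
      t <- t0 + (seq_len(n) - 1L) / sample_rate
      bi <- findInterval(t, sch$start_utc)
      rate <- params$mag_heading_drift_dps[match(sch$behavior[bi], params$behavior)]
      dt <- 1 / sample_rate
      incr <- stats::rnorm(n, 0, rate * sqrt(dt)) * pi / 180
      yaw <- cumsum(c(0, incr[-1L]))
      tibble::tibble(animal_id = sch$animal_id[1L], t = t,
                     mx = cos(incl) * cos(yaw),
                     my = cos(incl) * sin(yaw),
                     mz = rep(sin(incl), n))
    })
  })
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Simulate a GPS track for each animal
#'
#' A correlated random walk (AR(1) velocity) confined to a rectangular
#' pasture by reflection, sampled at the fix interval. Fixes cover
#' `[start, end]` inclusive.
#'
#' @param schedule Bout schedule (defines each animal's time range).
#' @param pasture_bounds Named numeric vector `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max` (degrees WGS84).
#' @param fix_interval Seconds between fixes (default 900, i.e. 15 min).
#' @param step_sd Per-fix step scale in degrees (default 2e-4, roughly 20 m).
#' @param persistence AR(1) coefficient of the velocity process in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble of fixes: `animal_id`, `t`, `lon`, `lat`.
#' @export
make_gps_track <- function(schedule,
                           pasture_bounds = c(lon_min = -97.1, lon_max = -97.096,
                                              lat_min = 34.17, lat_max = 34.173),
                           fix_interval = 900, step_sd = 2e-4,
                           persistence = 0.6, seed = 1L) {
  validate_schedule(schedule)
  b <- pasture_bounds
  if (!(b[["lon_max"]] > b[["lon_min"]] && b[["lat_max"]] > b[["lat_min"]])) {
    stop("degenerate pasture bounds", call. = FALSE)
  }
  reflect <- function(x, lo, hi) {
    width <- hi - lo
    y <- (x - lo) %% (2 * width)
    lo + ifelse(y > width, 2 * width - y, y)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(split(schedule, schedule$animal_id), function(sch) {
      t0 <- min(sch$start_utc); t1 <- max(sch$end_utc)
      tt <- seq(t0, t1, by = fix_interval)
      n <- length(tt)
      lon <- numeric(n); lat <- numeric(n)
      lon[1L] <- stats::runif(1, b[["lon_min"]], b[["lon_max"]])
      lat[1L] <- stats::runif(1, b[["lat_min"]], b[["lat_max"]])
      vx <- 0; vy <- 0
      for (i in seq_len(n - 1L)) {
        vx <- persistence * vx + stats::rnorm(1, 0, step_sd)
        vy <- persistence * vy + stats::rnorm(1, 0, step_sd)
        lon[i + 1L] <- reflect(lon[i] + vx, b[["lon_min"]], b[["lon_max"]])
        lat[i + 1L] <- reflect(lat[i] + vy, b[["lat_min"]], b[["lat_max"]])
      }
      tibble::tibble(animal_id = sch$animal_id[1L], t = tt, lon = lon, lat = lat)
    })
  })
}

#' Apply a controlled corruption to a signal frame
#'
#' Emulates field failure modes of collar accelerometers:
#' * `time_drift` — clock drift; timestamps stretched by `magnitude` seconds
#'   per hour of recording.
#' * `axis_flip` — the named axes are negated (a mis-mounted housing).
#' * `collar_spin` — the collar rotates about the X (forward) axis by
#'   `magnitude` degrees from a random onset time onward.
#'
#' @param frame A `signal_frame`.
#' @param mode One of `"time_drift"`, `"axis_flip"`, `"collar_spin"`.
#' @param magnitude Drift (s/hour) or rotation (degrees); 0 is the identity.
#' @param axes For `axis_flip`: subset of `c("x", "y", "z")`.
#' @param seed Seed for the random spin onset.
#' @return The corrupted `signal_frame`.
#' @export
corrupt_signal <- function(frame, mode = c("time_drift", "axis_flip", "collar_spin"),
                           magnitude = 0, axes = "z", seed = 1L) {
  mode <- match.arg(mode)
  out <- frame
  if (magnitude == 0) return(out)  # identity for every mode
  switch(mode,
    time_drift = {
      out$t <- out$t + magnitude * (out$t - out$t[1L]) / 3600
    },
    axis_flip = {
      for (a in axes) {
        col <- paste0("a", match.arg(a, c("x", "y", "z")))
        out[[col]] <- -out[[col]]
      }
    },
    collar_spin = {
      th <- magnitude * pi / 180
      onset <- withr::with_seed(seed,
        stats::runif(1, min(out$t), max(out$t)))
      sel <- out$t >= onset
      ay <- out$ay[sel]; az <- out$az[sel]
      out$ay[sel] <- cos(th) * ay + sin(th) * az
      out$az[sel] <- -sin(th) * ay + cos(th) * az
      attr(out, "spin_onset") <- onset
    })
  out
}

#' Simulate a complete synthetic collar study
#'
#' Convenience wrapper: bout schedules, acceleration signals, labeled 1-s
#' epochs, and GPS tracks for a herd, all deterministic given the seed.
#'
#' @param config A [bout_schedule_config()].
#' @param params Signature table from [signature_params()].
#' @param sample_rate Acceleration sampling rate, Hz.
#' @param seed Integer seed.
#' @param gps If `TRUE`, also simulate GPS fixes.
#' @param magnetometer If `TRUE`, also simulate 10-Hz magnetometry.
#' @return A list with `signals`, `bouts`, `epochs`, and optionally `gps` and
#'   `mag`.
#' @export
simulate_collar_study <- function(config = bout_schedule_config(), params = signature_params(),
                                  sample_rate = 40, seed = 1L, gps = FALSE,
                                  magnetometer = FALSE) {
  config$seed <- as.integer(seed)
  bouts <- make_bout_schedule(config)
  signals <- synthesize_signal(bouts, params, sample_rate = sample_rate,
                               seed = child_seed(seed, 1L))
  epochs <- join_labels(signals, bouts)
  out <- list(signals = signals, bouts = bouts, epochs = epochs)
  if (magnetometer) {
    out$mag <- synthesize_magnetometer(bouts, params, seed = child_seed(seed, 2L))
  }
  if (gps) {
    out$gps <- make_gps_track(bouts, seed = child_seed(seed, 3L))
  }
  out
}
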