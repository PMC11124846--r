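# Shared fixtures, built in code. The study-scale dataset used by the
# heavier end-to-end tests is memoized so several test blocks can share one
# generation + feature-extraction pass.

.fixture_cache <- new.env(parent = emptyenv())

# A constant-behavior schedule for one animal.
mono_schedule <- function(behavior = "resting", duration = 60, animal = "a1") {
  tibble::tibble(animal_id = animal, start_utc = 0, end_utc = duration,
                 behavior = behavior, source = "in_pasture")
}

# Noise-free signature parameters (pure gravity + optional sinusoid).
quiet_params <- function(amp = 0, freq = 0) {
  signature_params(overrides = tibble::tibble(
    behavior = behavior_levels(),
    periodic_freq_hz = freq, periodic_amp_g = amp, noise_sd_g = 0))
}

# Small labeled feature table for model/experiment tests (~n_epochs epochs,
# 2 animals, trivially separable defaults).
small_feature_table <- function(n_seconds = 400, window_s = 5, seed = 42) {
  key <- sprintf("small_%d_%d_%d", n_seconds, window_s, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- bout_schedule_config(animal_ids = c("a1", "a2"),
                              total_duration = n_seconds, seed = seed)
  study <- simulate_collar_study(cfg, seed = seed)
  ft <- extract_features(study$signals, study$epochs, window_s = window_s)
  .fixture_cache[[key]] <- ft
  ft
}

# Study-scale synthetic dataset: 8 animals x 2500 s (~20,000 labeled 1-s
# epochs) with default signatures and behavior proportions.
study_dataset <- function(seed = 1) {
  key <- sprintf("study_%d", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  study <- simulate_collar_study(bout_schedule_config(seed = seed), seed = seed)
  .fixture_cache[[key]] <- study
  study
}

# Feature tables of the study dataset at one or more windows, memoized.
study_features <- function(window_s, seed = 1) {
  study <- study_dataset(seed)
  out <- lapply(window_s, function(w) {
    key <- sprintf("feat_%d_%d", seed, w)
    if (is.null(.fixture_cache[[key]])) {
      .fixture_cache[[key]] <-
        extract_features(study$signals, study$epochs, window_s = w)
    }
    .fixture_cache[[key]]
  })
  names(out) <- as.character(window_s)
  out
}
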