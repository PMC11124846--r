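test_that("signal CSV round-trips and splits at recording gaps", {
  sig <- synthesize_signal(mono_schedule("resting", 10), quiet_params(), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  frames <- read_signal_csv(path)
  expect_length(frames, 1L)
  expect_equal(nrow(frames[[1]]), 400L)
  expect_equal(frames[[1]]$az, sig$az, tolerance = 1e-9)
  expect_equal(sample_rate(frames[[1]]), 40)

  # a 5-s gap splits the record into two frames
  gappy <- sig
  gappy$t[gappy$t >= 5] <- gappy$t[gappy$t >= 5] + 5
  write_signal_csv(gappy, path)
  expect_length(read_signal_csv(path), 2L)
})

test_that("duplicated timestamps are a data error naming the row", {
  sig <- synthesize_signal(mono_schedule("resting", 2), quiet_params(), seed = 1)
  sig$t[10] <- sig$t[9]
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  expect_error(read_signal_csv(path), "row 10")
})

test_that("missing signal columns are a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(animal_id = "a", timestamp_utc = "2020-06-01T00:00:00.000",
                                  ax_g = 0, ay_g = 0), path)
  expect_error(read_signal_csv(path), "az_g")
})

test_that("observation labels are normalized and overlaps rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(animal_id = "a", start_utc = c(0, 60),
                                  end_utc = c(60, 120),
                                  behavior = c("Grazing ", " RESTING"),
                                  source = "in_pasture"), path)
  obs <- read_observations(path)
  expect_equal(obs$behavior, c("grazing", "resting"))

  readr::write_csv(tibble::tibble(animal_id = "a", start_utc = c(0, 30),
                                  end_utc = c(60, 90), behavior = "grazing",
                                  source = "in_pasture"), path)
  expect_error(read_observations(path), "Overlapping")

  readr::write_csv(tibble::tibble(animal_id = character(), start_utc = numeric(),
                                  end_utc = numeric(), behavior = character(),
                                  source = character()), path)
  expect_equal(nrow(read_observations(path)), 0L)

  readr::write_csv(tibble::tibble(animal_id = "a", start_utc = 0, end_utc = 10,
                                  behavior = "flying", source = "in_pasture"), path)
  expect_error(read_observations(path), "flying")
})

test_that("video clips with behavior switches are removed whole", {
  clip <- function(id, t0, behaviors, cuts) {
    k <- length(behaviors)
    tibble::tibble(animal_id = "a", start_utc = t0 + c(0, cuts),
                   end_utc = t0 + c(cuts, 15), behavior = behaviors,
                   source = "collar_video", clip_id = id)
  }
  mixed <- clip("c1", 0, c("grazing", "walking"), 8)
  pure <- clip("c2", 3600, "resting", numeric(0))
  res <- filter_video_clips(dplyr::bind_rows(mixed, pure))
  expect_equal(res$n_removed_clips, 1L)
  expect_equal(unique(res$removed$clip_id), "c1")
  expect_equal(unique(res$kept$clip_id), "c2")

  # 10 clips, 3 mixed -> 7 kept, 3 removed; kept + removed partition the input
  clips <- dplyr::bind_rows(lapply(1:10, function(i) {
    if (i <= 3) clip(paste0("m", i), i * 3600, c("grazing", "resting"), 7)
    else clip(paste0("p", i), i * 3600, "grazing", numeric(0))
  }))
  res <- filter_video_clips(clips)
  expect_equal(res$n_removed_clips, 3L)
  expect_equal(dplyr::n_distinct(res$kept$clip_id), 7L)
  recombined <- dplyr::arrange(dplyr::bind_rows(res$kept, res$removed), animal_id, start_utc)
  expect_equal(nrow(recombined), nrow(clips))
  expect_setequal(paste(recombined$start_utc, recombined$behavior),
                  paste(clips$start_utc, clips$behavior))
})

test_that("clips are identified by contiguity when no clip_id is given", {
  bouts <- tibble::tibble(animal_id = "a",
                          start_utc = c(0, 8, 3600), end_utc = c(8, 15, 3615),
                          behavior = c("grazing", "walking", "resting"),
                          source = "collar_video")
  res <- filter_video_clips(bouts)
  expect_equal(nrow(res$removed), 2L)  # the two-bout clip goes as a whole
  expect_equal(res$kept$behavior, "resting")
})

test_that("label joining covers exactly the overlap, at 1-s epochs", {
  sig <- synthesize_signal(mono_schedule("grazing", 60), quiet_params(), seed = 1)
  full <- join_labels(sig, mono_schedule("grazing", 60))
  expect_equal(nrow(full), 60L)
  expect_true(all(full$behavior == "grazing"))

  tail_bout <- tibble::tibble(animal_id = "a1", start_utc = 50, end_utc = 60,
                              behavior = "walking", source = "in_pasture")
  part <- join_labels(sig, tail_bout)
  expect_equal(nrow(part), 10L)
  expect_equal(part$epoch_utc, 50:59)

  outside <- tibble::tibble(animal_id = "a1", start_utc = 100, end_utc = 160,
                            behavior = "walking", source = "in_pasture")
  expect_warning(res <- join_labels(sig, outside), "overlap")
  expect_equal(nrow(res), 0L)
})

test_that("signal-verification rules flag label/signal mismatches", {
  p <- signature_params()
  graze_sig <- synthesize_signal(mono_schedule("grazing", 40), p, seed = 1)
  rest_sig <- synthesize_signal(mono_schedule("resting", 40, animal = "a1"), p, seed = 2)
  graze_bout <- mono_schedule("grazing", 40)
  ep_ok <- flag_signal_mismatch(graze_sig, join_labels(graze_sig, graze_bout))
  expect_false(any(ep_ok$flagged))

  # a grazing label attached to a resting trace has no head-down static X
  ep_bad <- flag_signal_mismatch(rest_sig, join_labels(rest_sig, graze_bout))
  expect_true(mean(ep_bad$flagged) > 0.9)

  ep_off <- flag_signal_mismatch(rest_sig, join_labels(rest_sig, graze_bout),
                                 rules = mismatch_rules(enabled = FALSE))
  expect_false(any(ep_off$flagged))
})

test_that("nearest GPS join minimizes the offset and breaks ties earlier", {
  bout <- tibble::tibble(animal_id = "a", start_utc = 1000, end_utc = 1200,
                         behavior = "grazing", source = "in_pasture")  # midpoint 1100
  fixes <- tibble::tibble(animal_id = "a", t = c(1040, 1220), lon = c(1, 2), lat = c(1, 2))
  j <- nearest_gps_join(bout, fixes)
  expect_equal(j$fix_dt, -60)
  expect_equal(j$lon, 1)

  tie <- tibble::tibble(animal_id = "a", t = c(1040, 1160), lon = c(1, 2), lat = c(1, 2))
  expect_equal(nearest_gps_join(bout, tie)$lon, 1)  # earlier fix wins

  single <- tibble::tibble(animal_id = "a", t = 9000, lon = 5, lat = 5)
  expect_equal(nearest_gps_join(bout, single)$lon, 5)

  expect_error(nearest_gps_join(bout, tibble::tibble(animal_id = "b", t = 1,
                                                     lon = 0, lat = 0)), "No GPS fixes")
})

test_that("nearest GPS join agrees with brute force over random cases", {
  withr::with_seed(99, {
    for (i in 1:20) {
      bouts <- tibble::tibble(animal_id = "a",
                              start_utc = sort(stats::runif(5, 0, 5000)))
      bouts$end_utc <- bouts$start_utc + stats::runif(5, 1, 100)
      bouts$behavior <- "resting"; bouts$source <- "in_pasture"
      bouts <- bouts[c(TRUE, diff(bouts$start_utc) > 110), ]
      fixes <- tibble::tibble(animal_id = "a", t = sort(stats::runif(7, 0, 6000)),
                              lon = stats::rnorm(7), lat = stats::rnorm(7))
      j <- nearest_gps_join(bouts, fixes)
      mid <- (bouts$start_utc + bouts$end_utc) / 2
      best <- sapply(mid, function(m) min(abs(fixes$t - m)))
      expect_equal(abs(j$fix_dt), best, tolerance = 1e-9)
    }
  })
})

test_that("ethogram shares reproduce reported percentage arithmetic", {
  sh <- behavior_shares(c(resting = 10018, grazing = 9456, ruminating = 6106,
                          walking = 2659, grooming = 26), total = 28244)
  expect_equal(sh$share_pct[sh$behavior == "resting"], 35.5)
  expect_equal(sh$share_pct[sh$behavior == "grazing"], 33.5)
  expect_equal(sh$share_pct[sh$behavior == "walking"], 9.4)

  single <- summarize_ethogram(tibble::tibble(animal_id = "a", epoch_utc = 1:30,
                                              behavior = "resting",
                                              source = "in_pasture"))
  expect_equal(single$share_pct[single$source == "all"], 100.0)
  expect_error(summarize_ethogram(tibble::tibble(animal_id = character(),
                                                 epoch_utc = numeric(),
                                                 behavior = character(),
                                                 source = character())), "empty")
})

test_that("ethogram percentages sum to 100 within rounding", {
  study <- study_dataset(seed = 1)
  eth <- summarize_ethogram(study$epochs)
  sums <- tapply(eth$share_pct, eth$source, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("exclusion lists and mismatch flags drop the right epochs", {
  ep <- tibble::tibble(animal_id = "a", epoch_utc = 1:10,
                       behavior = "grazing", source = "in_pasture")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(animal_id = "a", epoch_utc = c(3, 7),
                                  reason = "drift"), path)
  ex <- read_exclusion_csv(path)
  out <- apply_exclusions(ep, ex)
  expect_equal(out$epoch_utc, setdiff(1:10, c(3, 7)))

  flagged <- dplyr::mutate(ep, flagged = epoch_utc <= 2,
                           flag_reason = NA_character_)
  out2 <- apply_exclusions(flagged, ex)
  expect_equal(out2$epoch_utc, setdiff(3:10, c(3, 7)))
  expect_false("flagged" %in% names(out2))
})
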