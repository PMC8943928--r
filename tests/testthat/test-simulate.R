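test_that("a null process (no bursts, no noise, no wobble) is constant gravity", {
  cfg <- uniform_config(bursts_only_params(burst_rate = 0), seed = 3)
  out <- simulate_recording(cfg, "R", "TEA", "P01")
  mag <- acc_magnitude(out$recording)
  expect_equal(mag, rep(9.81, length(mag)), tolerance = 1e-12)
  expect_equal(length(out$truth$burst_onsets), 0L)
})

test_that("simulation is deterministic in (config, group, task, id)", {
  cfg <- default_sim_config(seed = 42)
  a <- simulate_recording(cfg, "P", "GARDEN", "P07")
  b <- simulate_recording(cfg, "P", "GARDEN", "P07")
  expect_identical(a$recording$axyz, b$recording$axyz)
  expect_identical(a$truth, b$truth)
  # different id gives a different realization
  c <- simulate_recording(cfg, "P", "GARDEN", "P08")
  expect_false(identical(a$recording$axyz, c$recording$axyz))
  # and the global RNG stream is left untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_recording(cfg, "R", "TEA", "X"))
  expect_identical(before, rnorm(3))
})

test_that("unknown group/task cells are a configuration error", {
  cfg <- default_sim_config(seed = 1)
  expect_error(simulate_recording(cfg, "Q", "TEA", "P01"), "unknown")
  expect_error(simulate_recording(cfg, "R", "WALK", "P01"), "unknown")
})

test_that("frail TEA peaks stay low while robust TEA peaks reach high values", {
  cfg <- default_sim_config(seed = 5)
  max_peak <- function(grp, i) {
    sig <- preprocess(simulate_recording(cfg, grp, "TEA",
                                         sprintf("%s%02d", grp, i))$recording)
    pk <- detect_peaks(sig)
    c(max = max(pk$height), q90 = unname(stats::quantile(pk$height, 0.9)))
  }
  r <- vapply(1:5, function(i) max_peak("R", i), numeric(2))
  f <- vapply(1:5, function(i) max_peak("F", i), numeric(2))
  # robust recordings reach several m/s^2; frail peaks predominantly low
  expect_gt(max(r["max", ]), 2.5)
  expect_true(all(f["q90", ] < 1.3))
  expect_gt(mean(r["max", ]), mean(f["max", ]))
  expect_gt(max(r["max", ]), max(f["max", ]))
})

test_that("cohort composition and criteria are group-consistent", {
  cfg <- uniform_config(bursts_only_params(trial_duration = c(25, 0)),
                        seed = 2)
  coh <- simulate_cohort(cfg, c(R = 2, P = 3, F = 2))
  expect_s3_class(coh, "adl_cohort")
  expect_length(coh, 7L)
  expect_equal(sum(lengths(lapply(coh, `[[`, "recordings"))), 14L)
  for (part in coh) {
    expect_equal(part$score, sum(part$criteria))
    expect_equal(as.character(part$category), part$group)
  }
  # a single-group cohort of one
  one <- simulate_cohort(cfg, c(R = 1))
  expect_length(one, 1L)
  expect_equal(as.character(one[[1]]$category), "R")
})

test_that("pre-frail criterion draws always score 1 or 2, frail 3 to 5", {
  scores_p <- vapply(seq_len(1000), function(i) {
    sum(adlkin:::simulate_criteria(7L, paste0("P", i), "P"))
  }, numeric(1))
  expect_true(all(scores_p %in% 1:2))
  expect_true(all(1:2 %in% scores_p))  # both values actually occur
  scores_f <- vapply(seq_len(200), function(i) {
    sum(adlkin:::simulate_criteria(7L, paste0("F", i), "F"))
  }, numeric(1))
  expect_true(all(scores_f %in% 3:5))
})

test_that("active fraction approaches 1 - pause_fraction on long trials", {
  cfg <- uniform_config(bursts_only_params(pause_fraction = 0.4,
                                           trial_duration = c(300, 0)),
                        seed = 9)
  af <- vapply(1:10, function(i) {
    simulate_recording(cfg, "R", "GARDEN", paste0("L", i))$truth$active_fraction
  }, numeric(1))
  # the cohort-level mean converges tightly; individual trials carry the
  # participant-level spread of the pause fraction
  expect_lt(abs(mean(af) - 0.6), 0.05)
  expect_true(all(abs(af - 0.6) <= 0.2))
})

test_that("ground-truth pauses are non-overlapping and inside the trial", {
  cfg <- default_sim_config(seed = 13)
  out <- simulate_recording(cfg, "P", "TEA", "P03")
  pz <- out$truth$pause_intervals
  dur <- length(out$recording$t) / out$recording$sample_rate
  expect_true(all(pz[, 1] < pz[, 2]))
  expect_true(all(pz >= 0 & pz <= dur))
  if (nrow(pz) > 1) {
    expect_true(all(pz[-1, 1] >= pz[-nrow(pz), 2]))
  }
  expect_equal(out$truth$active_fraction,
               1 - sum(pz[, 2] - pz[, 1]) / dur, tolerance = 1e-9)
  # TEA carries the fixed boiling pause (60 s), GARDEN does not
  expect_true(any(abs((pz[, 2] - pz[, 1]) - 60) < 1e-6))
})

test_that("noiseless RA matches interval arithmetic on the ground truth", {
  cfg <- uniform_config(bursts_only_params(burst_rate = 0.4,
                                           amp = c(1.2, 0.4),
                                           trial_duration = c(120, 0)),
                        seed = 21)
  for (i in 1:3) {
    out <- simulate_recording(cfg, "R", "GARDEN", paste0("S", i))
    sig <- preprocess(out$recording)
    env <- truth_envelope(out$truth, length(sig$a), sig$sample_rate)
    expect_equal(relative_activity(sig), mean(env > 0.2), tolerance = 0.02)
  }
})

test_that("scaling burst amplitudes scales intensity features proportionally", {
  base_amp <- c(0.8, 0.25)
  profiles <- function(k, seed = 31) {
    cfg <- uniform_config(bursts_only_params(burst_rate = 0.6,
                                             amp = k * base_amp,
                                             trial_duration = c(90, 0)),
                          seed = seed)
    do.call(rbind, lapply(1:30, function(i) {
      sig <- preprocess(simulate_recording(cfg, "R", "GARDEN",
                                           sprintf("A%02d", i))$recording)
      extract_profile(sig)
    }))
  }
  p1 <- profiles(1)
  p2 <- profiles(2)
  for (col in c("MPA", "MAX95", "STD")) {
    ratio <- mean(p2[[col]], na.rm = TRUE) / mean(p1[[col]], na.rm = TRUE)
    expect_true(abs(ratio - 2) / 2 < 0.10,
                label = sprintf("%s ratio %.3f within 10%% of 2", col, ratio))
  }
  pps_ratio <- mean(p2$PPS) / mean(p1$PPS)
  expect_true(abs(pps_ratio - 1) < 0.10)
})

test_that("write_cohort produces readable recordings and a manifest", {
  dir <- withr::local_tempdir()
  cfg <- uniform_config(bursts_only_params(trial_duration = c(30, 0),
                                           amp = c(1, 0.2)),
                        seed = 17)
  coh <- simulate_cohort(cfg, c(R = 1, F = 1))
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(fried_criteria_names() %in% names(manifest)))
  raw <- read_recording(file.path(dir, manifest$file[1]),
                        participant_id = manifest$participant_id[1],
                        task = manifest$task[1])
  orig <- coh[[manifest$participant_id[1]]]$recordings[[manifest$task[1]]]
  expect_equal(raw$axyz, unname(orig$axyz), tolerance = 1e-6)
  expect_equal(raw$sample_rate, 100, tolerance = 1e-6)
})
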