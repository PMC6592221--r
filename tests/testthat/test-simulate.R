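test_that("configs are validated", {
  expect_error(sim_config(width_fraction = 1.5), "width_fraction")
  expect_error(sim_config(fs = 300), "divide")
  expect_error(sim_config(fs = 1000, amp_band = band_spec(400, 600),
                          phase_band = band_spec(5, 7)), "Nyquist")
  expect_error(sim_config(intensity = -1), "intensity")
  expect_error(sim_config(total_duration_s = 1), "too short")
  cfg <- sim_config()
  expect_equal(cfg$total_duration_s, 30 * 2.5 + 30)
})

test_that("simulated trial sets have the requested geometry and reproduce", {
  cfg <- sim_config(trial_length_ms = 500, n_trials = 8,
                    total_duration_s = 12, seed = 21)
  tr <- simulate_pac(cfg)
  expect_s3_class(tr, "pac_trials")
  expect_equal(nrow(tr), 8 * 500)
  expect_equal(attr(tr, "n_trials"), 8)
  expect_equal(attr(tr, "trial_length"), 500)
  expect_true(all(tr$phase > -pi & tr$phase <= pi))
  expect_true(all(tr$amplitude >= 0))
  expect_identical(tr$amplitude, simulate_pac(cfg)$amplitude)
  tr2 <- simulate_pac(sim_config(trial_length_ms = 500, n_trials = 8,
                                 total_duration_s = 12, seed = 22))
  expect_false(identical(tr$amplitude, tr2$amplitude))
})

test_that("halving the rate halves sample counts, not durations", {
  cfg <- sim_config(trial_length_ms = 500, n_trials = 6, fs = 500,
                    total_duration_s = 10, seed = 4)
  tr <- simulate_pac(cfg)
  expect_equal(nrow(tr), 6 * 250)
  per_trial_s <- tapply(tr$time_s, tr$trial, function(x) diff(range(x)))
  expect_equal(as.numeric(per_trial_s), rep(0.498, 6), tolerance = 1e-9)
})

test_that("trial placement respects margins, gaps and order", {
  for (placement in c("random", "regular")) {
    starts <- pacbench:::segment_starts(
      n_total = 50000, margin = 2000, trial_len = 1000, n_trials = 20,
      min_gap = 167, placement = placement, seed = 7)
    expect_length(starts, 20)
    expect_true(all(starts > 2000))
    expect_true(all(starts + 1000 - 1 <= 48000))
    expect_true(all(diff(starts) >= 1000 + 167))
  }
  expect_error(pacbench:::segment_starts(5000, 2000, 1000, 20, 167,
                                         "random", 1), "too short")
})

test_that("concatenated trials are a strict subsequence of source time", {
  cfg <- sim_config(trial_length_ms = 400, n_trials = 10,
                    total_duration_s = 20, seed = 31)
  tr <- simulate_pac(cfg)
  src_idx <- round(tr$time_s * cfg$fs)
  # strictly increasing within trials, with at least one slow cycle between
  by_trial <- split(src_idx, tr$trial)
  for (s in by_trial) expect_equal(diff(s), rep(1, length(s) - 1))
  ends <- vapply(by_trial, max, numeric(1))
  starts <- vapply(by_trial, min, numeric(1))
  expect_true(all(starts[-1] - ends[-length(ends)] > 1000 / 7))
})

test_that("external data frames coerce to trial sets", {
  df <- data.frame(phase = runif(300, -pi, pi), amplitude = abs(rnorm(300)),
                   trial = rep(1:3, each = 100))
  tr <- as_pac_trials(df, fs = 250)
  expect_equal(attr(tr, "n_trials"), 3)
  expect_equal(attr(tr, "provenance"), "external")
  bad <- df[-1, ]
  expect_error(as_pac_trials(bad, fs = 250), "same length")
})
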