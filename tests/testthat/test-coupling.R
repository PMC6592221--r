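fs <- 1000
t1s <- (0:999) / fs
c6 <- cos(2 * pi * 6 * t1s)

test_that("extrema detection finds one peak (and trough) per cycle", {
  peaks <- find_modulation_centers(c6, "monophasic")
  expect_equal(length(peaks), 6, tolerance = 1)
  both <- find_modulation_centers(c6, "biphasic")
  expect_equal(length(both), 12, tolerance = 1)
  # peaks at phase ~ 0, troughs at ~ +/-180 degrees
  ph <- analytic_signal(c6, fs)$phase
  expect_lt(max(abs(ph[peaks])), 0.05)
  troughs <- setdiff(both, peaks)
  expect_lt(max(pi - abs(ph[troughs])), 0.05)
  # margin drops edge centers
  expect_true(all(find_modulation_centers(c6, "monophasic", margin = 200) > 200))
  expect_error(find_modulation_centers(rep(1, 100), "monophasic"), "extrema")
})

test_that("coupling implantation has the exact Hanning gain profile", {
  centers <- find_modulation_centers(c6, "monophasic", margin = 50)
  cyc <- fs / 6
  # I = 0 is the exact identity
  expect_identical(implant_coupling(c6, centers, 0, 0.25, cyc), c6)
  # gain at center = 1 + I; edges of the window unchanged
  base <- rep(1, 1000)
  g <- implant_coupling(base, centers, 1, 0.25, cyc)
  expect_equal(g[centers], rep(2, length(centers)))
  L <- round(0.25 * cyc)
  if (L %% 2 == 0) L <- L + 1
  half <- (L - 1) / 2
  expect_equal(g[centers[1] - half - 1], 1)
  expect_equal(g[centers[1] + half + 1], 1)
  g05 <- implant_coupling(base, centers, 0.5, 0.25, cyc)
  expect_equal(g05[centers], rep(1.5, length(centers)))
  # windows at the studied widths never overlap, even biphasically
  both <- find_modulation_centers(c6, "biphasic", margin = 50)
  expect_true(all(diff(both) > round(0.275 * cyc) + 1))
})

test_that("band-matched noise is calibrated to the signal RMS", {
  x <- bandpass_zero_phase(power_law_noise(20000, fs, 2, seed = 1),
                           band_spec(5, 7), fs)
  expect_identical(add_band_matched_noise(x, band_spec(5, 7), fs, 0, seed = 2), x)
  keep <- 2000:18000
  for (scale in c(0.9, 1.1)) {
    xn <- add_band_matched_noise(x, band_spec(5, 7), fs, scale, seed = 2)
    expect_equal(rms((xn - x)[keep]) / rms(x[keep]), scale, tolerance = 0.05)
  }
  n1 <- add_band_matched_noise(x, band_spec(5, 7), fs, 1, seed = 2)
  n2 <- add_band_matched_noise(x, band_spec(5, 7), fs, 1, seed = 3)
  expect_false(identical(n1, n2))
  expect_identical(n1, add_band_matched_noise(x, band_spec(5, 7), fs, 1, seed = 2))
})
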