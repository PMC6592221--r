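fs <- 1000
t10 <- (0:9999) / fs
mid <- 3000:7000

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  y <- bandpass_zero_phase(cos(2 * pi * 6 * t10), band_spec(5, 7), fs)
  expect_equal(max(y[mid]), 1, tolerance = 0.05)
  y20 <- bandpass_zero_phase(cos(2 * pi * 20 * t10), band_spec(5, 7), fs)
  expect_lt(rms(y20[mid]), 0.01)
})

test_that("kernel is symmetric and the filter has zero net phase", {
  fir <- design_fir_bandpass(band_spec(5, 7), fs)
  expect_equal(fir$taps, rev(fir$taps), tolerance = 1e-14)
  expect_equal(fir$order %% 2, 0)
  # time-reversal commutes with a zero-phase filter
  x <- power_law_noise(8000, fs, beta = 2, seed = 3)
  expect_equal(bandpass_zero_phase(rev(x), band_spec(5, 7), fs),
               rev(bandpass_zero_phase(x, band_spec(5, 7), fs)),
               tolerance = 1e-9)
  # delay compensation: filtered 6 Hz tone peaks align with the input's
  y <- bandpass_zero_phase(cos(2 * pi * 6 * t10), band_spec(5, 7), fs)
  lag <- which.max(ccf(y[mid], cos(2 * pi * 6 * t10)[mid], lag.max = 20,
                       plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
})

test_that("stop-band attenuation exceeds 40 dB one transition width out", {
  fir <- design_fir_bandpass(band_spec(5, 7), fs)
  f_probe <- c(5 - 2 * fir$transition_hz, 7 + 2 * fir$transition_hz)
  k <- seq(-fir$delay, fir$delay)
  for (f in f_probe) {
    gain <- Mod(sum(fir$taps * exp(-2i * pi * f * k / fs)))
    expect_lt(20 * log10(gain), -40)
  }
  expect_error(design_fir_bandpass(band_spec(5, 600), fs), "Nyquist")
})

test_that("analytic signal recovers amplitude and phase of a cosine", {
  x <- 3 * cos(2 * pi * 6 * t10)
  a <- analytic_signal(x, fs)
  expect_equal(mean(a$amplitude[mid]), 3, tolerance = 1e-3)
  expect_true(all(a$phase > -pi & a$phase <= pi))
  # cosine convention: phase ~ 0 at sample-time maxima
  peaks <- which(diff(sign(diff(x))) < 0) + 1
  peaks <- peaks[peaks > 2000 & peaks < 8000]
  expect_lt(max(abs(a$phase[peaks])), 0.05)
  # instantaneous frequency ~ 6 cycles/s
  dphi <- diff(a$phase[mid])
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi) * fs / (2 * pi), 6, tolerance = 0.01)
})

test_that("paired Hilbert transform is exact", {
  withr::with_seed(5, {
    a1 <- abs(rnorm(4096))
    a2 <- abs(rnorm(4096))
  })
  hp <- pacbench:::hilbert_pair(a1, a2)
  expect_equal(hp$h1, Im(pacbench:::hilbert_analytic(a1)), tolerance = 1e-12)
  expect_equal(hp$h2, Im(pacbench:::hilbert_analytic(a2)), tolerance = 1e-12)
})

test_that("resampling preserves duration, content and band power", {
  x <- cos(2 * pi * 6 * t10)
  y <- resample_signal(x, 1000, 500)
  expect_length(y, 5000)
  a <- analytic_signal(y, 500)
  dphi <- diff(a$phase[1500:3500])
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi) * 500 / (2 * pi), 6, tolerance = 0.01)
  # band power in 50-70 Hz preserved within 5%
  g <- bandpass_zero_phase(power_law_noise(20000, 1000, 2, seed = 8),
                           band_spec(50, 70), 1000)
  g5 <- resample_signal(g, 1000, 500)
  expect_equal(rms(g5[2000:8000]) / rms(g[4000:16000]), 1, tolerance = 0.05)
  expect_error(resample_signal(x, 1000, 100, max_band_hz = 70), "Nyquist")
  expect_error(resample_signal(x, 1000, 300), "integer")
})
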