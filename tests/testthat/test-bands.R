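test_that("amplitude band spans the modulation sidebands", {
  expect_equal(as.numeric(amplitude_band_limits(band_spec(5, 7), 40)),
               c(33, 47))
  expect_equal(as.numeric(amplitude_band_limits(band_spec(8, 10), 60)),
               c(50, 70))
})

test_that("degenerate amplitude bands are rejected", {
  expect_error(amplitude_band_limits(band_spec(8, 10), 9), "too low")
  expect_error(band_spec(7, 5), "exceed")
  expect_error(band_spec(0, 5))
})

test_that("frequency-pair presets give the two canonical pairs", {
  th <- pac_frequency_pair("theta_low_gamma")
  expect_equal(as.numeric(th$phase_band), c(5, 7))
  expect_equal(as.numeric(th$amp_band), c(33, 47))
  al <- pac_frequency_pair("alpha_high_gamma")
  expect_equal(as.numeric(al$phase_band), c(8, 10))
  expect_equal(as.numeric(al$amp_band), c(50, 70))
})
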