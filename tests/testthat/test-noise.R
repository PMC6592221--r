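test_that("spectral slope tracks the requested exponent", {
  slopes0 <- vapply(1:5, function(s) {
    spectral_slope(power_law_noise(4000, 1000, beta = 0, seed = s), 1000)
  }, numeric(1))
  expect_lt(abs(mean(slopes0)), 0.15)

  slopes2 <- vapply(1:5, function(s) {
    spectral_slope(power_law_noise(60000, 1000, beta = 2, seed = s), 1000)
  }, numeric(1))
  expect_gt(mean(slopes2), -2.3)
  expect_lt(mean(slopes2), -1.7)
})

test_that("noise is zero-mean, unit-sd and seed-deterministic", {
  x <- power_law_noise(5000, 500, beta = 2, seed = 42)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_identical(x, power_law_noise(5000, 500, beta = 2, seed = 42))
  expect_false(identical(x, power_law_noise(5000, 500, beta = 2, seed = 43)))
})

test_that("degenerate noise requests are rejected", {
  expect_error(power_law_noise(100, 1000, beta = 2, seed = 1), "2 \\* fs")
  expect_error(power_law_noise(5000, 1000, beta = -1, seed = 1), "beta")
})
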