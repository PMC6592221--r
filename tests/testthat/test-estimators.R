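test_that("hand-evaluated toy cases are reproduced exactly", {
  # six phase differences {0,0,0,pi,pi,pi} cancel: build via equal phases and
  # an envelope whose second-Hilbert phase we control is awkward, so check
  # the resultant arithmetic through mvl on explicit vectors instead.
  toy <- toy_trials(phase = c(0, pi / 2, -pi / 2, 0), amplitude = c(2, 1, 1, 2))
  expect_equal(pac_mvl(toy)$value, 1.0, tolerance = 1e-12)
  expect_equal(pac_mvl_direct(toy)$value,
               4 / sqrt(4 * 10), tolerance = 1e-12)

  # uniform phases with constant amplitude cancel completely
  unif <- toy_trials(phase = seq(-pi + pi / 6, pi, by = pi / 6),
                     amplitude = rep(2, 12))
  expect_equal(pac_mvl(unif)$value, 0, tolerance = 1e-12)
  # all phases aligned: mvl = mean amplitude; with constant amplitude the
  # direct mvl attains its Cauchy-Schwarz bound of 1
  aligned <- toy_trials(phase = rep(0, 5), amplitude = c(1, 2, 3, 4, 5))
  expect_equal(pac_mvl(aligned)$value, 3, tolerance = 1e-12)
  const <- toy_trials(phase = rep(0.7, 6), amplitude = rep(2.5, 6))
  expect_equal(pac_mvl_direct(const)$value, 1, tolerance = 1e-12)
})

test_that("modulation index closed forms hold", {
  n_bins <- 18
  # equal mean amplitude in all bins -> MI = 0
  ph <- rep(seq(-pi + pi / n_bins, pi, by = 2 * pi / n_bins), each = 4)
  flat <- toy_trials(ph, rep(1, length(ph)))
  expect_equal(pac_mi(flat)$value, 0, tolerance = 1e-12)
  # all amplitude mass in one bin -> MI = 1
  spike <- toy_trials(ph, ifelse(abs(ph) < pi / n_bins, 1, 0))
  expect_equal(pac_mi(spike)$value, 1, tolerance = 1e-12)
  # two equal bins -> (ln 18 - ln 2)/ln 18
  two <- toy_trials(ph, as.numeric(abs(ph) < 2 * pi / n_bins + 1e-9))
  expect_equal(pac_mi(two)$value, (log(18) - log(2)) / log(18),
               tolerance = 1e-12)
  # empty bin rejected with a diagnostic
  expect_error(pac_mi(toy_trials(runif(20, 0, 1), rep(1, 20))), "bin")
})

test_that("estimators match naive loop implementations", {
  for (seed in 1:8) {
    d <- random_phase_amp(400, seed)
    tr <- toy_trials(d$phase, d$amplitude)
    expect_equal(pac_plv(tr)$value, naive_plv(d$phase, d$amplitude),
                 tolerance = 1e-10)
    expect_equal(pac_mvl(tr)$value, naive_mvl(d$phase, d$amplitude),
                 tolerance = 1e-10)
    expect_equal(pac_mvl_direct(tr)$value,
                 naive_direct_mvl(d$phase, d$amplitude), tolerance = 1e-10)
    expect_equal(pac_mi(tr)$value, naive_mi(d$phase, d$amplitude),
                 tolerance = 1e-10)
  }
})

test_that("range and scaling invariants hold on random inputs", {
  for (seed in 11:16) {
    d <- random_phase_amp(600, seed)
    tr <- toy_trials(d$phase, d$amplitude)
    tr10 <- toy_trials(d$phase, 10 * d$amplitude)
    plv <- pac_plv(tr)$value
    expect_gte(plv, 0); expect_lte(plv, 1)
    mi <- pac_mi(tr)$value
    expect_gte(mi, 0); expect_lte(mi, 1)
    dm <- pac_mvl_direct(tr)$value
    expect_gte(dm, 0); expect_lte(dm, 1)
    # mvl scales linearly; mi/direct mvl are scale-invariant
    expect_equal(pac_mvl(tr10)$value, 10 * pac_mvl(tr)$value,
                 tolerance = 1e-12)
    expect_equal(pac_mi(tr10)$value, mi, tolerance = 1e-12)
    expect_equal(pac_mvl_direct(tr10)$value, dm, tolerance = 1e-12)
  }
})

test_that("phase-amplitude histogram is a proper distribution", {
  d <- random_phase_amp(2000, 3)
  h <- phase_amplitude_histogram(toy_trials(d$phase, d$amplitude))
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_true(all(h$p >= 0))
  expect_equal(sum(h$n), 2000)
  expect_equal(h$bin_center_deg[1], -170)
  expect_equal(h$bin_center_deg[18], 170)
  # +pi wraps into the last bin
  hp <- phase_amplitude_histogram(
    toy_trials(c(rep(pi, 5), seq(-pi + 0.1, pi - 0.2, length.out = 100)),
               rep(1, 105)))
  expect_equal(hp$n[18], 5 + sum(seq(-pi + 0.1, pi - 0.2, length.out = 100) >=
                                   pi - 2 * pi / 18))
})

test_that("biphasic envelopes cancel the mean vector but not the MI", {
  n <- 6000
  ph <- seq(-pi, pi - 2 * pi / n, length.out = n)
  amp_bi <- 1 + 0.8 * cos(2 * ph)   # bumps at 0 and +/-pi
  tr <- toy_trials(ph, amp_bi)
  expect_lt(pac_mvl(tr)$value, 1e-3)
  expect_gt(pac_mi(tr)$value, 0.001)
  expect_gt(pac_glm(tr)$value, 0.5)
})

test_that("degenerate estimator inputs are rejected", {
  expect_error(pac_plv(toy_trials(c(0, 1, 2), rep(2, 3))), "constant")
  expect_error(pac_mvl_direct(toy_trials(c(0, 1), c(0, 0))), "zero")
  expect_error(pac_glm(toy_trials(runif(500, -pi, pi),
                                  c(-1, abs(rnorm(499))))), "positive")
})
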