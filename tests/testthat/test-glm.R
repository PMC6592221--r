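test_that("gamma/log IRLS matches stats::glm to machine precision", {
  withr::with_seed(4, {
    ph <- runif(2000, -pi, pi)
    am <- exp(0.3 * cos(ph)) * rgamma(2000, shape = 5, rate = 5)
  })
  for (p in c(5, 10)) {
    B <- pacbench:::cyclic_phase_basis(ph, p)
    ref <- glm(am ~ B - 1, family = Gamma(link = "log"))
    d <- pacbench:::glm_design(B)
    own <- pacbench:::fit_gamma_log_batch(d, matrix(am))
    expect_equal(as.numeric(own$beta), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(own$deviance, unname(deviance(ref)), tolerance = 1e-8)
  }
})

test_that("the statistic recovers known modulation depths", {
  n <- 4000
  ph <- seq(-pi, pi - 2 * pi / n, length.out = n)
  # flat envelope -> statistic ~ 0
  withr::with_seed(9, flat <- rep(2, n) * (1 + 0.001 * rnorm(n)))
  expect_lt(pac_glm(toy_trials(ph, flat))$value, 0.01)
  # 50% sinusoidal modulation -> statistic ~ 0.5
  stat <- pac_glm(toy_trials(ph, 2 * (1 + 0.5 * cos(ph))))$value
  expect_equal(stat, 0.5, tolerance = 0.02)
  # biphasic modulation detected
  expect_gt(pac_glm(toy_trials(ph, 2 * (1 + 0.5 * cos(2 * ph))))$value, 0.3)
  # invariant to amplitude scale
  expect_equal(pac_glm(toy_trials(ph, 20 * (1 + 0.5 * cos(ph))))$value,
               stat, tolerance = 1e-10)
})

test_that("AIC scan selects a sensible control-point count", {
  n <- 3000
  ph <- seq(-pi, pi - 2 * pi / n, length.out = n)
  withr::with_seed(2, am <- (1 + 0.5 * cos(ph)) * rgamma(n, 8, 8))
  res <- pac_glm(toy_trials(ph, am), select_by_aic = TRUE)
  p_sel <- attr(res, "n_control_points")
  expect_gte(p_sel, 4)
  expect_lte(p_sel, 12)
  expect_equal(res$value, 0.5, tolerance = 0.15)
})

test_that("periodic basis is smooth across the phase wrap", {
  B <- pacbench:::cyclic_phase_basis(c(-pi + 1e-9, pi - 1e-9), 10)
  expect_equal(B[1, ], B[2, ], tolerance = 1e-6)
  expect_equal(rowSums(pacbench:::cyclic_phase_basis(runif(50, -pi, pi), 10)),
               rep(1, 50), tolerance = 1e-10)
})
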