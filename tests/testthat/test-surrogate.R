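test_that("cut-and-swap conserves each trial's amplitude multiset", {
  d <- random_phase_amp(900, 5)
  tr <- toy_trials(d$phase, d$amplitude, trial = rep(1:3, each = 300))
  perm <- permute_amplitude(tr, seed = 11)
  expect_identical(perm$phase, tr$phase)
  for (j in 1:3) {
    orig <- tr$amplitude[tr$trial == j]
    shuf <- perm$amplitude[perm$trial == j]
    expect_equal(sort(orig), sort(shuf))
    # a circular rotation, and never the identity rotation
    expect_false(identical(orig, shuf))
    hits <- vapply(seq_along(orig) - 1, function(c) {
      identical(shuf, c(orig[(c + 1):length(orig)], orig[seq_len(c)]))
    }, logical(1))
    expect_equal(sum(hits), 1)
  }
  expect_identical(permute_amplitude(tr, seed = 11)$amplitude, perm$amplitude)
})

test_that("z-standardization follows the shuffled-distribution formula", {
  expect_equal(z_standardize(4, c(1, 2, 3))$z, 2.0)  # sd with n-1 is 1
  expect_equal(z_standardize(2, c(1, 2, 3))$z, 0.0)
  s <- rnorm(50)
  expect_equal(z_standardize(mean(s) + sd(s), s)$z, 1, tolerance = 1e-12)
  expect_error(z_standardize(1, c(2)), "at least 2")
  expect_error(z_standardize(1, rep(3, 10)), "zero spread")
})

test_that("empirical critical z is the 95th percentile of the null", {
  withr::with_seed(1, z <- rnorm(20000))
  expect_equal(empirical_critical_z(z), qnorm(0.95), tolerance = 0.03)
  expect_equal(empirical_critical_z(z, alpha = 0.5), median(z),
               tolerance = 1e-9)
  expect_error(empirical_critical_z(rnorm(50)), "100")
  # calibration identity: ~alpha of the inputs exceed the threshold
  withr::with_seed(2, zz <- rexp(400))
  crit <- empirical_critical_z(zz)
  expect_true(sum(zz > crit) %in% c(floor(0.05 * 400), ceiling(0.05 * 400)))
})

test_that("estimate_pac surrogate machinery matches brute-force permutation", {
  d <- random_phase_amp(750, 6)
  tr <- toy_trials(d$phase, d$amplitude, trial = rep(1:5, each = 150))
  res <- estimate_pac(tr, method = c("plv", "mvl", "direct_mvl", "mi"),
                      n_perm = 30, seed = 77, keep_surrogates = TRUE)
  surr <- attr(res, "surrogates")
  cuts <- withr::with_seed(77L, matrix(sample.int(149L, 5L * 30L, TRUE), 5L, 30L))
  for (p in c(1, 7, 30)) {
    ap <- as.numeric(unlist(lapply(1:5, function(j) {
      a <- d$amplitude[((j - 1) * 150 + 1):(j * 150)]
      c(a[(cuts[j, p] + 1):150], a[seq_len(cuts[j, p])])
    })))
    expect_equal(unname(surr[p, "plv"]), naive_plv(d$phase, ap), tolerance = 1e-10)
    expect_equal(unname(surr[p, "mvl"]), naive_mvl(d$phase, ap), tolerance = 1e-10)
    expect_equal(unname(surr[p, "direct_mvl"]), naive_direct_mvl(d$phase, ap),
                 tolerance = 1e-10)
    expect_equal(unname(surr[p, "mi"]), naive_mi(d$phase, ap), tolerance = 1e-10)
  }
  # PACResult invariant: z recomputes from its own columns
  expect_equal(res$z, (res$raw - res$surrogate_mean) / res$surrogate_sd,
               tolerance = 1e-12)
})

test_that("permuted MVL z is exactly invariant to amplitude scaling", {
  d <- random_phase_amp(600, 8)
  tr <- toy_trials(d$phase, d$amplitude, trial = rep(1:4, each = 150))
  tr_scaled <- toy_trials(d$phase, 7.3 * d$amplitude, trial = rep(1:4, each = 150))
  z1 <- estimate_pac(tr, "mvl", n_perm = 40, seed = 5)
  z2 <- estimate_pac(tr_scaled, "mvl", n_perm = 40, seed = 5)
  expect_equal(z2$raw, 7.3 * z1$raw, tolerance = 1e-12)
  expect_equal(z2$z, z1$z, tolerance = 1e-10)
})

test_that("degenerate surrogate requests error out", {
  d <- random_phase_amp(300, 9)
  tr <- toy_trials(d$phase, d$amplitude, trial = rep(1:2, each = 150))
  expect_error(estimate_pac(tr, "mvl", n_perm = 1, seed = 1), "at least 2")
  tiny <- toy_trials(c(0, 1, 2, 3), c(1, 2, 3, 4), trial = rep(1:2, each = 2))
  expect_error(estimate_pac(tiny, "mvl", n_perm = 5, seed = 1), "3 samples")
})

test_that("significance flags honour supplied critical values", {
  cfg <- sim_config(intensity = 1.1, trial_length_ms = 1000, n_trials = 10,
                    seed = 14)
  tr <- simulate_pac(cfg)
  res <- estimate_pac(tr, c("mvl", "mi"), n_perm = 60, seed = 3,
                      critical_z = c(mvl = 1.91, mi = 1.94))
  expect_type(res$significant, "logical")
  res2 <- estimate_pac(tr, "mvl", n_perm = 60, seed = 3)
  expect_true(is.na(res2$significant))
})
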