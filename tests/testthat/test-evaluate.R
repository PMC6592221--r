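# Small-scale study runs: structure, determinism and balanced-design
# identities (the statistical calibration itself is exercised in
# test-acceptance.R at larger n).

test_that("specificity runs produce tidy per-cell null tables", {
  spec <- suppressWarnings(run_specificity(
    pair = "theta_low_gamma", methods = c("mvl", "mi"),
    n_sims = 2, n_perm = 30, data_length_ms = c(400, 2500),
    sampling_rate = 1000, noise_scale = 1, master_seed = 5))
  expect_s3_class(spec, "pac_specificity")
  expect_equal(nrow(spec$z), 2 * 2 * 2)  # datasets x lengths x methods
  expect_setequal(unique(spec$z$method), c("mvl", "mi"))
  expect_true(all(is.finite(spec$z$z)))
  expect_true(all(spec$z$intensity == 0))
  # identical master seed reproduces every z exactly
  spec2 <- suppressWarnings(run_specificity(
    pair = "theta_low_gamma", methods = c("mvl", "mi"),
    n_sims = 2, n_perm = 30, data_length_ms = c(400, 2500),
    sampling_rate = 1000, noise_scale = 1, master_seed = 5))
  expect_equal(spec$z$z, spec2$z$z, tolerance = 1e-14)
})

test_that("sensitivity marginals satisfy the balanced-average identity", {
  sens <- run_sensitivity(
    pair = "theta_low_gamma", methods = c("mvl", "mi"),
    n_sims = 2, n_perm = 30, intensity = c(0.9, 1.1),
    width_fraction = 0.25, data_length_ms = 2500,
    sampling_rate = 1000, noise_scale = c(0.9, 1.1), master_seed = 9)
  # 2 intensities x 2 modes x 2 noise levels x 2 datasets x 2 methods
  expect_equal(nrow(sens$z), 2 * 2 * 2 * 2 * 2)
  mm_mode <- marginal_means(sens, "multimodality")
  mm_all <- marginal_means(sens, "method")
  for (m in c("mvl", "mi")) {
    expect_equal(mm_all$mean_z[mm_all$method == m],
                 mean(mm_mode$mean_z[mm_mode$method == m]),
                 tolerance = 1e-12)
  }
  mm_i <- marginal_means(sens, "intensity")
  for (m in c("mvl", "mi")) {
    expect_equal(mm_all$mean_z[mm_all$method == m],
                 mean(mm_i$mean_z[mm_i$method == m]), tolerance = 1e-12)
  }
  # significance flags appear when criticals are supplied
  sens_c <- run_sensitivity(
    pair = "theta_low_gamma", methods = "mvl", n_sims = 1, n_perm = 30,
    intensity = 1.1, width_fraction = 0.25, data_length_ms = 2500,
    sampling_rate = 1000, noise_scale = 1, master_seed = 9,
    critical = c(mvl = 1.91))
  expect_type(sens_c$z$significant, "logical")
})

test_that("the factorial grid enumerates the study cells", {
  g <- pac_grid()
  expect_equal(nrow(g), 3 * 3 * 2 * 3 * 2 * 3)
  expect_equal(dplyr::n_distinct(g$cell), nrow(g))
  g0 <- pac_grid(intensity = 0, width_fraction = 0.25,
                 multimodality = "monophasic")
  expect_equal(nrow(g0), 18)
})

test_that("false-positive subsampling counts exceedances per block", {
  expect_equal(subsample_false_positives(rep(0, 100), 1.9, 50), c(0L, 0L))
  z <- c(rep(0, 48), 5, 5, rep(0, 49), 5)
  expect_equal(subsample_false_positives(z, 1.9, 50), c(2L, 1L))
  # remainder truncated
  expect_equal(length(subsample_false_positives(rep(0, 130), 1.9, 50)), 2)
  expect_error(subsample_false_positives(rep(0, 30), 1.9, 50), "exceeds")
})

test_that("glm replication can be reduced independently", {
  spec <- suppressWarnings(run_specificity(
    pair = "theta_low_gamma", methods = c("mvl", "glm_cfc"),
    n_sims = 2, n_perm = 20, glm_n_sims = 1, glm_n_perm = 10,
    data_length_ms = 400, sampling_rate = 1000, noise_scale = 1,
    master_seed = 3))
  counts <- table(spec$z$method)
  expect_equal(unname(counts["mvl"]), 2L)
  expect_equal(unname(counts["glm_cfc"]), 1L)
  expect_equal(unique(spec$z$n_perm[spec$z$method == "glm_cfc"]), 10)
})
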