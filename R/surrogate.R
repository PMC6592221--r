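#' Cut-and-swap surrogate of a trial set
#'
#' For each trial independently, the amplitude series is cut at a uniformly
#' random point `c` in `[1, len - 1]` and the two parts are swapped
#' (`c(amp[(c+1):len], amp[1:c])`), i.e. circularly rotated.  This destroys
#' the temporal alignment between phase and amplitude while leaving every
#' other property of the series intact: the amplitude multiset per trial is
#' preserved exactly, and the phase series is untouched.  `c = 0` is
#' excluded, so a surrogate is never identical to the input by construction.
#'
#' @param trials a `pac_trials` object (or data frame with `phase`,
#'   `amplitude`, `trial`).
#' @param seed optional integer seed.
#' @return A `pac_trials` object with permuted amplitudes.
#' @export
permute_amplitude <- function(trials, seed = NULL) {
  trials <- as_pac_trials(trials, fs = attr(trials, "fs") %||% NA_real_)
  geom <- trial_geometry(trials)
  if (geom$trial_len < 3) abort("each trial must have at least 3 samples")
  cuts <- with_seed_or_current(seed,
    sample.int(geom$trial_len - 1L, geom$n_trials, replace = TRUE))
  out <- trials
  out$amplitude <- rotate_trials_cpp(as.numeric(trials$amplitude),
                                     cuts, geom$trial_len)
  out
}

# Concatenated-sample index implementing per-trial rotation by `cuts`.
rotation_index <- function(cuts, trial_len, n_trials) {
  trial_len <- as.integer(trial_len)
  cuts <- as.integer(cuts)
  rel <- 0:(trial_len - 1L)
  offsets <- rep((seq_len(n_trials) - 1L) * trial_len, each = trial_len)
  as.vector(vapply(seq_len(n_trials),
                   function(j) (rel + cuts[j]) %% trial_len,
                   integer(trial_len))) + offsets + 1L
}

#' Standardize an observed coupling value against surrogates
#'
#' \eqn{z = (CV_{obs} - \mu_{shuffled}) / \sigma_{shuffled}}, with the
#' sample standard deviation (`n - 1` denominator).
#'
#' @param observed observed coupling value.
#' @param surrogate_values numeric vector of surrogate coupling values
#'   (at least 2, with nonzero spread).
#' @return A one-row tibble: `raw`, `surrogate_mean`, `surrogate_sd`, `z`,
#'   `n_perm`.
#' @export
z_standardize <- function(observed, surrogate_values) {
  assert_scalar_number(observed, "observed")
  if (length(surrogate_values) < 2) {
    abort("need at least 2 surrogate values (SD undefined otherwise)")
  }
  mu <- mean(surrogate_values)
  sigma <- sd(surrogate_values)
  if (sigma == 0) abort("degenerate null: surrogate values have zero spread")
  tibble::tibble(raw = observed, surrogate_mean = mu, surrogate_sd = sigma,
                 z = (observed - mu) / sigma,
                 n_perm = length(surrogate_values))
}

#' Empirical critical z-value from a null distribution
#'
#' The phase-amplitude coupling z-distribution under the null hypothesis is
#' not standard normal (the raw statistics are bounded and their surrogate
#' distributions skewed), so significance is not inferred from the Gaussian
#' 1.64 but from the empirical `(1 - alpha)` quantile of simulated null
#' z-values (type-7 linear interpolation).
#'
#' @param null_z numeric vector of z-values from no-coupling simulations
#'   (at least 100).
#' @param alpha nominal false-positive rate.
#' @return The critical z (single number).
#' @export
empirical_critical_z <- function(null_z, alpha = 0.05) {
  if (length(null_z) < 100) abort("need at least 100 null z-values")
  assert_scalar_number(alpha, "alpha", lower = 1e-6, upper = 1 - 1e-6)
  unname(quantile(null_z, probs = 1 - alpha, type = 7, names = FALSE))
}

pac_methods <- c("plv", "mvl", "direct_mvl", "mi", "glm_cfc")

#' Estimate phase-amplitude coupling with surrogate standardization
#'
#' Computes the raw coupling value on the observed trials, builds a
#' surrogate distribution from `n_perm` within-trial cut-and-swap
#' permutations of the amplitude series ([permute_amplitude()]), and
#' z-standardizes the observed value against it ([z_standardize()]).
#' Surrogate cut points are drawn independently per trial and per
#' permutation from the derived seed, so results are exactly reproducible.
#'
#' For the GLM measure, an optional AIC scan selects the control-point
#' count on the observed data; surrogates are refit at the selected count.
#'
#' @inheritParams pac_estimators
#' @param method one or more of `"plv"`, `"mvl"`, `"direct_mvl"`, `"mi"`,
#'   `"glm_cfc"`.
#' @param n_perm number of permutations (commonly 200 to 1000).
#' @param seed integer seed for the surrogate draws.
#' @param critical_z optional critical value (scalar or named by method);
#'   fills the `significant` column.
#' @param keep_surrogates keep the full surrogate value vectors (attribute
#'   `surrogates`).
#' @return A `pac_result` tibble, one row per method, with columns `method`,
#'   `raw`, `surrogate_mean`, `surrogate_sd`, `z`, `n_perm`, `seed`,
#'   `significant`.
#' @examples
#' trials <- simulate_pac(sim_config(intensity = 1, trial_length_ms = 1000,
#'                                   n_trials = 10, seed = 3))
#' estimate_pac(trials, method = c("mvl", "mi"), n_perm = 100, seed = 9)
#' @export
estimate_pac <- function(trials, method = c("plv", "mvl", "mi", "glm_cfc"),
                         n_perm = 1000, seed = NULL, critical_z = NULL,
                         n_bins = 18, envelope_prefilter = NULL,
                         n_control_points = 10, select_by_aic = FALSE,
                         keep_surrogates = FALSE) {
  method <- match.arg(method, pac_methods, several.ok = TRUE)
  trials <- as_pac_trials(trials, fs = attr(trials, "fs") %||% NA_real_)
  if (n_perm < 2) abort("`n_perm` must be at least 2 (surrogate SD undefined)")
  geom <- trial_geometry(trials)
  seed <- seed %||% derive_seed(sample.int(2^30, 1))
  prefir <- NULL
  if (!is.null(envelope_prefilter)) {
    fs <- attr(trials, "fs")
    if (!is.finite(fs)) abort("envelope pre-filtering needs an `fs` attribute")
    prefir <- design_fir_bandpass(envelope_prefilter, fs)
  }
  res <- surrogate_stats(
    phase = as.numeric(trials$phase), amplitude = as.numeric(trials$amplitude),
    trial_len = geom$trial_len, n_trials = geom$n_trials,
    methods = method, n_perm = as.integer(n_perm), seed = seed,
    n_bins = n_bins, envelope_prefilter_fir = prefir,
    glm_opts = list(n_control_points = n_control_points,
                    select_by_aic = select_by_aic),
    keep_surrogates = keep_surrogates)
  out <- res$summary
  out$seed <- seed
  crit <- resolve_critical(critical_z, out$method)
  out$significant <- ifelse(is.na(crit), NA, out$z > crit)
  class(out) <- c("pac_result", class(out))
  if (keep_surrogates) attr(out, "surrogates") <- res$surrogates
  out
}

resolve_critical <- function(critical_z, methods) {
  if (is.null(critical_z)) return(rep(NA_real_, length(methods)))
  if (!is.null(names(critical_z))) {
    unname(critical_z[methods])
  } else {
    rep(as.numeric(critical_z), length(methods))
  }
}

# ---------------------------------------------------------------------------
# Vectorized surrogate engine.
#
# All requested statistics are computed inside one loop over permutation
# blocks, sharing the rotated-amplitude matrix.  Per block of size m:
#   MVL / direct MVL : one crossprod against [cos theta, sin theta];
#   MI               : one rowsum() by precomputed phase-bin index
#                      (the phase series never changes under amplitude
#                      permutation, so binning is done once);
#   GLM-CFC          : batched IRLS -- the basis QR is fixed, each iteration
#                      solves all m working responses in one call;
#   PLV              : the only statistic needing a transform per surrogate;
#                      consecutive surrogate pairs share one FFT/IFFT via
#                      hilbert_pair().
surrogate_stats <- function(phase, amplitude, trial_len, n_trials,
                            methods, n_perm, seed, n_bins = 18,
                            envelope_prefilter_fir = NULL,
                            glm_opts = list(n_control_points = 10,
                                            select_by_aic = FALSE),
                            chunk_size = NULL, keep_surrogates = FALSE) {
  # GLM iterations allocate several temporaries per block; keeping blocks
  # near 10 columns avoids malloc/mmap churn on long series.  The other
  # statistics are one BLAS/rowsum pass per block and favor larger blocks.
  chunk_size <- chunk_size %||% (if ("glm_cfc" %in% methods) 10L else 50L)
  n <- trial_len * n_trials
  stopifnot(length(phase) == n, length(amplitude) == n)
  if (trial_len < 3) abort("each trial must have at least 3 samples")

  want <- function(m) m %in% methods
  cos_t <- if (want("plv") || want("mvl") || want("direct_mvl")) cos(phase)
  sin_t <- if (!is.null(cos_t)) sin(phase)
  cs <- if (want("mvl") || want("direct_mvl")) cbind(cos_t, sin_t)
  sumsq <- if (want("direct_mvl")) sum(amplitude^2)
  if (want("direct_mvl") && sumsq <= 0) abort("all-zero amplitude envelope")
  bins <- counts <- NULL
  if (want("mi")) {
    bins <- mi_bin_index(phase, n_bins)
    counts <- tabulate(bins, n_bins)
    if (any(counts == 0)) {
      abort(sprintf("empty phase bin(s): too few samples for %d bins", n_bins))
    }
  }
  glm_env <- NULL
  if (want("glm_cfc")) {
    if (any(amplitude <= 0)) abort("amplitudes must be strictly positive for the gamma GLM")
    obs_fit <- glm_cfc_fit(phase, amplitude,
                           n_control_points = glm_opts$n_control_points,
                           select_by_aic = isTRUE(glm_opts$select_by_aic))
    glm_env <- list(
      design = obs_fit$design,
      grid = cyclic_phase_basis(glm_phase_grid(), obs_fit$n_control_points),
      beta_init = obs_fit$beta,
      amp_mean = mean(amplitude), observed = obs_fit$statistic)
  }

  observed <- c(
    plv = if (want("plv")) plv_stat(amplitude, phase, cos_t, sin_t,
                                    envelope_prefilter_fir),
    mvl = if (want("mvl")) Mod(mean(amplitude * exp(1i * phase))),
    direct_mvl = if (want("direct_mvl")) {
      Mod(sum(amplitude * exp(1i * phase))) / sqrt(n * sumsq)
    },
    mi = if (want("mi")) {
      abar <- as.numeric(rowsum(amplitude, bins)) / counts
      mi_from_p(abar / sum(abar), n_bins)
    },
    glm_cfc = if (want("glm_cfc")) glm_env$observed
  )

  cuts <- with_seed_or_current(seed,
    matrix(sample.int(trial_len - 1L, n_trials * n_perm, replace = TRUE),
           n_trials, n_perm))
  surr <- matrix(NA_real_, n_perm, length(methods),
                 dimnames = list(NULL, methods))

  # MVL, direct MVL and MI depend on the rotated series only through
  # per-trial circular cross-correlations between the amplitude and fixed
  # phase functionals, so their value at EVERY possible cut comes from a few
  # FFTs per trial -- no surrogate series is ever materialized and the cost
  # is independent of n_perm.  For small permutation counts the direct
  # rotate-and-sum evaluation is cheaper than building the tables.
  if (want("mvl") || want("direct_mvl") || want("mi")) {
    if (n_perm > 60) {
      xc <- xcorr_surrogates(amplitude, phase, bins, counts, n_bins,
                             trial_len, n_trials, cuts,
                             need_mvl = want("mvl") || want("direct_mvl"),
                             need_mi = want("mi"))
      mvl_num <- xc$mvl_num
      mi_vals <- xc$mi
    } else {
      A <- rotate_trials_block_cpp(amplitude, cuts, trial_len)
      mvl_num <- mi_vals <- NULL
      if (want("mvl") || want("direct_mvl")) {
        S <- crossprod(A, cs)
        mvl_num <- sqrt(rowSums(S^2))
      }
      if (want("mi")) {
        Mb <- rowsum(A, bins) / counts
        P <- sweep(Mb, 2, colSums(Mb), "/")
        Lp <- P
        pos <- P > 0
        Lp[pos] <- log(P[pos])
        Lp[!pos] <- 0
        mi_vals <- (log(n_bins) + colSums(P * Lp)) / log(n_bins)
      }
    }
    if (want("mvl")) surr[, "mvl"] <- mvl_num / n
    if (want("direct_mvl")) surr[, "direct_mvl"] <- mvl_num / sqrt(n * sumsq)
    if (want("mi")) surr[, "mi"] <- mi_vals
  }

  # The GLM needs the rotated responses themselves; fit them in blocks.
  if (want("glm_cfc")) {
    for (start in seq(1L, n_perm, by = chunk_size)) {
      cols <- start:min(start + chunk_size - 1L, n_perm)
      A <- rotate_trials_block_cpp(amplitude, cuts[, cols, drop = FALSE],
                                   trial_len)
      fit <- fit_gamma_log_batch(glm_env$design, A,
                                 beta_init = glm_env$beta_init)
      surr[cols, "glm_cfc"] <-
        glm_cfc_statistic(fit$beta, glm_env$amp_mean, glm_env$grid)
    }
  }

  # PLV needs a Hilbert transform per surrogate envelope: consecutive
  # surrogates are packed two-per-transform and the resultant is reduced in
  # one fused pass.
  if (want("plv")) {
    if (!is.null(envelope_prefilter_fir)) {
      for (p in seq_len(n_perm)) {
        env <- fir_filter_zero_phase(
          rotate_trials_cpp(amplitude, cuts[, p], trial_len),
          envelope_prefilter_fir)
        z <- hilbert_analytic(env)
        surr[p, "plv"] <- plv_single_cpp(Re(z), Im(z), cos_t, sin_t)
      }
    } else {
      p <- 1L
      while (p + 1L <= n_perm) {
        g <- rotate_pack_cpp(amplitude, cuts[, p], cuts[, p + 1L], trial_len)
        w <- fft(analytic_mask_apply_cpp(fft(g)), inverse = TRUE) / n
        surr[p:(p + 1L), "plv"] <- plv_pair_g_cpp(w, g, cos_t, sin_t)
        p <- p + 2L
      }
      if (p == n_perm) {
        v <- rotate_trials_cpp(amplitude, cuts[, p], trial_len)
        z <- hilbert_analytic(v)
        surr[p, "plv"] <- plv_single_cpp(Re(z), Im(z), cos_t, sin_t)
      }
    }
  }

  mu <- colMeans(surr)
  sigma <- vapply(seq_along(methods), function(j) sd(surr[, j]), numeric(1))
  if (any(sigma == 0)) abort("degenerate null: surrogate values have zero spread")
  obs <- unname(observed[methods])
  summary <- tibble::tibble(
    method = methods, raw = obs, surrogate_mean = unname(mu),
    surrogate_sd = sigma, z = (obs - unname(mu)) / sigma,
    n_perm = n_perm)
  list(summary = summary,
       surrogates = if (keep_surrogates) surr else NULL)
}

# Surrogate MVL numerators and MI values for all cuts via per-trial circular
# cross-correlation.  For a trial rotated by cut c, the rotated amplitude is
# a[(t + c) mod len], so any statistic of the form sum_t w[t] * a_rot[t] is
# the circular cross-correlation (w star a)[c] = ifft(Conj(fft(w)) * fft(a)).
# MVL uses w = exp(i * theta); MI uses one indicator w per phase bin (giving
# the rotated bin sums), with indicator pairs packed into single complex
# transforms.
xcorr_surrogates <- function(amplitude, phase, bins, counts, n_bins,
                             trial_len, n_trials, cuts,
                             need_mvl = TRUE, need_mi = TRUE) {
  n_perm <- ncol(cuts)
  mvl_acc <- if (need_mvl) complex(n_perm)
  S <- if (need_mi) matrix(0, n_perm, n_bins)   # rotated bin sums per perm
  for (j in seq_len(n_trials)) {
    rows <- ((j - 1L) * trial_len + 1L):(j * trial_len)
    Fa <- fft(amplitude[rows])
    ci <- cuts[j, ] + 1L                        # cut c indexes corr[c + 1]
    if (need_mvl) {
      W <- fft(exp(1i * phase[rows]))
      corr <- fft(Conj(W) * Fa, inverse = TRUE) / trial_len
      mvl_acc <- mvl_acc + corr[ci]
    }
    if (need_mi) {
      bj <- bins[rows]
      k <- 1L
      while (k <= n_bins) {
        k2 <- min(k + 1L, n_bins)
        # two real indicators packed into one complex transform: with real
        # amplitude, ifft(Conj(fft(w1 + i w2)) * Fa) = corr1 - i corr2
        w <- complex(real = as.numeric(bj == k),
                     imaginary = if (k2 > k) as.numeric(bj == k2) else 0)
        packed <- fft(Conj(fft(w)) * Fa, inverse = TRUE) / trial_len
        S[, k] <- S[, k] + Re(packed)[ci]
        if (k2 > k) S[, k2] <- S[, k2] - Im(packed)[ci]
        k <- k + 2L
      }
    }
  }
  out <- list()
  if (need_mvl) out$mvl_num <- Mod(mvl_acc)
  if (need_mi) {
    Mb <- sweep(S, 2, counts, "/")
    P <- Mb / rowSums(Mb)
    Lp <- P
    pos <- P > 0
    Lp[pos] <- log(P[pos])
    Lp[!pos] <- 0
    H <- -rowSums(P * Lp)
    out$mi <- (log(n_bins) - H) / log(n_bins)
  }
  out
}

# PLV of one envelope against the precomputed slow-band phase.
plv_stat <- function(env, phase, cos_t, sin_t, prefir = NULL) {
  if (sd(env) == 0) abort("constant amplitude envelope: PLV undefined")
  if (!is.null(prefir)) env <- fir_filter_zero_phase(env, prefir)
  z <- hilbert_analytic(env)
  plv_from_parts(Re(z), Im(z), cos_t, sin_t)
}

# PLV from the analytic envelope's real/imaginary parts:
# exp(-i theta_u) = (a - i h)/|z|, so the resultant splits into real sums.
plv_from_parts <- function(a, h, cos_t, sin_t) {
  r <- sqrt(a * a + h * h)
  r[r == 0] <- .Machine$double.eps
  re <- sum((cos_t * a + sin_t * h) / r)
  im <- sum((sin_t * a - cos_t * h) / r)
  sqrt(re^2 + im^2) / length(a)
}

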