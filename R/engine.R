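# Continuous-signal engine shared by simulate_pac() and the factorial
# evaluation runners.
#
# One "base" simulation holds everything derived from a single background
# noise realization: the band-passed slow and fast signals, the implanted
# coupling variants, and the band-matched noise series -- each stored as a
# complex analytic signal, at the generation rate and at every requested
# decimated rate.  Because the Hilbert transform, filtering and resampling
# are all linear, a grid cell's analytic series is a cheap linear
# combination: signal + noise_scale * calibration * noise.  This lets a
# factorial study derive hundreds of cells (intensity x width x
# multimodality x noise x rate x length) from a handful of FFTs.

phase_center_freq <- function(phase_band) {
  (phase_band[["low_hz"]] + phase_band[["high_hz"]]) / 2
}

# implants: data frame with columns intensity, width_fraction, multimodality.
# One independent pair of band-matched noise realizations is generated per
# noise level (a shared realization merely rescaled would make the noise-level
# cells of a dataset near-duplicates).
pac_continuous_base <- function(phase_band, amp_band, duration_s,
                                fs_sim, beta, seed, implants,
                                rates = fs_sim, noise_scales = 1) {
  n <- round(duration_s * fs_sim)
  fir_p <- design_fir_bandpass(phase_band, fs_sim)
  fir_a <- design_fir_bandpass(amp_band, fs_sim)
  fc <- phase_center_freq(phase_band)
  cycle_sim <- fs_sim / fc
  margin_sim <- max(fir_p$delay, fir_a$delay) + ceiling(cycle_sim)

  raw <- power_law_noise(n, fs_sim, beta, derive_seed(seed, 101))
  sig_p <- fir_filter_zero_phase(raw, fir_p)
  sig_a <- fir_filter_zero_phase(raw, fir_a)
  n_lev <- length(noise_scales)
  noise_p <- lapply(seq_len(n_lev), function(s) {
    fir_filter_zero_phase(
      power_law_noise(n, fs_sim, beta, derive_seed(seed, 102, s)), fir_p)
  })
  noise_a <- lapply(seq_len(n_lev), function(s) {
    fir_filter_zero_phase(
      power_law_noise(n, fs_sim, beta, derive_seed(seed, 103, s)), fir_a)
  })

  interior <- (margin_sim + 1L):(n - margin_sim)
  centers <- list(
    monophasic = find_modulation_centers(sig_p, "monophasic", margin = margin_sim),
    biphasic   = find_modulation_centers(sig_p, "biphasic",   margin = margin_sim)
  )
  amp_variants <- lapply(seq_len(nrow(implants)), function(v) {
    iv <- implants$intensity[v]
    if (iv == 0) return(sig_a)
    implant_coupling(sig_a, centers[[implants$multimodality[v]]],
                     iv, implants$width_fraction[v], cycle_sim)
  })

  # RMS calibration on the interior of the generation-rate series; scale 1
  # means noise RMS equals the RMS of the series it is added to.
  r_sig_p <- rms(sig_p[interior])
  phase_noise_gain <- vapply(noise_p, function(x) r_sig_p / rms(x[interior]),
                             numeric(1))
  r_amp <- vapply(amp_variants, function(a) rms(a[interior]), numeric(1))
  amp_noise_gain <- vapply(noise_a, function(x) r_amp / rms(x[interior]),
                           numeric(length(r_amp)))
  amp_noise_gain <- matrix(amp_noise_gain, nrow = length(r_amp))

  by_rate <- lapply(rates, function(r) {
    q <- round(fs_sim / r)
    if (q == 1L) {
      margin <- margin_sim
      dn <- function(x) x
    } else {
      fir_d <- decimation_fir(fs_sim, r)
      margin <- ceiling((margin_sim + fir_d$delay) / q) + 1L
      dn <- function(x) resample_signal(x, fs_sim, r)
    }
    list(
      fs = r,
      margin = margin,
      cycle = r / fc,
      z_sig_p = hilbert_analytic(dn(sig_p)),
      z_noise_p = lapply(seq_len(n_lev), function(s) {
        hilbert_analytic(dn(noise_p[[s]])) * phase_noise_gain[s]
      }),
      z_amp = lapply(amp_variants, function(a) hilbert_analytic(dn(a))),
      z_noise_a = lapply(noise_a, function(x) hilbert_analytic(dn(x)))
    )
  })
  names(by_rate) <- as.character(rates)

  list(by_rate = by_rate, implants = implants,
       noise_scales = noise_scales,
       amp_noise_gain = amp_noise_gain,
       phase_band = phase_band, amp_band = amp_band,
       fs_sim = fs_sim, seed = seed, duration_s = duration_s)
}

noise_level_index <- function(base, noise_scale) {
  s <- match(noise_scale, base$noise_scales)
  if (is.na(s)) abort("noise level not present in this base simulation")
  s
}

# Instantaneous phase of the slow band for one (rate, noise) combination.
cell_phase <- function(base, rate, noise_scale) {
  br <- base$by_rate[[as.character(rate)]]
  s <- noise_level_index(base, noise_scale)
  wrap_phase(Arg(br$z_sig_p + noise_scale * br$z_noise_p[[s]]))
}

# Envelope of the fast band for one (rate, variant, noise) combination.
cell_amplitude <- function(base, rate, variant, noise_scale) {
  br <- base$by_rate[[as.character(rate)]]
  s <- noise_level_index(base, noise_scale)
  Mod(br$z_amp[[variant]] +
        noise_scale * base$amp_noise_gain[variant, s] * br$z_noise_a[[s]])
}

# Trial start indices within the continuous series: edge margins discarded,
# trials separated by at least one slow cycle (the data discontinuities),
# remaining slack spread randomly (default) or evenly.
segment_starts <- function(n_total, margin, trial_len, n_trials,
                           min_gap, placement = "random", seed = NULL) {
  avail <- n_total - 2L * margin
  need <- n_trials * trial_len + (n_trials - 1L) * min_gap
  slack <- avail - need
  if (slack < 0) abort("continuous record too short for the requested trials")
  parts <- if (placement == "random") {
    with_seed_or_current(seed,
      as.vector(rmultinom(1, slack, rep(1, n_trials + 1L))))
  } else {
    even <- slack %/% (n_trials + 1L)
    c(rep(even, n_trials), slack - n_trials * even)
  }
  starts <- margin + 1L + cumsum(c(parts[1L], parts[-1L][seq_len(n_trials - 1L)] +
                                     trial_len + min_gap))
  as.integer(starts)
}

# Column-major index matrix turning starts into concatenated trial samples.
trial_index <- function(starts, trial_len) {
  as.vector(outer(0:(trial_len - 1L), starts, "+"))
}
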