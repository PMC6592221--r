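#' Recipe for one synthetic coupling dataset
#'
#' Collects every parameter of the simulation pipeline into a validated
#' list.  Defaults reproduce the canonical study cell: theta (5-7 Hz) phase
#' modulating low gamma (33-47 Hz), 30 trials of 2500 ms cut from a
#' continuous record with an extra 30 s for discontinuities, simulated at
#' 1000 Hz with Brownian background noise at 100% of signal strength.
#'
#' @param pair frequency-pair preset, see [pac_frequency_pair()]; ignored
#'   when both `phase_band` and `amp_band` are given.
#' @param phase_band,amp_band explicit bands ([band_spec()]).
#' @param intensity modulation factor `I` (`0` = no coupling, `1` doubles
#'   the envelope at the window center).
#' @param width_fraction modulation window length as a fraction of one slow
#'   cycle (the cycle of the band's center frequency).
#' @param multimodality `"monophasic"` (peaks) or `"biphasic"` (peaks and
#'   troughs).
#' @param fs target sampling rate in Hz; must divide `fs_sim`.
#' @param fs_sim generation rate in Hz (resampling to `fs` is the last
#'   modification before phase/amplitude extraction).
#' @param n_trials number of trials to cut.
#' @param trial_length_ms trial length in milliseconds.
#' @param total_duration_s continuous record length; default
#'   `n_trials * trial_length_ms / 1000 + 30` seconds.
#' @param noise_scale band-matched noise strength relative to signal RMS.
#' @param beta spectral exponent of the background noise.
#' @param trial_placement `"random"` onsets (default) or `"regular"`
#'   spacing; either way trials are separated by at least one slow cycle to
#'   create data discontinuities.
#' @param seed master seed for the dataset; all internal draws (noise
#'   realizations, trial placement) are derived from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(trial_length_ms = 1000, n_trials = 10, seed = 1)
#' cfg$amp_band
#' @export
sim_config <- function(pair = "theta_low_gamma",
                       phase_band = NULL, amp_band = NULL,
                       intensity = 0, width_fraction = 0.25,
                       multimodality = c("monophasic", "biphasic"),
                       fs = 1000, fs_sim = 1000,
                       n_trials = 30, trial_length_ms = 2500,
                       total_duration_s = NULL,
                       noise_scale = 1, beta = 2,
                       trial_placement = c("random", "regular"),
                       seed = NULL) {
  multimodality <- match.arg(multimodality)
  trial_placement <- match.arg(trial_placement)
  if (is.null(phase_band) || is.null(amp_band)) {
    bands <- pac_frequency_pair(pair)
    phase_band <- phase_band %||% bands$phase_band
    amp_band <- amp_band %||% bands$amp_band
  } else {
    pair <- "custom"
  }
  phase_band <- as_band(phase_band)
  amp_band <- as_band(amp_band)
  assert_scalar_number(intensity, "intensity", lower = 0)
  assert_scalar_number(width_fraction, "width_fraction",
                       lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_number(fs, "fs", lower = 1)
  assert_scalar_number(fs_sim, "fs_sim", lower = 1)
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  assert_scalar_number(trial_length_ms, "trial_length_ms", lower = 1)
  assert_scalar_number(noise_scale, "noise_scale", lower = 0)
  assert_scalar_number(beta, "beta", lower = 0)
  if (fs > fs_sim) abort("`fs` cannot exceed `fs_sim`")
  q <- fs_sim / fs
  if (abs(q - round(q)) > 1e-9) abort("`fs` must divide `fs_sim`")
  if (amp_band[["high_hz"]] >= fs / 2) {
    abort("amplitude band reaches the Nyquist frequency of the target rate")
  }
  if (phase_band[["high_hz"]] >= amp_band[["low_hz"]]) {
    abort("phase and amplitude bands overlap")
  }
  total_duration_s <- total_duration_s %||%
    (n_trials * trial_length_ms / 1000 + 30)
  need_s <- n_trials * trial_length_ms / 1000
  if (total_duration_s < need_s + 2) {
    abort("`total_duration_s` too short for the requested trials plus edge margins")
  }
  structure(
    list(pair = pair, phase_band = phase_band, amp_band = amp_band,
         intensity = intensity, width_fraction = width_fraction,
         multimodality = multimodality, fs = fs, fs_sim = fs_sim,
         n_trials = as.integer(n_trials),
         trial_length_ms = trial_length_ms,
         total_duration_s = total_duration_s,
         noise_scale = noise_scale, beta = beta,
         trial_placement = trial_placement,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config: phase %g-%g Hz, amplitude %g-%g Hz, I=%g, ",
           "width=%g, %s,\n  %d x %g ms trials @ %g Hz (simulated at %g Hz), ",
           "noise %g%%, seed %s>\n"),
    x$phase_band[["low_hz"]], x$phase_band[["high_hz"]],
    x$amp_band[["low_hz"]], x$amp_band[["high_hz"]],
    x$intensity, x$width_fraction, x$multimodality,
    x$n_trials, x$trial_length_ms, x$fs, x$fs_sim,
    100 * x$noise_scale, x$seed %||% "<none>"))
  invisible(x)
}
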