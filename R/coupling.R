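#' Locate modulation centers on the slow band-passed signal
#'
#' Coupling is implanted at the relative maxima (monophasic) or at maxima and
#' minima (biphasic) of the band-passed phase-providing signal; these
#' correspond to instantaneous phases of 0 and +/-180 degrees.  Extrema are
#' detected by sign changes of the first difference; a plateau contributes
#' its first sample.  Centers closer than `margin` samples to either end are
#' dropped, so a modulation window never reaches outside the series.
#'
#' @param x band-passed slow signal.
#' @param multimodality `"monophasic"` (peaks only) or `"biphasic"` (peaks
#'   and troughs).
#' @param margin minimum distance (samples) from the signal edges.
#' @return Integer vector of sample indices (sorted).
#' @export
find_modulation_centers <- function(x,
                                    multimodality = c("monophasic", "biphasic"),
                                    margin = 0L) {
  multimodality <- match.arg(multimodality)
  n <- length(x)
  if (n < 3) abort("signal too short for extremum detection")
  d <- diff(x)
  s_full <- sign(d)
  # carry the last nonzero slope across plateaus (last-observation forward
  # fill) so each plateau yields one sign change at its first sample
  nz <- which(s_full != 0)
  if (length(nz) == 0) abort("no extrema found (constant signal)")
  pos <- findInterval(seq_along(s_full), nz)
  s_full <- c(0, s_full[nz])[pos + 1L]
  flips <- diff(s_full)
  peaks <- which(flips < 0) + 1L
  troughs <- which(flips > 0) + 1L
  centers <- if (multimodality == "monophasic") peaks else sort(c(peaks, troughs))
  centers <- centers[centers > margin & centers <= n - margin]
  if (length(centers) == 0) abort("no extrema found away from the edges")
  centers
}

# Hanning window of odd length L with endpoints exactly 0 and peak exactly 1.
hann_window <- function(L) {
  stopifnot(L >= 3, L %% 2 == 1)
  0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
}

#' Implant phase-amplitude coupling into the fast band-passed signal
#'
#' Multiplies the amplitude-providing signal by `1 + I * hann` in a window
#' centered on each modulation center: the gain is exactly `1 + I` at the
#' window center (`I = 1` doubles the amplitude there), exactly 1 at the
#' window edges and outside all windows, and `I = 0` leaves the signal
#' bit-identical.  The window length is `round(width_fraction *
#' cycle_samples)` forced odd; at the widths studied here (<= 27.5% of a
#' cycle) adjacent windows never overlap, and if they ever do the gains
#' multiply.
#'
#' @param x band-passed fast signal.
#' @param centers sample indices from [find_modulation_centers()].
#' @param intensity modulation factor `I >= 0`.
#' @param width_fraction window length as a fraction of one slow cycle,
#'   in (0, 1).
#' @param cycle_samples samples per slow-frequency cycle (`fs / f_center`).
#' @return Modulated numeric vector, same length as `x`.
#' @export
implant_coupling <- function(x, centers, intensity, width_fraction, cycle_samples) {
  assert_scalar_number(intensity, "intensity", lower = 0)
  assert_scalar_number(width_fraction, "width_fraction",
                       lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_number(cycle_samples, "cycle_samples", lower = 3)
  if (intensity == 0) return(x)
  L <- round(width_fraction * cycle_samples)
  if (L %% 2 == 0) L <- L + 1L
  if (L < 3) L <- 3L
  if (L > length(x)) abort("modulation window longer than the signal")
  half <- (L - 1L) %/% 2L
  if (any(centers <= half | centers > length(x) - half)) {
    abort("a modulation window would reach outside the signal; drop edge centers first")
  }
  gain_win <- 1 + intensity * hann_window(L)
  gain <- rep(1, length(x))
  offs <- seq(-half, half)
  for (ct in centers) {
    idx <- ct + offs
    gain[idx] <- gain[idx] * gain_win
  }
  x * gain
}

#' Add band-matched power-law noise
#'
#' Simulates an independent Brownian-noise series, band-pass filters it with
#' the same design as the signal's band, scales it so that its RMS equals
#' `noise_scale` times the RMS of `x` (the "signal strength" calibration:
#' 0.9/1.0/1.1 correspond to 90/100/110% noise), and adds it.
#'
#' @param x band-passed (possibly modulated) signal.
#' @param band the band to match ([band_spec()] or length-2 numeric).
#' @param fs sampling rate in Hz.
#' @param noise_scale noise strength relative to the signal RMS, `>= 0`.
#' @param seed optional integer seed for the noise realization.
#' @param beta spectral exponent of the raw noise (Brownian by default).
#' @param fir optional precomputed `pac_fir` for the band.
#' @return `x` plus calibrated band-limited noise.
#' @export
add_band_matched_noise <- function(x, band, fs, noise_scale, seed = NULL,
                                   beta = 2, fir = NULL) {
  assert_scalar_number(noise_scale, "noise_scale", lower = 0)
  if (noise_scale == 0) return(x)
  fir <- fir %||% design_fir_bandpass(band, fs)
  noise <- power_law_noise(length(x), fs, beta = beta, seed = seed)
  noise <- fir_filter_zero_phase(noise, fir)
  # calibrate on the interior: the filter warm-up tapers both series near the
  # edges, which are discarded before trials are cut anyway
  keep <- (fir$delay + 1L):(length(x) - fir$delay)
  x + noise * (noise_scale * rms(x[keep]) / rms(noise[keep]))
}
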