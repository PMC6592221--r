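#' Define a frequency band
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return A `pac_band` object (named numeric vector with elements `low_hz`
#'   and `high_hz`).
#' @examples
#' band_spec(5, 7)
#' @export
band_spec <- function(low_hz, high_hz) {
  assert_scalar_number(low_hz, "low_hz", lower = .Machine$double.eps)
  assert_scalar_number(high_hz, "high_hz")
  if (high_hz <= low_hz) abort("`high_hz` must exceed `low_hz`")
  structure(c(low_hz = low_hz, high_hz = high_hz), class = "pac_band")
}

#' @export
print.pac_band <- function(x, ...) {
  cat(sprintf("<band %g-%g Hz>\n", x[["low_hz"]], x[["high_hz"]]))
  invisible(x)
}

as_band <- function(x) {
  if (inherits(x, "pac_band")) return(x)
  if (is.numeric(x) && length(x) == 2) return(band_spec(x[[1]], x[[2]]))
  abort("expected a band: band_spec(low, high) or a length-2 numeric")
}

#' Amplitude-band edges matched to the modulating band
#'
#' The band extracting the fast (amplitude-providing) oscillation must be
#' wide enough to contain the modulation sidebands, i.e. the center frequency
#' of the fast band plus/minus the upper edge of the slow (phase-providing)
#' band.  This returns that band.
#'
#' @param phase_band slow band, e.g. `band_spec(5, 7)`.
#' @param amp_center center frequency of the fast band in Hz.
#' @return A `pac_band`:
#'   `[amp_center - phase_band$high_hz, amp_center + phase_band$high_hz]`.
#' @examples
#' amplitude_band_limits(band_spec(5, 7), 40)   # 33-47 Hz
#' amplitude_band_limits(band_spec(8, 10), 60)  # 50-70 Hz
#' @export
amplitude_band_limits <- function(phase_band, amp_center) {
  phase_band <- as_band(phase_band)
  assert_scalar_number(amp_center, "amp_center", lower = .Machine$double.eps)
  half <- phase_band[["high_hz"]]
  if (amp_center - half <= half) {
    abort("`amp_center` too low: amplitude band would reach into the phase band")
  }
  band_spec(amp_center - half, amp_center + half)
}

#' Standard frequency-pair presets
#'
#' Two canonical coupling pairs: theta phase (5-7 Hz) modulating low gamma
#' (33-47 Hz, i.e. 40 Hz center +/- 7 Hz), and alpha phase (8-10 Hz)
#' modulating high gamma (50-70 Hz, i.e. 60 Hz center +/- 10 Hz).
#'
#' @param pair `"theta_low_gamma"` or `"alpha_high_gamma"`.
#' @return A list with elements `phase_band` and `amp_band`.
#' @export
pac_frequency_pair <- function(pair = c("theta_low_gamma", "alpha_high_gamma")) {
  pair <- match.arg(pair)
  switch(pair,
    theta_low_gamma = list(
      phase_band = band_spec(5, 7),
      amp_band   = amplitude_band_limits(band_spec(5, 7), 40)
    ),
    alpha_high_gamma = list(
      phase_band = band_spec(8, 10),
      amp_band   = amplitude_band_limits(band_spec(8, 10), 60)
    )
  )
}
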