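#' Design a Hamming-windowed sinc FIR band-pass filter
#'
#' Linear-phase band-pass design following the automatic-order heuristic used
#' throughout EEG preprocessing: the transition bandwidth is
#' `min(max(0.25 * low_hz, 2), low_hz)` Hz and the filter order is
#' `ceiling(3.3 / (tbw / fs))`, rounded up to the next even number, so the
#' kernel has an odd number of taps and an integer group delay.  The kernel
#' is a difference of two windowed sincs, normalized to unit gain at the band
#' center.
#'
#' @param band a [band_spec()] (or length-2 numeric) within Nyquist.
#' @param fs sampling rate in Hz.
#' @return A list of class `pac_fir` with elements `taps` (odd-length
#'   symmetric kernel), `order`, `delay` (= order/2 samples), `band`, `fs`,
#'   and `transition_hz`.
#' @export
design_fir_bandpass <- function(band, fs) {
  band <- as_band(band)
  assert_scalar_number(fs, "fs", lower = .Machine$double.eps)
  f1 <- band[["low_hz"]]; f2 <- band[["high_hz"]]
  if (f2 >= fs / 2) abort("band edge at or above Nyquist (fs/2)")
  tbw <- min(max(0.25 * f1, 2), f1)
  ord <- ceiling(3.3 / (tbw / fs))
  if (ord %% 2 == 1) ord <- ord + 1
  m <- ord / 2
  k <- seq(-m, m)
  sinc_lp <- function(fc) {
    h <- sin(2 * pi * fc * k / fs) / (pi * k)
    h[k == 0] <- 2 * fc / fs
    h
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (k + m) / ord)
  h <- (sinc_lp(f2) - sinc_lp(f1)) * w
  fc <- (f1 + f2) / 2
  gain <- Mod(sum(h * exp(-2i * pi * fc * k / fs)))
  structure(
    list(taps = h / gain, order = ord, delay = m, band = band, fs = fs,
         transition_hz = tbw),
    class = "pac_fir"
  )
}

# Delay-compensated linear convolution with a symmetric FIR kernel, via FFT.
# Returns a series the same length as `x`; the first and last `delay` samples
# carry edge transients and are expected to be discarded by the caller.
fir_filter_zero_phase <- function(x, fir) {
  n <- length(x)
  taps <- fir$taps
  L <- length(taps)
  if (n <= L) abort("signal shorter than the filter kernel")
  nfft <- nextn(n + L - 1L)
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * fft(c(taps, numeric(nfft - L))),
              inverse = TRUE)) / nfft
  y[(fir$delay + 1L):(fir$delay + n)]
}

#' Zero-phase band-pass filtering
#'
#' Filters `x` with the symmetric FIR kernel from [design_fir_bandpass()],
#' compensating the group delay so the output has zero net phase shift.
#' Edge segments of half the filter order at each end contain transients;
#' downstream code discards them before any trial is cut.
#'
#' @param x numeric signal.
#' @param band pass band ([band_spec()] or length-2 numeric).
#' @param fs sampling rate in Hz.
#' @param fir optionally a precomputed `pac_fir` (then `band`/`fs` are ignored).
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, band, fs, fir = NULL) {
  fir <- fir %||% design_fir_bandpass(band, fs)
  fir_filter_zero_phase(x, fir)
}

#' Analytic signal via the Hilbert transform
#'
#' Extends a band-limited real signal to its complex analytic signal (FFT
#' method: negative frequencies zeroed, positive doubled).  The modulus is
#' the instantaneous amplitude envelope and the argument the instantaneous
#' phase, returned in \eqn{(-\pi, \pi]} with the cosine convention (a cosine
#' has phase 0 at its maxima).
#'
#' @param x real, band-limited numeric signal.
#' @param fs sampling rate in Hz (stored as an attribute).
#' @return A tibble with columns `phase` and `amplitude`, one row per sample,
#'   with attribute `fs`.
#' @export
analytic_signal <- function(x, fs = NA_real_) {
  z <- hilbert_analytic(x)
  out <- tibble::tibble(phase = wrap_phase(Arg(z)), amplitude = Mod(z))
  attr(out, "fs") <- fs
  out
}

# Complex analytic signal of a real vector (single transform).
hilbert_analytic <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  X <- fft(x)
  X <- X * analytic_mask(n)
  fft(X, inverse = TRUE) / n
}

# Spectral mask that maps a spectrum onto its analytic-signal spectrum.
analytic_mask <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Hilbert transforms of two real vectors with a single FFT/IFFT pair.
# Pack a1 + i*a2, apply the analytic mask to the packed spectrum (the mask is
# the same linear operator for both components), and invert:
#   ifft(mask * fft(a1 + i a2)) = z1 + i z2  with  z_j = a_j + i H{a_j},
# so H{a1} = Im(w) - a2 and H{a2} = a1 - Re(w).  Exact, not an approximation.
hilbert_pair <- function(a1, a2) {
  n <- length(a1)
  stopifnot(length(a2) == n)
  w <- fft(analytic_mask(n) * fft(complex(real = a1, imaginary = a2)),
           inverse = TRUE) / n
  list(h1 = Im(w) - a2, h2 = a1 - Re(w))
}

#' Resample a signal to a lower rate
#'
#' Integer-factor decimation with an anti-aliasing zero-phase FIR low-pass
#' (windowed sinc, cutoff at 80% of the new Nyquist frequency).  Duration is
#' preserved to within one sample.
#'
#' @param x numeric signal.
#' @param fs_from,fs_to old and new sampling rates; `fs_from / fs_to` must be
#'   a whole number.
#' @param max_band_hz optional highest band edge still in use downstream; the
#'   call is rejected if `fs_to <= 2 * max_band_hz` (Nyquist violation).
#' @return Numeric vector of length `ceiling(length(x) * fs_to / fs_from)`.
#' @export
resample_signal <- function(x, fs_from, fs_to, max_band_hz = NULL) {
  assert_scalar_number(fs_from, "fs_from", lower = .Machine$double.eps)
  assert_scalar_number(fs_to, "fs_to", lower = .Machine$double.eps)
  if (fs_to >= fs_from) abort("`fs_to` must be below `fs_from`")
  if (!is.null(max_band_hz) && fs_to <= 2 * max_band_hz) {
    abort("`fs_to` violates Nyquist for the highest band in use")
  }
  q <- fs_from / fs_to
  if (abs(q - round(q)) > 1e-9) abort("only integer decimation factors are supported")
  q <- as.integer(round(q))
  fir <- decimation_fir(fs_from, fs_to)
  y <- fir_filter_zero_phase(x, fir)
  y[seq(1L, length(y), by = q)]
}

decimation_fir <- function(fs_from, fs_to) {
  cutoff <- 0.8 * fs_to / 2
  tbw <- 0.2 * fs_to
  ord <- ceiling(3.3 / (tbw / fs_from))
  if (ord %% 2 == 1) ord <- ord + 1
  m <- ord / 2
  k <- seq(-m, m)
  h <- sin(2 * pi * cutoff * k / fs_from) / (pi * k)
  h[k == 0] <- 2 * cutoff / fs_from
  h <- h * (0.54 - 0.46 * cos(2 * pi * (k + m) / ord))
  structure(
    list(taps = h / sum(h), order = ord, delay = m,
         band = NULL, fs = fs_from, transition_hz = tbw),
    class = "pac_fir"
  )
}
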