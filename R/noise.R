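#' Generate power-law (\eqn{1/f^\beta}) noise
#'
#' Synthesizes noise whose power spectrum follows \eqn{P(f) \propto 1/f^\beta}
#' by frequency-domain shaping: a white complex Gaussian spectrum is scaled by
#' \eqn{f^{-\beta/2}}, made Hermitian-symmetric, and inverse transformed.
#' \eqn{\beta = 0} gives white noise, \eqn{\beta = 1} pink noise and
#' \eqn{\beta = 2} Brownian (red) noise, the regime that approximates the
#' background dynamics of human EEG.  The DC coefficient is set to zero, so
#' the output is exactly zero-mean; the series is normalized to unit standard
#' deviation.
#'
#' @param n_samples number of samples (must be at least `2 * fs` so that the
#'   spectral slope is identifiable down to 1 Hz).
#' @param fs sampling rate in Hz.
#' @param beta spectral exponent, `>= 0`.
#' @param seed optional integer seed; the same seed reproduces the same
#'   series exactly.
#' @return Numeric vector of length `n_samples`.
#' @seealso [spectral_slope()] to recover \eqn{-\beta} from a realization.
#' @examples
#' x <- power_law_noise(4000, fs = 1000, beta = 2, seed = 1)
#' spectral_slope(x, fs = 1000)
#' @export
power_law_noise <- function(n_samples, fs, beta = 2, seed = NULL) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(fs, "fs", lower = .Machine$double.eps)
  assert_scalar_number(beta, "beta", lower = 0)
  n <- as.integer(n_samples)
  if (n < 2 * fs) {
    abort("`n_samples` must be at least 2 * fs (too short for spectral slope control)")
  }
  with_seed_or_current(seed, {
    n_pos <- (n - 1L) %/% 2L           # strictly positive, non-Nyquist bins
    f_pos <- (1:n_pos) * fs / n
    amp <- f_pos^(-beta / 2)
    z_pos <- complex(
      real = rnorm(n_pos), imaginary = rnorm(n_pos)
    ) * amp / sqrt(2)
    spec <- complex(real = numeric(n), imaginary = numeric(n))
    spec[2:(n_pos + 1L)] <- z_pos
    spec[n:(n - n_pos + 1L)] <- Conj(z_pos)
    if (n %% 2L == 0L) {               # real Nyquist bin
      f_nyq <- fs / 2
      spec[n %/% 2L + 1L] <- rnorm(1) * f_nyq^(-beta / 2)
    }
    x <- Re(fft(spec, inverse = TRUE)) / n
    x / sd(x)
  })
}

#' Fit the spectral slope of a signal on log-log axes
#'
#' Estimates the log-log slope of the periodogram between `f_min` and `f_max`
#' (default 1 Hz to `fs/4`) by least squares.  For noise generated with
#' exponent \eqn{\beta} the expected slope is \eqn{-\beta}.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param f_min,f_max frequency range of the fit, in Hz.
#' @return The fitted slope (a single number).
#' @export
spectral_slope <- function(x, fs, f_min = 1, f_max = fs / 4) {
  n <- length(x)
  stopifnot(n >= 4)
  pw <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_min & f <= f_max
  if (sum(keep) < 8) abort("too few periodogram bins in [f_min, f_max]")
  unname(coef(lm(log(pw[keep]) ~ log(f[keep])))[2])
}
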