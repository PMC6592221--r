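#' @title Raw phase-amplitude coupling statistics
#'
#' @description
#' Each estimator consumes per-sample instantaneous phase \eqn{\theta_t} of
#' the slow band and amplitude envelope \eqn{a_t} of the fast band (trials
#' concatenated at the sample level) and returns a one-row tibble with the
#' raw, un-standardized coupling value:
#'
#' * `pac_plv()` — phase-locking value: the envelope is Hilbert-transformed a
#'   second time, its instantaneous phase \eqn{\theta_{ut}} extracted, and
#'   the mean resultant length of \eqn{\theta_{lt} - \theta_{ut}} computed;
#'   in `[0, 1]`.
#' * `pac_mvl()` — mean vector length \eqn{|\sum_t a_t e^{i\theta_t}/n|};
#'   non-negative, scales linearly with the envelope.
#' * `pac_mvl_direct()` — amplitude-normalized variant
#'   \eqn{|\sum_t a_t e^{i\theta_t}| / \sqrt{n \sum_t a_t^2}}; in `[0, 1]`
#'   and invariant to amplitude scaling.
#' * `pac_mi()` — modulation index: mean envelope per phase bin, normalized
#'   to a distribution `p(j)`, scored by the Kullback-Leibler distance from
#'   uniform via Shannon entropy (natural log) and normalized by `log(n_bins)`;
#'   in `[0, 1]`.
#' * `pac_glm()` — gamma/log-link GLM of the envelope on a periodic cubic
#'   B-spline basis of phase; the statistic is the maximum absolute deviation
#'   of the spline-modelled envelope from the intercept-only (null) envelope,
#'   as a proportion of the null envelope; non-negative.
#'
#' @param trials a `pac_trials` object from [simulate_pac()], or any data
#'   frame with numeric columns `phase` and `amplitude`.
#' @param envelope_prefilter optional [band_spec()]: band-pass the envelope
#'   in the slow band (requires the `fs` attribute) before the second Hilbert
#'   transform, the classical counter-measure when the envelope is not a
#'   narrow-band oscillation.  Off by default.
#' @param n_bins number of phase bins for the modulation index (18 bins of
#'   20 degrees by default).
#' @param n_control_points number of control points (periodic spline basis
#'   functions), evenly spaced over \eqn{(-\pi, \pi]}.
#' @param select_by_aic scan 4..12 control points and keep the count with
#'   the lowest Akaike information criterion.  Off by default: the scan
#'   multiplies the (already dominant) GLM fitting cost.
#' @return A one-row tibble with columns `method`, `value` and (PLV/MVL
#'   only) `preferred_phase` in radians.  Under biphasic coupling the
#'   preferred phase is meaningless and should not be interpreted.
#' @name pac_estimators
#' @examples
#' trials <- simulate_pac(sim_config(trial_length_ms = 1000, n_trials = 8,
#'                                   seed = 7))
#' pac_mi(trials)
#' pac_mvl(trials)
NULL

extract_phase_amp <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("phase", "amplitude") %in% names(trials))) {
    abort("`trials` must be a data frame with `phase` and `amplitude` columns")
  }
  list(
    phase = as.numeric(trials$phase),
    amplitude = as.numeric(trials$amplitude),
    fs = attr(trials, "fs", exact = TRUE) %||% NA_real_
  )
}

#' @rdname pac_estimators
#' @export
pac_plv <- function(trials, envelope_prefilter = NULL) {
  d <- extract_phase_amp(trials)
  if (length(d$phase) < 2) abort("need at least 2 samples")
  if (sd(d$amplitude) == 0) {
    abort("constant amplitude envelope: the second Hilbert phase is undefined")
  }
  env <- d$amplitude
  if (!is.null(envelope_prefilter)) {
    if (!is.finite(d$fs)) abort("envelope pre-filtering needs an `fs` attribute")
    env <- bandpass_zero_phase(env, envelope_prefilter, d$fs)
  }
  theta_u <- Arg(hilbert_analytic(env))
  v <- mean(exp(1i * (d$phase - theta_u)))
  tibble::tibble(method = "plv", value = Mod(v), preferred_phase = Arg(v))
}

#' @rdname pac_estimators
#' @export
pac_mvl <- function(trials) {
  d <- extract_phase_amp(trials)
  if (length(d$phase) < 2) abort("need at least 2 samples")
  v <- mean(d$amplitude * exp(1i * d$phase))
  tibble::tibble(method = "mvl", value = Mod(v), preferred_phase = Arg(v))
}

#' @rdname pac_estimators
#' @export
pac_mvl_direct <- function(trials) {
  d <- extract_phase_amp(trials)
  n <- length(d$phase)
  if (n < 2) abort("need at least 2 samples")
  ss <- sum(d$amplitude^2)
  if (ss <= 0) abort("all-zero amplitude envelope")
  v <- sum(d$amplitude * exp(1i * d$phase))
  tibble::tibble(method = "direct_mvl", value = Mod(v) / sqrt(n * ss),
                 preferred_phase = Arg(v))
}

# Half-open phase bins [edge, next_edge) over (-pi, pi]; a sample at exactly
# +pi wraps into the last bin.
mi_bin_index <- function(phase, n_bins) {
  j <- floor((phase + pi) / (2 * pi / n_bins)) + 1L
  j[j > n_bins] <- n_bins
  as.integer(j)
}

#' Phase-binned mean-amplitude distribution
#'
#' The histogram underlying the modulation index: mean envelope per phase
#' bin, plus the normalized distribution `p` (which sums to one).
#'
#' @inheritParams pac_estimators
#' @return A tibble with one row per bin: `bin`, `bin_center_deg`,
#'   `bin_center_rad`, `n`, `mean_amplitude`, `p`.
#' @export
phase_amplitude_histogram <- function(trials, n_bins = 18) {
  d <- extract_phase_amp(trials)
  if (n_bins < 2) abort("`n_bins` must be at least 2")
  bins <- mi_bin_index(d$phase, n_bins)
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0)) {
    abort(sprintf(
      "empty phase bin(s) %s: too few samples for %d bins",
      paste(which(counts == 0), collapse = ", "), n_bins))
  }
  sums <- as.numeric(rowsum(d$amplitude, bins))
  abar <- sums / counts
  width <- 360 / n_bins
  centers_deg <- -180 + width * (seq_len(n_bins) - 0.5)
  tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_deg = centers_deg,
    bin_center_rad = centers_deg * pi / 180,
    n = counts,
    mean_amplitude = abar,
    p = abar / sum(abar)
  )
}

# Modulation index from a normalized phase-amplitude distribution.
# 0 * log(0) is taken as 0 (a bin whose mean amplitude is zero carries no
# entropy mass).
mi_from_p <- function(p, n_bins) {
  lp <- ifelse(p > 0, log(p), 0)
  h <- -sum(p * lp)
  (log(n_bins) - h) / log(n_bins)
}

#' @rdname pac_estimators
#' @export
pac_mi <- function(trials, n_bins = 18) {
  hist <- phase_amplitude_histogram(trials, n_bins)
  tibble::tibble(method = "mi", value = mi_from_p(hist$p, n_bins),
                 preferred_phase = NA_real_)
}

#' @rdname pac_estimators
#' @export
pac_glm <- function(trials, n_control_points = 10, select_by_aic = FALSE) {
  d <- extract_phase_amp(trials)
  if (any(d$amplitude <= 0)) abort("amplitudes must be strictly positive for the gamma GLM")
  if (length(d$phase) < 10 * n_control_points) {
    abort("need at least 10 samples per control point")
  }
  fit <- glm_cfc_fit(d$phase, d$amplitude,
                     n_control_points = n_control_points,
                     select_by_aic = select_by_aic)
  out <- tibble::tibble(method = "glm_cfc", value = fit$statistic,
                        preferred_phase = NA_real_)
  attr(out, "n_control_points") <- fit$n_control_points
  out
}
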