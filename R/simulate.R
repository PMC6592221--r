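#' Simulate a trial set with implanted phase-amplitude coupling
#'
#' Runs the full generative pipeline for one dataset: Brownian background
#' noise is band-pass filtered into a slow (phase-providing) and a fast
#' (amplitude-providing) component; coupling is implanted by multiplying the
#' fast component with `1 + I * hann` windows locked to the peaks (or peaks
#' and troughs) of the slow component; independent band-matched noise is
#' added to both components at `noise_scale` times their RMS; the series are
#' resampled to the target rate if it is below the generation rate; phase
#' and envelope are extracted by Hilbert transform of the continuous series;
#' and finally `n_trials` non-contiguous trials are cut, discarding the
#' filter edge regions and separating trials by at least one slow cycle.
#'
#' @param config a [sim_config()].
#' @return A `pac_trials` tibble with columns `trial`, `time_s` (source time
#'   of each sample in the continuous record), `phase` (radians, slow band)
#'   and `amplitude` (envelope, fast band), and attributes `fs`,
#'   `trial_length` (samples), `n_trials` and `config`.
#' @examples
#' trials <- simulate_pac(sim_config(intensity = 1, trial_length_ms = 1000,
#'                                   n_trials = 8, seed = 42))
#' trials
#' @export
simulate_pac <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed %||% derive_seed(sample.int(2^30, 1))
  implants <- data.frame(intensity = config$intensity,
                         width_fraction = config$width_fraction,
                         multimodality = config$multimodality)
  base <- pac_continuous_base(
    config$phase_band, config$amp_band, config$total_duration_s,
    config$fs_sim, config$beta, seed, implants, rates = config$fs,
    noise_scales = config$noise_scale)
  br <- base$by_rate[[as.character(config$fs)]]
  theta <- cell_phase(base, config$fs, config$noise_scale)
  amp <- cell_amplitude(base, config$fs, 1L, config$noise_scale)

  trial_len <- as.integer(round(config$trial_length_ms * config$fs / 1000))
  starts <- segment_starts(
    n_total = length(theta), margin = br$margin, trial_len = trial_len,
    n_trials = config$n_trials, min_gap = ceiling(br$cycle),
    placement = config$trial_placement, seed = derive_seed(seed, 201))
  idx <- trial_index(starts, trial_len)
  new_pac_trials(
    phase = theta[idx], amplitude = amp[idx],
    trial = rep(seq_len(config$n_trials), each = trial_len),
    time_s = (idx - 1) / config$fs,
    fs = config$fs, config = config)
}

new_pac_trials <- function(phase, amplitude, trial, time_s, fs, config = NULL,
                           provenance = "simulated") {
  out <- tibble::tibble(trial = as.integer(trial), time_s = time_s,
                        phase = phase, amplitude = amplitude)
  class(out) <- c("pac_trials", class(out))
  attr(out, "fs") <- fs
  attr(out, "trial_length") <- sum(trial == trial[1])
  attr(out, "n_trials") <- length(unique(trial))
  attr(out, "config") <- config
  attr(out, "provenance") <- provenance
  out
}

#' Coerce a data frame to a trial set
#'
#' @param x data frame with columns `phase`, `amplitude` and optionally
#'   `trial` (defaults to a single trial) and `time_s`.
#' @param fs sampling rate in Hz.
#' @return A `pac_trials` tibble.
#' @export
as_pac_trials <- function(x, fs = NA_real_) {
  if (inherits(x, "pac_trials")) return(x)
  if (!all(c("phase", "amplitude") %in% names(x))) {
    abort("`x` needs `phase` and `amplitude` columns")
  }
  trial <- x$trial %||% rep(1L, nrow(x))
  lens <- table(trial)
  if (length(unique(as.integer(lens))) != 1L) {
    abort("all trials must have the same length")
  }
  new_pac_trials(x$phase, x$amplitude, trial,
                 x$time_s %||% seq_len(nrow(x)) / fs,
                 fs = fs, provenance = "external")
}

#' @export
print.pac_trials <- function(x, ...) {
  cat(sprintf("<pac_trials: %d trials x %d samples @ %s Hz (%s)>\n",
              attr(x, "n_trials"), attr(x, "trial_length"),
              format(attr(x, "fs")), attr(x, "provenance") %||% "unknown"))
  NextMethod()
}

trial_geometry <- function(trials) {
  tl <- attr(trials, "trial_length", exact = TRUE)
  nt <- attr(trials, "n_trials", exact = TRUE)
  if (!is.null(tl) && !is.null(nt) && tl * nt != nrow(trials)) {
    tl <- NULL  # stale attributes (e.g. after subsetting); recompute
  }
  if (is.null(tl) || is.null(nt)) {
    trial <- trials$trial %||% rep(1L, nrow(trials))
    lens <- as.integer(table(trial))
    if (length(unique(lens)) != 1L) abort("trials differ in length")
    tl <- lens[1]
    nt <- length(lens)
  }
  list(trial_len = as.integer(tl), n_trials = as.integer(nt))
}
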