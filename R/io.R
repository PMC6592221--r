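#' Write / read a signal as raw float64 with a JSON sidecar
#'
#' Continuous signals are serialized as little-endian IEEE float64 arrays
#' (`<path>.bin`) with a JSON sidecar (`<path>.json`) holding the sampling
#' rate, optional band edges, seed and a content fingerprint, so datasets
#' can be exchanged with any numerical environment.
#'
#' @param x numeric signal.
#' @param path base path (without extension).
#' @param fs sampling rate in Hz.
#' @param band optional [band_spec()] the signal was filtered to.
#' @param seed optional seed recorded in the sidecar.
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, fs, band = NULL, seed = NULL, extra = list()) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  meta <- c(list(
    n_samples = length(x), fs = fs,
    band = if (!is.null(band)) as.numeric(as_band(band)),
    seed = seed,
    fingerprint = signal_fingerprint(x),
    toolkit = as.character(packageVersion("pacbench"))
  ), extra)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @return `read_signal()`: a list with `x` (numeric vector) and `meta`
#'   (sidecar contents).
#' @export
read_signal <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_samples, size = 8, endian = "little")
  if (!identical(signal_fingerprint(x), meta$fingerprint)) {
    warning("signal fingerprint mismatch: file may be corrupted", call. = FALSE)
  }
  list(x = x, meta = meta)
}

# FNV-1a over the hex representation of the first/last samples and moments;
# cheap content check, not cryptographic.
signal_fingerprint <- function(x) {
  s <- paste(format(c(length(x), head(x, 3), tail(x, 3), mean(x), sd(x)),
                    digits = 15), collapse = ",")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double to stay
    # clear of R's 32-bit integer range
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  # h is a double (can exceed .Machine$integer.max); format halves separately
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load a simulation or study configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] argument names exactly (for a
#' single dataset) or the [run_specificity()]/[run_sensitivity()] grid
#' arguments (for a study; marked by `study: specificity` or
#' `study: sensitivity`).  Unknown keys are rejected with the offending name.
#'
#' @param path YAML file.
#' @return A `sim_config`, or a list of study arguments with class
#'   `pac_study_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("config file must contain a YAML mapping")
  if (!is.null(raw$study)) {
    study <- match.arg(raw$study, c("specificity", "sensitivity"))
    raw$study <- NULL
    allowed <- setdiff(names(formals(
      if (study == "specificity") run_specificity else run_sensitivity)),
      "progress")
    bad <- setdiff(names(raw), allowed)
    if (length(bad) > 0) {
      abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    structure(c(list(study = study), raw), class = "pac_study_config")
  } else {
    allowed <- names(formals(sim_config))
    bad <- setdiff(names(raw), allowed)
    if (length(bad) > 0) {
      abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    if (!is.null(raw$phase_band)) raw$phase_band <- as_band(unlist(raw$phase_band))
    if (!is.null(raw$amp_band)) raw$amp_band <- as_band(unlist(raw$amp_band))
    do.call(sim_config, raw)
  }
}

#' Write a configuration to YAML
#'
#' Round-trips with [load_config()]: every field of the configuration is
#' reproduced exactly.
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$phase_band <- as.numeric(out$phase_band)
  out$amp_band <- as.numeric(out$amp_band)
  out$pair <- NULL  # bands written explicitly
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

#' Generate small deterministic fixture datasets
#'
#' Writes a trial set to disk for testing and demonstrations: `"null"` (no
#' coupling), `"mono"` (monophasic, I = 1) or `"bi"` (biphasic, I = 1); the
#' `small` variant uses 10 trials of 1000 ms.
#'
#' @param kind `"null"`, `"mono"` or `"bi"`.
#' @param dir output directory.
#' @param small use the small geometry (default) or the full 30 x 2500 ms.
#' @param seed integer seed.
#' @param pair frequency-pair preset.
#' @return The `pac_trials` object, invisibly; files `<kind>_phase.bin/.json`,
#'   `<kind>_amplitude.bin/.json` and `<kind>_manifest.json` in `dir`.
#' @export
generate_fixture <- function(kind = c("null", "mono", "bi"), dir = ".",
                             small = TRUE, seed = 1,
                             pair = "theta_low_gamma") {
  kind <- match.arg(kind)
  cfg <- sim_config(
    pair = pair,
    intensity = if (kind == "null") 0 else 1,
    multimodality = if (kind == "bi") "biphasic" else "monophasic",
    n_trials = if (small) 10 else 30,
    trial_length_ms = if (small) 1000 else 2500,
    seed = seed)
  trials <- simulate_pac(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, kind)
  write_signal(trials$phase, paste0(base, "_phase"), fs = cfg$fs, seed = seed,
               extra = list(quantity = "phase_rad"))
  write_signal(trials$amplitude, paste0(base, "_amplitude"), fs = cfg$fs,
               seed = seed, extra = list(quantity = "amplitude"))
  manifest <- list(
    kind = kind, seed = seed, fs = cfg$fs,
    n_trials = cfg$n_trials, trial_length_ms = cfg$trial_length_ms,
    intensity = cfg$intensity, multimodality = cfg$multimodality,
    files = paste0(kind, c("_phase.bin", "_phase.json",
                           "_amplitude.bin", "_amplitude.json")),
    toolkit = as.character(packageVersion("pacbench")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(base, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(trials)
}

#' Export a tibble as an RFC 4180 CSV at fixed precision
#'
#' Numeric columns are written with 12 significant digits so re-runs from
#' the same manifest produce byte-identical tables.
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pac_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) signif(col, 12))
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a study run: master seed, grid,
#' toolkit version, timestamps and the output file inventory.
#'
#' @param params named list of run parameters (including `master_seed`).
#' @param files character vector of output files produced.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, files, path) {
  manifest <- list(
    params = params, files = files,
    toolkit = as.character(packageVersion("pacbench")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
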