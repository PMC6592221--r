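#' Factorial grids for the specificity and sensitivity studies
#'
#' Expands the moderator grid of the simulation studies into a tibble of
#' cells: data length x sampling rate x noise level, plus (sensitivity)
#' modulation strength x width x multimodality.
#'
#' @param intensity modulation strengths; `0` for the specificity (null)
#'   grid.
#' @param width_fraction modulation widths (fractions of one slow cycle).
#' @param multimodality `"monophasic"`, `"biphasic"` or both.
#' @param data_length_ms trial lengths in ms.
#' @param sampling_rate target rates in Hz.
#' @param noise_scale noise levels relative to signal strength.
#' @return A tibble with one row per cell and a `cell` id column.
#' @export
pac_grid <- function(intensity = c(0.9, 1.0, 1.1),
                     width_fraction = c(0.225, 0.25, 0.275),
                     multimodality = c("monophasic", "biphasic"),
                     data_length_ms = c(400, 2500, 5000),
                     sampling_rate = c(500, 1000),
                     noise_scale = c(0.9, 1.0, 1.1)) {
  g <- tidyr::expand_grid(
    intensity = intensity, width_fraction = width_fraction,
    multimodality = multimodality, data_length_ms = data_length_ms,
    sampling_rate = sampling_rate, noise_scale = noise_scale)
  g$cell <- seq_len(nrow(g))
  g
}

# Shared runner: simulates `n_sims` base datasets for one frequency pair and
# evaluates every grid cell of every base, reusing one noise realization per
# base across all cells (the within-dataset factorial modification).
run_pac_study <- function(pair, implants, methods, n_sims, n_perm,
                          glm_n_sims, glm_n_perm, glm_select_by_aic,
                          data_length_ms, sampling_rate, noise_scale,
                          n_trials, fs_sim, beta, n_bins,
                          trial_placement, master_seed, progress) {
  bands <- pac_frequency_pair(pair)
  duration <- max(data_length_ms) * n_trials / 1000 + 30
  base_methods <- setdiff(methods, "glm_cfc")
  with_glm <- "glm_cfc" %in% methods
  n_total <- max(n_sims * (length(base_methods) > 0), glm_n_sims * with_glm)
  stopifnot(n_total >= 1)

  rows <- vector("list", n_total)
  for (d in seq_len(n_total)) {
    base_seed <- derive_seed(master_seed, 11, d)
    base <- pac_continuous_base(
      bands$phase_band, bands$amp_band, duration, fs_sim, beta,
      base_seed, implants, rates = sampling_rate,
      noise_scales = noise_scale)
    drows <- list()
    for (r in sampling_rate) {
      br <- base$by_rate[[as.character(r)]]
      for (ns in noise_scale) {
        theta <- cell_phase(base, r, ns)
        for (v in seq_len(nrow(implants))) {
          amp <- cell_amplitude(base, r, v, ns)
          for (len_ms in data_length_ms) {
            cell_id <- cell_key(r, ns, v, len_ms)
            trial_len <- as.integer(round(len_ms * r / 1000))
            # trials for a length condition are drawn from a record of that
            # condition's own duration (n_trials x length + 30 s), not from
            # the whole longest record
            window <- round((n_trials * len_ms / 1000 + 30) * r)
            starts <- segment_starts(
              min(length(theta), window), br$margin, trial_len, n_trials,
              min_gap = ceiling(br$cycle), placement = trial_placement,
              seed = derive_seed(base_seed, 21, cell_id))
            idx <- trial_index(starts, trial_len)
            th <- theta[idx]; am <- amp[idx]
            res <- list()
            if (length(base_methods) > 0 && d <= n_sims) {
              res$base <- surrogate_stats(
                th, am, trial_len, n_trials, base_methods,
                n_perm = n_perm,
                seed = derive_seed(base_seed, 31, cell_id),
                n_bins = n_bins)$summary
            }
            if (with_glm && d <= glm_n_sims) {
              res$glm <- surrogate_stats(
                th, am, trial_len, n_trials, "glm_cfc",
                n_perm = glm_n_perm,
                seed = derive_seed(base_seed, 41, cell_id),
                glm_opts = list(n_control_points = 10,
                                select_by_aic = glm_select_by_aic))$summary
            }
            if (length(res) > 0) {
              out <- dplyr::bind_rows(res)
              out$dataset <- d
              out$intensity <- implants$intensity[v]
              out$width_fraction <- implants$width_fraction[v]
              out$multimodality <- implants$multimodality[v]
              out$data_length_ms <- len_ms
              out$sampling_rate <- r
              out$noise_scale <- ns
              drows[[length(drows) + 1L]] <- out
            }
          }
        }
      }
    }
    rows[[d]] <- dplyr::bind_rows(drows)
    if (progress && d %% 10 == 0) {
      message(sprintf("[%s] dataset %d/%d", pair, d, n_total))
    }
  }
  z <- dplyr::bind_rows(rows)
  z$pair <- pair
  dplyr::relocate(z, "pair", "dataset", "method")
}

cell_key <- function(rate, noise, variant, len_ms) {
  as.integer(rate) * 1000000L + as.integer(round(noise * 100)) * 1000L +
    as.integer(variant) * 10L + as.integer(len_ms %/% 400)
}

#' Run the specificity (null calibration) study
#'
#' Simulates `n_sims` no-coupling datasets (modulation strength `I = 0`),
#' modifies each across the data length x sampling rate x noise grid,
#' z-standardizes every coupling measure by within-trial permutation, and
#' calibrates the empirical critical z per method as the pooled
#' `(1 - alpha)` quantile of the null z distribution.  False positives at
#' that threshold are counted in consecutive subsamples of
#' `subsample_size` datasets per grid cell.
#'
#' Because the GLM measure is orders of magnitude slower than the others,
#' its replication is controlled separately (`glm_n_sims`, `glm_n_perm`);
#' by default it runs with the AIC control-point scan on the observed side,
#' mirroring the original procedure.
#'
#' @param pair `"theta_low_gamma"` or `"alpha_high_gamma"`.
#' @param methods coupling measures to evaluate.
#' @param n_sims number of base datasets (paper scale: 5000).
#' @param n_perm permutations per estimate (paper scale: 1000).
#' @param glm_n_sims,glm_n_perm replication for the GLM measure.
#' @param glm_select_by_aic AIC scan for the GLM control-point count
#'   (observed data only; surrogates refit at the selected count).
#' @param data_length_ms,sampling_rate,noise_scale the moderator grid.
#' @param n_trials trials per dataset.
#' @param fs_sim generation rate in Hz.
#' @param beta spectral exponent of the background noise.
#' @param n_bins phase bins for the modulation index.
#' @param alpha nominal false-positive rate for the calibration.
#' @param subsample_size datasets per false-positive subsample.
#' @param trial_placement `"random"` or `"regular"` trial onsets.
#' @param master_seed master seed; every draw is derived from it.
#' @param progress emit a message every 10 datasets.
#' @return A `pac_specificity` object: list with tibbles `z` (one row per
#'   dataset x cell x method), `critical` (per method), `fp` (false-positive
#'   counts per subsample and cell), and the call parameters.
#' @export
run_specificity <- function(pair = "theta_low_gamma",
                            methods = c("plv", "mvl", "mi", "glm_cfc"),
                            n_sims = 5000, n_perm = 1000,
                            glm_n_sims = n_sims, glm_n_perm = n_perm,
                            glm_select_by_aic = TRUE,
                            data_length_ms = c(400, 2500, 5000),
                            sampling_rate = c(500, 1000),
                            noise_scale = c(0.9, 1.0, 1.1),
                            n_trials = 30, fs_sim = 1000, beta = 2,
                            n_bins = 18, alpha = 0.05, subsample_size = 50,
                            trial_placement = "random",
                            master_seed = 1, progress = FALSE) {
  methods <- match.arg(methods, pac_methods, several.ok = TRUE)
  implants <- data.frame(intensity = 0, width_fraction = 0.25,
                         multimodality = "monophasic")
  z <- run_pac_study(pair, implants, methods, n_sims, n_perm,
                     glm_n_sims, glm_n_perm, glm_select_by_aic,
                     data_length_ms, sampling_rate, noise_scale,
                     n_trials, fs_sim, beta, n_bins,
                     trial_placement, master_seed, progress)
  critical <- z |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      critical_z = if (dplyr::n() >= 100) {
        empirical_critical_z(.data$z, alpha)
      } else {
        NA_real_  # too few null values for a stable quantile
      },
      n = dplyr::n(), .groups = "drop")
  if (anyNA(critical$critical_z)) {
    warning("fewer than 100 null z-values per method: critical_z is NA",
            call. = FALSE)
  }
  crit_vec <- setNames(critical$critical_z, critical$method)
  calibrated <- names(crit_vec)[is.finite(crit_vec)]
  fp <- if (length(calibrated) == 0 || n_sims < subsample_size) {
    tibble::tibble(method = character(), data_length_ms = numeric(),
                   sampling_rate = numeric(), noise_scale = numeric(),
                   subsample = integer(), n_false_positive = integer())
  } else {
    z |>
      dplyr::filter(.data$method %in% calibrated) |>
      dplyr::group_by(.data$method, .data$data_length_ms, .data$sampling_rate,
                      .data$noise_scale) |>
      dplyr::group_modify(function(df, key) {
        counts <- subsample_false_positives(
          df$z[order(df$dataset)], crit_vec[[key$method[[1]]]], subsample_size)
        tibble::tibble(subsample = seq_along(counts), n_false_positive = counts)
      }) |>
      dplyr::ungroup()
  }
  structure(
    list(z = z, critical = critical, fp = fp,
         params = list(pair = pair, methods = methods, n_sims = n_sims,
                       n_perm = n_perm, glm_n_sims = glm_n_sims,
                       glm_n_perm = glm_n_perm, alpha = alpha,
                       subsample_size = subsample_size,
                       master_seed = master_seed)),
    class = "pac_specificity")
}

#' Run the sensitivity (moderator) study
#'
#' Simulates `n_sims` base datasets with implanted coupling and modifies
#' each across the full factorial grid: modulation strength x width x
#' multimodality x data length x sampling rate x noise level.  Marginal
#' means over any factor are balanced averages over all others
#' ([marginal_means()]).
#'
#' @inheritParams run_specificity
#' @param intensity modulation strengths (`I > 0`).
#' @param width_fraction modulation widths.
#' @param multimodality coupling forms to include.
#' @param critical optional named vector of critical z-values (from
#'   [run_specificity()]) used to flag significance.
#' @return A `pac_sensitivity` object: list with tibble `z` and the call
#'   parameters.
#' @export
run_sensitivity <- function(pair = "theta_low_gamma",
                            methods = c("plv", "mvl", "mi", "glm_cfc"),
                            n_sims = 100, n_perm = 1000,
                            glm_n_sims = n_sims, glm_n_perm = n_perm,
                            glm_select_by_aic = FALSE,
                            intensity = c(0.9, 1.0, 1.1),
                            width_fraction = c(0.225, 0.25, 0.275),
                            multimodality = c("monophasic", "biphasic"),
                            data_length_ms = c(400, 2500, 5000),
                            sampling_rate = c(500, 1000),
                            noise_scale = c(0.9, 1.0, 1.1),
                            n_trials = 30, fs_sim = 1000, beta = 2,
                            n_bins = 18, critical = NULL,
                            trial_placement = "random",
                            master_seed = 1, progress = FALSE) {
  methods <- match.arg(methods, pac_methods, several.ok = TRUE)
  multimodality <- match.arg(multimodality,
                             c("monophasic", "biphasic"), several.ok = TRUE)
  if (any(intensity <= 0)) abort("sensitivity requires `intensity` > 0")
  implants <- as.data.frame(tidyr::expand_grid(
    intensity = intensity, width_fraction = width_fraction,
    multimodality = multimodality))
  z <- run_pac_study(pair, implants, methods, n_sims, n_perm,
                     glm_n_sims, glm_n_perm, glm_select_by_aic,
                     data_length_ms, sampling_rate, noise_scale,
                     n_trials, fs_sim, beta, n_bins,
                     trial_placement, master_seed, progress)
  if (!is.null(critical)) {
    crit <- resolve_critical(critical, z$method)
    z$significant <- z$z > crit
  }
  structure(
    list(z = z,
         params = list(pair = pair, methods = methods, n_sims = n_sims,
                       n_perm = n_perm, glm_n_sims = glm_n_sims,
                       glm_n_perm = glm_n_perm, master_seed = master_seed)),
    class = "pac_sensitivity")
}

#' Balanced marginal means of standardized coupling values
#'
#' Mean and standard error of the z-values at each level of one factor,
#' averaged over all other factor levels.  With a balanced grid this equals
#' the unweighted average of the constituent cell means; the standard error
#' is computed across per-dataset means, mirroring the repeated-measures
#' design of the factorial studies.
#'
#' @param object a `pac_sensitivity` (or `pac_specificity`) object, or its
#'   `z` tibble.
#' @param margin factor column to keep: `"method"`, `"intensity"`,
#'   `"width_fraction"`, `"multimodality"`, `"data_length_ms"`,
#'   `"sampling_rate"` or `"noise_scale"` (always crossed with `method`).
#' @return A tibble with `method`, the margin level, `mean_z`, `se_z`, `n`.
#' @export
marginal_means <- function(object, margin = "method") {
  z <- if (is.data.frame(object)) object else object$z
  group_cols <- unique(c("method", margin))
  per_dataset <- z |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "dataset")))) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  per_dataset |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(mean_z = mean(.data$z),
                     se_z = sd(.data$z) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Count false positives in consecutive subsamples
#'
#' Splits a vector of null z-values into consecutive subsamples of
#' `subsample_size` (dropping any remainder) and counts, per subsample, how
#' many exceed the critical value.
#'
#' @param null_z numeric vector of z-values from no-coupling simulations.
#' @param critical_z significance threshold.
#' @param subsample_size values per subsample.
#' @return Integer vector of counts, one per subsample.
#' @export
subsample_false_positives <- function(null_z, critical_z, subsample_size = 50) {
  assert_scalar_number(critical_z, "critical_z")
  assert_scalar_number(subsample_size, "subsample_size", lower = 1)
  n_sub <- length(null_z) %/% subsample_size
  if (n_sub < 1) abort("`subsample_size` exceeds the number of values")
  used <- null_z[seq_len(n_sub * subsample_size)]
  as.integer(rowsum(as.numeric(used > critical_z),
                    rep(seq_len(n_sub), each = subsample_size)))
}

#' @export
print.pac_specificity <- function(x, ...) {
  cat(sprintf("<pac_specificity: %s, %d datasets x %d cells, %d perms>\n",
              x$params$pair, x$params$n_sims,
              nrow(dplyr::distinct(x$z[, c("data_length_ms", "sampling_rate",
                                           "noise_scale")])),
              x$params$n_perm))
  print(x$critical)
  invisible(x)
}

#' @export
print.pac_sensitivity <- function(x, ...) {
  cat(sprintf("<pac_sensitivity: %s, %d datasets, %d perms>\n",
              x$params$pair, x$params$n_sims, x$params$n_perm))
  print(marginal_means(x))
  invisible(x)
}
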