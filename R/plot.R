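#' Phase-amplitude histogram plot
#'
#' Bar chart of the mean envelope per phase bin (the distribution scored by
#' the modulation index): flat under no coupling, one bump under monophasic
#' and two opposed bumps under biphasic coupling.
#'
#' @inheritParams pac_estimators
#' @return A ggplot object.
#' @export
plot_phase_amplitude <- function(trials, n_bins = 18) {
  h <- phase_amplitude_histogram(trials, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_center_deg,
                                  y = .data$mean_amplitude)) +
    ggplot2::geom_col(fill = "steelblue", color = "grey20", width = 360 / n_bins) +
    ggplot2::labs(x = "phase of slow oscillation (deg)",
                  y = "mean amplitude of fast oscillation") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::theme_minimal()
}

#' Polar scatter of the analytic coupling vectors
#'
#' Each sample is the vector \eqn{a_t e^{i\theta_t}} whose average is the
#' mean vector length; the red segment marks the mean vector (drawn at 10x
#' length for visibility).
#'
#' @inheritParams pac_estimators
#' @param max_points subsample cap for plotting.
#' @return A ggplot object.
#' @export
plot_coupling_polar <- function(trials, max_points = 3000) {
  d <- extract_phase_amp(trials)
  keep <- if (length(d$phase) > max_points) {
    seq(1, length(d$phase), length.out = max_points)
  } else {
    seq_along(d$phase)
  }
  df <- tibble::tibble(phase = d$phase[keep], amplitude = d$amplitude[keep])
  mv <- mean(d$amplitude * exp(1i * d$phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$amplitude)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::annotate("segment", x = Arg(mv), xend = Arg(mv),
                      y = 0, yend = 10 * Mod(mv), color = "red",
                      linewidth = 1) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi),
                                labels = c("-90", "0", "90", "180")) +
    ggplot2::labs(x = "phase (deg)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' @describeIn pac-autoplot surrogate distributions with the observed value
#'   per method.
#' @export
autoplot.pac_result <- function(object, ...) {
  surr <- attr(object, "surrogates")
  if (is.null(surr)) {
    abort("run estimate_pac() with keep_surrogates = TRUE to plot surrogates")
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(surr),
                              dplyr::everything(),
                              names_to = "method", values_to = "value")
  obs <- tibble::tibble(method = object$method, value = object$raw)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        color = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = "coupling value", y = "surrogate count") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for study objects
#'
#' @param object a study result object.
#' @param margin factor to display on the x axis (sensitivity only).
#' @param ... unused.
#' @return A ggplot object.
#' @name pac-autoplot
NULL

#' @describeIn pac-autoplot null z distributions with the calibrated
#'   critical value per method.
#' @export
autoplot.pac_specificity <- function(object, ...) {
  ggplot2::ggplot(object$z, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = object$critical,
                        ggplot2::aes(xintercept = .data$critical_z),
                        color = "red", linetype = 2) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "standardized coupling value (z)", y = "density",
                  title = "Null distributions and empirical critical values") +
    ggplot2::theme_minimal()
}

#' @describeIn pac-autoplot marginal mean z (+/- SE) per factor level and
#'   method.
#' @export
autoplot.pac_sensitivity <- function(object, margin = "intensity", ...) {
  mm <- marginal_means(object, margin)
  mm$level <- factor(mm[[margin]])
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$level, y = .data$mean_z,
                                   group = .data$method,
                                   color = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$se_z,
                   ymax = .data$mean_z + .data$se_z),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = margin, y = "mean z (+/- SE)") +
    ggplot2::theme_minimal()
}
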