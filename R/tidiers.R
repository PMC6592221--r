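#' Tidiers for coupling results and study objects
#'
#' broom-style methods: `tidy()` returns one row per estimate or cell,
#' `glance()` a one-row (per method) summary.
#'
#' @param x a `pac_result`, `pac_specificity` or `pac_sensitivity` object.
#' @param ... unused.
#' @return A tibble.
#' @name pac-tidiers
NULL

#' @rdname pac-tidiers
#' @export
tidy.pac_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname pac-tidiers
#' @export
glance.pac_result <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x),
    n_perm = x$n_perm[1],
    max_z = max(x$z),
    any_significant = if (all(is.na(x$significant))) NA else
      any(x$significant, na.rm = TRUE)
  )
}

#' @rdname pac-tidiers
#' @export
tidy.pac_specificity <- function(x, ...) {
  x$z |>
    dplyr::group_by(.data$method, .data$data_length_ms, .data$sampling_rate,
                    .data$noise_scale) |>
    dplyr::summarise(mean_z = mean(.data$z),
                     se_z = sd(.data$z) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' @rdname pac-tidiers
#' @export
glance.pac_specificity <- function(x, ...) {
  null_means <- x$z |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_null_z = mean(.data$z),
                     se_null_z = sd(.data$z) / sqrt(dplyr::n()),
                     .groups = "drop")
  dplyr::left_join(x$critical, null_means, by = "method")
}

#' @rdname pac-tidiers
#' @export
tidy.pac_sensitivity <- function(x, ...) {
  x$z
}

#' @rdname pac-tidiers
#' @export
glance.pac_sensitivity <- function(x, ...) {
  marginal_means(x, "method")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
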