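#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a restitution curve
#'
#' @param x A `restitution_curve`.
#' @param ... Unused.
#' @return Tibble of per-BCL records (`bcl`, `di`, `apd`, `apd_alt`,
#'   `alternans`, `slope`).
#' @method tidy restitution_curve
#' @export
tidy.restitution_curve <- function(x, ...) {
  tibble::as_tibble(x)[, c("bcl", "di", "apd", "apd_alt", "alternans",
                           "slope")]
}

#' One-row summary of a restitution curve
#'
#' @inheritParams tidy.restitution_curve
#' @return Tibble with `cell_type`, `condition`, `protocol`, `max_slope`,
#'   `alternans_onset` and `truncated`.
#' @method glance restitution_curve
#' @export
glance.restitution_curve <- function(x, ...) {
  onset <- if (!is.null(attr(x, "apd_sequences"))) {
    detect_alternans(x, threshold = attr(x, "alternans_threshold"))
  } else {
    NA_real_
  }
  tibble::tibble(
    cell_type = attr(x, "cell_type"), condition = attr(x, "condition"),
    protocol = attr(x, "protocol"),
    max_slope = max(x$slope, na.rm = TRUE),
    alternans_onset = onset, truncated = attr(x, "truncated"))
}

#' Tidy pressure-volume metrics
#'
#' @param x A `pv_loop_metrics` row.
#' @param ... Unused.
#' @return Long tibble `metric`, `value`.
#' @method tidy pv_loop_metrics
#' @export
tidy.pv_loop_metrics <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of activation maps
#'
#' @param x An `activation_maps` tibble.
#' @param ... Unused.
#' @return Tibble with EAT/EDT extrema and the QRS/QT surrogates.
#' @method glance activation_maps
#' @export
glance.activation_maps <- function(x, ...) {
  tibble::tibble(
    min_eat = min(x$eat, na.rm = TRUE), max_eat = max(x$eat, na.rm = TRUE),
    max_edt = max(x$edt, na.rm = TRUE),
    qrs = attr(x, "qrs"), qt = attr(x, "qt"),
    n_unactivated = attr(x, "n_unactivated"))
}
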