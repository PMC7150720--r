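#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a paced single-cell trace
#'
#' Membrane potential and cytosolic calcium against time.
#'
#' @param object A `paced_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot paced_trace
#' @export
autoplot.paced_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "V", "Ca_i")],
    c("V", "Ca_i"), names_to = "series", values_to = "value")
  df$series <- factor(df$series, c("V", "Ca_i"),
                      c("V (mV)", "Ca_i (mM)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (ms)", y = NULL,
      title = paste(attr(object, "cell_type"), "cell,",
                    attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' Plot a restitution curve
#'
#' APD against diastolic interval; alternating BCLs show both branches.
#'
#' @param object A `restitution_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot restitution_curve
#' @export
autoplot.restitution_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[!is.na(df$apd), ],
                       ggplot2::aes(.data$di, .data$apd)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$alternans), size = 1)
  if (any(!is.na(df$apd_alt))) {
    p <- p + ggplot2::geom_point(
      data = df[!is.na(df$apd_alt), ],
      ggplot2::aes(y = .data$apd_alt), shape = 1, size = 1)
  }
  p + ggplot2::labs(
    x = "diastolic interval (ms)", y = "APD90 (ms)",
    title = paste(attr(object, "cell_type"), "cell,",
                  attr(object, "condition"), "-",
                  attr(object, "protocol"), "restitution")) +
    ggplot2::theme_minimal()
}

#' Plot a force trace
#'
#' Normalised active force and its driving calcium.
#'
#' @param object A `force_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "F_active", "Ca_i")],
    c("F_active", "Ca_i"), names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the left-ventricular pressure-volume loop
#'
#' @param object A `circulation_run`.
#' @param beats How many final beats to draw.
#' @param bcl Pacing period, ms (to delimit beats).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circulation_run
#' @export
autoplot.circulation_run <- function(object, beats = 2, bcl = 600, ...) {
  t_end <- max(object$t)
  df <- object[object$t > t_end - beats * bcl, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$V_lv, .data$P_lv)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "LV volume (mL)", y = "LV pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot activation / deactivation maps
#'
#' EAT and EDT as spatial rasters (2D sheets) or profiles (cables).
#'
#' @param object An `activation_maps` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activation_maps
#' @export
autoplot.activation_maps <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("eat", "edt"),
                            names_to = "map", values_to = "ms")
  if (length(unique(object$y_cm)) > 1) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x_cm, .data$y_cm,
                                     fill = .data$ms)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~map) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (cm)", y = "y (cm)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x_cm, .data$ms,
                                     colour = .data$map)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "position (cm)", y = "time (ms)") +
      ggplot2::theme_minimal()
  }
}
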