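#' Mutation conditions for the Kir2.1 inward-rectifier current
#'
#' The three expression levels of the KCNJ2 E299V gain-of-function mutation
#' are modelled as three closed-form current-voltage relations for I_K1:
#' wild type (`"WT"`), heterozygous expression (`"WT_E299V"`), and pure
#' mutant (`"E299V"`). The wild-type and heterozygous curves are inwardly
#' rectifying rational functions of the driving force; the pure mutant has
#' lost rectification and is a quasi-ohmic quadratic. Nothing else in the
#' ionic model changes between conditions.
#'
#' Each formulation carries a single multiplicative conductance scale,
#' calibrated once so that the peak outward current over a resting-to-peak
#' voltage sweep matches the reported current densities (1.9 pA/pF for WT,
#' 2.3 pA/pF for WT/E299V; the mutant curve is used as printed and peaks
#' above 4 pA/pF). See the methods vignette for the calibration rationale.
#'
#' @param label One of `"WT"`, `"WT_E299V"`, `"E299V"`.
#' @return A `mutation_condition` object: a list with the label, the integer
#'   code used by the compiled model, the polynomial/rational coefficients,
#'   and the calibrated conductance scale.
#' @examples
#' mutation_condition("E299V")
#' @export
mutation_condition <- function(label = c("WT", "WT_E299V", "E299V")) {
  if (inherits(label, "mutation_condition")) {
    return(label)
  }
  if (!is.character(label) || length(label) != 1 ||
      !label %in% c("WT", "WT_E299V", "E299V")) {
    stop("unknown mutation condition; must be one of ",
         "\"WT\", \"WT_E299V\", \"E299V\"", call. = FALSE)
  }
  code <- match(label, c("WT", "WT_E299V", "E299V")) - 1L
  coef <- switch(label,
    WT = c(a = 0.24731, shift = 0, b = 0.86426, c = 0.0904, d = -0.06519),
    WT_E299V = c(a = 0.11905, shift = 2.4, b = 0.04092, c = 0.01732,
                 d = -0.36212),
    E299V = c(a = 0.06634, shift = 6.5, q = -2.44009e-4, d = -0.51383)
  )
  structure(
    list(label = label, code = code, coefficients = coef,
         scale = ik1_conductance_scale(code)),
    class = "mutation_condition"
  )
}

#' @export
print.mutation_condition <- function(x, ...) {
  cat("<mutation_condition> ", x$label, "\n", sep = "")
  cat("  conductance scale: ", format(x$scale, digits = 6), "\n", sep = "")
  cat("  coefficients: ",
      paste(names(x$coefficients), format(x$coefficients), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# reported peak outward I_K1 densities (pA/pF) used as calibration anchors
ik1_peak_targets <- c(1.9, 2.3, NA)

# per-condition conductance scale: peak of the raw curve over the
# physiological driving-force range is matched to the reported density;
# the pure-mutant quadratic is used as printed (scale 1)
ik1_conductance_scale <- function(code) {
  target <- ik1_peak_targets[code + 1]
  if (is.na(target)) {
    return(1)
  }
  pk <- stats::optimize(function(u) cpp_ik1_shape(u, code),
                        interval = c(0, 130), maximum = TRUE)$objective
  target / pk
}

#' Inward-rectifier potassium current
#'
#' Evaluates the I_K1 current-voltage relation for a mutation condition,
#' including the calibrated conductance scale. Vectorised over `V`.
#'
#' @param V Membrane potential, mV.
#' @param E_K Potassium equilibrium potential, mV (about -86 mV at
#'   physiological concentrations).
#' @param condition A condition label or [mutation_condition()] object.
#' @return Current density in pA/pF (positive = outward).
#' @examples
#' ik1_current(-60, -86, "WT")
#' @export
ik1_current <- function(V, E_K = -86, condition = "WT") {
  cond <- mutation_condition(condition)
  u <- V - E_K
  raw <- vapply(u, cpp_ik1_shape, numeric(1), cond = cond$code)
  cond$scale * raw
}
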