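#' Synthetic calcium transient parameters
#'
#' A periodic double-exponential (fast rise, slow decay) calcium transient
#' used to exercise the myofilament stage in isolation from the ionic
#' model. The rise constant is derived from the requested time-to-peak so
#' that the transient attains exactly `baseline + amplitude` at
#' `time_to_peak` within each period.
#'
#' @param baseline Diastolic calcium, mM (> 0).
#' @param amplitude Transient amplitude above baseline, mM (>= 0).
#' @param time_to_peak Time to peak within the period, ms.
#' @param tau_decay Decay time constant, ms.
#' @param period Repetition period, ms.
#' @return List of class `ca_transient_spec`.
#' @export
synthetic_ca_transient <- function(baseline = 1e-4, amplitude = 9e-4,
                                   time_to_peak = 30, tau_decay = 60,
                                   period = 600) {
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  stopifnot(time_to_peak > 0, tau_decay > 0, period > time_to_peak)
  # rise constant such that the double exponential peaks at time_to_peak
  f <- function(tr) {
    log(tau_decay / tr) * tau_decay * tr / (tau_decay - tr) - time_to_peak
  }
  tau_rise <- stats::uniroot(f, c(tau_decay * 1e-4, tau_decay * 0.9999),
                             tol = 1e-10)$root
  shape_peak <- exp(-time_to_peak / tau_decay) - exp(-time_to_peak / tau_rise)
  structure(list(baseline = baseline, amplitude = amplitude,
                 time_to_peak = time_to_peak, tau_decay = tau_decay,
                 tau_rise = tau_rise, period = period,
                 norm = 1 / shape_peak),
            class = "ca_transient_spec")
}

#' Evaluate a synthetic calcium transient
#'
#' @param spec A [synthetic_ca_transient()] specification.
#' @param t Time grid, ms.
#' @return Tibble `t`, `Ca_i` (mM); the series never drops below baseline.
#' @export
synthetic_ca <- function(spec, t) {
  stopifnot(inherits(spec, "ca_transient_spec"))
  tp <- t %% spec$period
  shape <- spec$norm *
    (exp(-tp / spec$tau_decay) - exp(-tp / spec$tau_rise))
  shape[shape < 0] <- 0
  tibble::tibble(t = t, Ca_i = spec$baseline + spec$amplitude * shape)
}

scenario_conditions <- c("WT", "WT_E299V", "E299V")
scenario_cell_types <- c("endo", "mid", "epi")

#' Scenario catalogue
#'
#' The registered experiment configurations: nine single-cell sinus runs
#' (condition x cell type), and one restitution scan, transmural cable
#' run, ring-reentry run and pump (circulation) run per condition.
#'
#' @return Tibble with `name`, `kind`, `condition`, `cell_type`.
#' @export
scenario_catalogue <- function() {
  sinus <- tidyr::expand_grid(condition = scenario_conditions,
                              cell_type = scenario_cell_types)
  dplyr::bind_rows(
    tibble::tibble(name = paste0("sinus-", sinus$condition, "-",
                                 sinus$cell_type),
                   kind = "sinus", condition = sinus$condition,
                   cell_type = sinus$cell_type),
    tibble::tibble(name = paste0("restitution-", scenario_conditions),
                   kind = "restitution", condition = scenario_conditions,
                   cell_type = NA_character_),
    tibble::tibble(name = paste0("cable-", scenario_conditions),
                   kind = "cable", condition = scenario_conditions,
                   cell_type = NA_character_),
    tibble::tibble(name = paste0("reentry-", scenario_conditions),
                   kind = "reentry", condition = scenario_conditions,
                   cell_type = NA_character_),
    tibble::tibble(name = paste0("pump-", scenario_conditions),
                   kind = "pump", condition = scenario_conditions,
                   cell_type = NA_character_)
  )
}

#' Build a scenario configuration
#'
#' Returns the complete, validated configuration for a registered scenario
#' name. Every numeric protocol parameter is explicit in the returned
#' object, so a scenario serialises losslessly ([scenario_to_json()]) and
#' two runs of the same scenario are identical in configuration.
#'
#' @param name A name from [scenario_catalogue()].
#' @param reduced Use the reduced-duration test variant (shorter reentry
#'   and fewer circulation beats); the full variant is the default.
#' @return List of class `scenario`.
#' @export
make_scenario <- function(name, reduced = FALSE) {
  cat_tbl <- scenario_catalogue()
  row <- cat_tbl[cat_tbl$name == name, ]
  if (!nrow(row)) {
    stop("unknown scenario '", name, "'; valid names:\n  ",
         paste(cat_tbl$name, collapse = ", "), call. = FALSE)
  }
  base <- list(name = name, kind = row$kind, condition = row$condition,
               cell_type = row$cell_type, seed = 1L, reduced = reduced)
  proto <- switch(row$kind,
    sinus = list(bcl = 600, n_beats = 10, dt = 0.02, record_dt = 0.25),
    restitution = list(bcl_start = 400, bcl_start_mid = 550,
                       bcl_stop = 200, bcl_step = 10,
                       n_equil = 30, n_measure = 8,
                       alternans_threshold = 2, dt = 0.02),
    cable = list(length_cm = 1.5, dx = 0.025, D = D_NORMAL, bcl = 600,
                 n_beats = 2, dt = 0.02),
    reentry = list(circumference_cm = if (reduced) 6 else 7, dx = 0.025,
                   D = D_LOW_CV, duration = if (reduced) 2000 else 10000,
                   block_ms = 320, dt = 0.02),
    pump = list(bcl = 600, n_beats = 10,
                myo_beats = 8, dt_circ = 0.25)
  )
  structure(c(base, list(protocol = proto)), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, " (", x$kind, ", ", x$condition,
      if (!is.na(x$cell_type)) paste0(", ", x$cell_type), ")\n", sep = "")
  utils::str(x$protocol, give.attr = FALSE)
  invisible(x)
}

#' Serialise / deserialise a scenario
#'
#' Round-trips through JSON without loss: `scenario_from_json(
#' scenario_to_json(s))` is identical to `s`.
#'
#' @param scenario A [make_scenario()] object.
#' @return JSON string.
#' @export
scenario_to_json <- function(scenario) {
  jsonlite::toJSON(unclass(scenario), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}

#' @rdname scenario_to_json
#' @param json JSON string from [scenario_to_json()].
#' @export
scenario_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$cell_type <- if (is.null(x$cell_type)) NA_character_ else x$cell_type
  x$seed <- as.integer(x$seed)
  x$protocol <- lapply(x$protocol,
                       function(v) if (is.numeric(v)) as.numeric(v) else v)
  structure(x, class = "scenario")
}
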