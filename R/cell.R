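par_order <- c(
  "g_Na", "g_K1", "g_to", "g_Kr", "g_Ks", "g_CaL", "g_bNa", "g_bCa",
  "g_pCa", "K_pCa", "g_pK", "P_NaK", "K_mK", "K_mNa", "k_NaCa", "K_sat",
  "alpha_NaCa", "gamma_NaCa", "K_mNai", "K_mCa", "V_maxup", "K_up", "V_rel",
  "V_leak", "V_xfer", "k1_prime", "k2_prime", "k3", "k4", "EC", "max_sr",
  "min_sr", "Buf_c", "K_bufc", "Buf_sr", "K_bufsr", "Buf_ss", "K_bufss",
  "V_c", "V_sr", "V_ss", "C_m", "K_o", "Na_o", "Ca_o"
)

base_cell_params <- c(
  g_Na = 14.838, g_K1 = 1, g_to = 0.294, g_Kr = 0.153, g_Ks = 0.392,
  g_CaL = 3.98e-5, g_bNa = 2.9e-4, g_bCa = 5.92e-4, g_pCa = 0.1238,
  K_pCa = 5e-4, g_pK = 0.0146, P_NaK = 2.724, K_mK = 1, K_mNa = 40,
  k_NaCa = 1000, K_sat = 0.1, alpha_NaCa = 2.5, gamma_NaCa = 0.35,
  K_mNai = 87.5, K_mCa = 1.38, V_maxup = 0.006375, K_up = 2.5e-4,
  V_rel = 0.102, V_leak = 3.6e-4, V_xfer = 0.0038, k1_prime = 0.15,
  k2_prime = 0.045, k3 = 0.06, k4 = 0.005, EC = 1.5, max_sr = 2.5,
  min_sr = 1, Buf_c = 0.2, K_bufc = 0.001, Buf_sr = 10, K_bufsr = 0.3,
  Buf_ss = 0.4, K_bufss = 2.5e-4, V_c = 0.016404, V_sr = 0.001094,
  V_ss = 5.468e-5, C_m = 0.185, K_o = 5.4, Na_o = 140, Ca_o = 2
)

cell_type_code <- function(cell_type) {
  if (!is.character(cell_type) || length(cell_type) != 1 ||
      !cell_type %in% c("endo", "mid", "epi")) {
    stop("unknown cell type; must be one of \"endo\", \"mid\", \"epi\"",
         call. = FALSE)
  }
  match(cell_type, c("endo", "mid", "epi")) - 1L
}

#' Ionic parameter set for a ventricular cell type
#'
#' Builds the full parameter vector of the ventricular myocyte model for one
#' of the three transmural cell types. The slow delayed-rectifier
#' conductance follows the study's transmural assignment: `g_Ks` is
#' 0.392 x 1.3 mS/uF for endocardial and epicardial cells and 0.073 mS/uF
#' for the midmyocardial cell; the transient-outward conductance keeps the
#' base model's endocardial/epicardial difference. The inward-rectifier
#' conductance slot holds the calibrated per-condition scale.
#'
#' @param cell_type `"endo"`, `"mid"` or `"epi"`.
#' @param condition Mutation condition (label or object).
#' @param ... Named parameter overrides (e.g. `g_Ks = 0.392`).
#' @return Named numeric vector of class `ionic_parameters` with
#'   `cell_type` and `condition` attributes.
#' @export
cell_parameters <- function(cell_type = "endo", condition = "WT", ...) {
  ctc <- cell_type_code(cell_type)
  cond <- mutation_condition(condition)
  p <- base_cell_params
  if (cell_type == "endo") {
    p[["g_to"]] <- 0.073
    p[["g_Ks"]] <- 0.392 * 1.3
  } else if (cell_type == "mid") {
    p[["g_to"]] <- 0.294
    p[["g_Ks"]] <- 0.073
  } else {
    p[["g_to"]] <- 0.294
    p[["g_Ks"]] <- 0.392 * 1.3
  }
  p[["g_K1"]] <- cond$scale
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- unlist(dots)
  }
  if (any(p[grep("^g_", names(p))] < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  structure(p[par_order], class = "ionic_parameters",
            cell_type = cell_type, condition = cond$label)
}

#' Construct a resting ventricular cell
#'
#' Returns the initial (diastolic) state and the parameter set for a cell of
#' the given transmural type under a mutation condition. The initial state
#' is the model's quiescent point; paced protocols equilibrate from here.
#'
#' @inheritParams cell_parameters
#' @return List with elements `state` (named state vector of class
#'   `cell_state`) and `params` ([cell_parameters()] vector).
#' @examples
#' cell <- make_cell("endo", "WT")
#' cell$params[["g_Ks"]]
#' @export
make_cell <- function(cell_type = "endo", condition = "WT", ...) {
  params <- cell_parameters(cell_type, condition, ...)
  state <- cpp_default_state()
  attr(state, "t") <- 0
  class(state) <- "cell_state"
  list(state = state, params = params)
}

#' Validate a cell state vector
#'
#' Checks the physical invariants of a ventricular cell state: all gating
#' variables in \[0, 1\], all ionic concentrations positive, and membrane
#' potential finite within \[-120, 80\] mV.
#'
#' @param state Named state vector as produced by [make_cell()] or
#'   [step_cell()].
#' @return Invisibly `TRUE`; stops with a message naming the failing
#'   variable otherwise.
#' @export
validate_cell_state <- function(state) {
  gates <- c("m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
             "xr1", "xr2", "xs", "Rbar")
  conc <- c("Ca_i", "Ca_SR", "Ca_ss", "Na_i", "K_i")
  if (!all(gates %in% names(state)) || !all(conc %in% names(state))) {
    stop("state is missing required variables", call. = FALSE)
  }
  for (g in gates) {
    if (!is.finite(state[[g]]) || state[[g]] < -1e-9 || state[[g]] > 1 + 1e-9) {
      stop("gating variable '", g, "' outside [0, 1]: ", state[[g]],
           call. = FALSE)
    }
  }
  for (cc in conc) {
    if (!is.finite(state[[cc]]) || state[[cc]] <= 0) {
      stop("concentration '", cc, "' not positive: ", state[[cc]],
           call. = FALSE)
    }
  }
  if (!is.finite(state[["V"]]) || state[["V"]] < -120 || state[["V"]] > 80) {
    stop("membrane potential outside [-120, 80] mV: ", state[["V"]],
         call. = FALSE)
  }
  invisible(TRUE)
}

#' All membrane currents and SR fluxes at a state
#'
#' Evaluates the twelve membrane currents of the ionic model, their sum,
#' the sarcoplasmic-reticulum fluxes and the equilibrium potentials at a
#' given state. The inward-rectifier current is delegated to the
#' condition-specific formulation (see [ik1_current()]).
#'
#' @param state Cell state vector.
#' @param params [cell_parameters()] vector.
#' @param condition Mutation condition; defaults to the condition the
#'   parameter set was built for.
#' @return One-row tibble with currents (pA/pF), fluxes (mM/ms) and
#'   equilibrium potentials (mV).
#' @export
compute_currents <- function(state, params,
                             condition = attr(params, "condition")) {
  if (!all(is.finite(unclass(state)))) {
    stop("non-finite entries in cell state", call. = FALSE)
  }
  cond <- mutation_condition(condition)
  ctc <- cell_type_code(attr(params, "cell_type") %||% "endo")
  out <- cpp_currents(as.numeric(state), as.numeric(params), ctc, cond$code)
  tibble::as_tibble(out)
}

#' Advance a single cell by one or more fixed time steps
#'
#' Operator-split update: Rush-Larsen exponential integration for the
#' Hodgkin-Huxley gates and forward Euler for membrane potential and
#' concentrations. Deterministic for fixed inputs.
#'
#' @param state Cell state vector.
#' @param params [cell_parameters()] vector.
#' @param condition Mutation condition.
#' @param I_stim Stimulus current density, pA/pF (negative depolarises).
#' @param dt Time step, ms. The production default for this model family is
#'   0.02 ms.
#' @param n Number of steps to take.
#' @return Updated state vector.
#' @export
step_cell <- function(state, params, condition = attr(params, "condition"),
                      I_stim = 0, dt = 0.02, n = 1) {
  cond <- mutation_condition(condition)
  ctc <- cell_type_code(attr(params, "cell_type") %||% "endo")
  out <- cpp_step_cell(as.numeric(state), as.numeric(params), ctc, cond$code,
                       I_stim, dt, as.integer(n))
  attr(out, "t") <- (attr(state, "t") %||% 0) + n * dt
  class(out) <- "cell_state"
  out
}

#' Simulate a stimulated single cell
#'
#' Low-level paced run. Most users want [pace_to_steady_state()], which
#' wraps this with the sinus-rhythm protocol.
#'
#' @param cell List with `state` and `params`, as from [make_cell()].
#' @param duration Total simulated time, ms.
#' @param stim_times Onset times of the stimulus pulses, ms.
#' @param stim_amp,stim_dur Stimulus amplitude (pA/pF) and width (ms).
#' @param dt Integration step, ms.
#' @param record_from Time from which the trace is stored, ms.
#' @param record_dt Output sampling interval, ms.
#' @param record_currents Store all membrane currents, not just I_K1.
#' @return A `paced_trace` tibble with columns `t`, `V`, `Ca_i`, `I_K1`
#'   (plus currents if requested); attributes hold the stimulus schedule and
#'   the final state for protocol continuation.
#' @export
simulate_cell <- function(cell, duration, stim_times, stim_amp = -52,
                          stim_dur = 1, dt = 0.02, record_from = 0,
                          record_dt = 0.25, record_currents = FALSE) {
  cond <- mutation_condition(attr(cell$params, "condition"))
  ctc <- cell_type_code(attr(cell$params, "cell_type"))
  res <- cpp_run_cell(as.numeric(cell$state), as.numeric(cell$params), ctc,
                      cond$code, duration, dt, stim_times, stim_amp,
                      stim_dur, record_from, record_dt, record_currents)
  tr <- tibble::as_tibble(as.data.frame(res$trace))
  final <- res$state
  attr(final, "t") <- (attr(cell$state, "t") %||% 0) + duration
  class(final) <- "cell_state"
  new_paced_trace(tr,
                  stim_times = stim_times, stim_amp = stim_amp,
                  stim_dur = stim_dur, dt = dt,
                  cell_type = attr(cell$params, "cell_type"),
                  condition = cond$label, final_state = final,
                  params = cell$params)
}

#' Resting membrane potential by root finding
#'
#' Finds the potential at which the total membrane current vanishes, with
#' gates at their steady-state values and concentrations held at the given
#' state. Serves as an independent check on the quiescent state of the
#' model.
#'
#' @inheritParams compute_currents
#' @param interval Search interval for the root, mV.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(params, condition = attr(params, "condition"),
                              state = cpp_default_state(),
                              interval = c(-95, -60)) {
  f <- function(v) {
    s <- equilibrate_gates(state, v)
    compute_currents(s, params, condition)$I_ion
  }
  stats::uniroot(f, interval, tol = 1e-8)$root
}

# gates to steady state at potential v (concentrations untouched)
equilibrate_gates <- function(state, v) {
  s <- as.numeric(state)
  names(s) <- names(state)
  s[["V"]] <- v
  inf2 <- function(vh, k) 1 / (1 + exp((s[["V"]] + vh) / k))
  s[["m"]] <- 1 / (1 + exp((-56.86 - v) / 9.03))^2
  s[["h"]] <- 1 / (1 + exp((v + 71.55) / 7.43))^2
  s[["j"]] <- s[["h"]]
  s[["d"]] <- 1 / (1 + exp((-8 - v) / 7.5))
  s[["f"]] <- inf2(20, 7)
  s[["f2"]] <- 0.67 / (1 + exp((v + 35) / 7)) + 0.33
  s[["fcass"]] <- 0.6 / (1 + (s[["Ca_ss"]] / 0.05)^2) + 0.4
  s[["r"]] <- 1 / (1 + exp((20 - v) / 6))
  s[["s"]] <- inf2(28, 5)
  s[["xr1"]] <- 1 / (1 + exp((-26 - v) / 7))
  s[["xr2"]] <- inf2(88, 24)
  s[["xs"]] <- 1 / (1 + exp((-5 - v) / 14))
  class(s) <- "cell_state"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
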