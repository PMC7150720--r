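myo_par_order <- c(
  "k_on", "k_off", "k_np", "k_pn", "perm50", "n_perm_half", "pn_cap",
  "f_app", "g_app", "g_slmod", "h_f", "h_fmdc", "h_b", "g_xb",
  "sigma_p", "sigma_n", "x_0", "phi", "SL"
)

#' Myofilament (cross-bridge) model parameters
#'
#' Parameter set for the regulatory-unit / cross-bridge cycling model
#' (Rice-type formulation): calcium binds troponin (`k_on`, `k_off`,
#' per-mM-per-ms and per-ms), regulatory units switch between
#' nonpermissive and permissive conformations with strongly cooperative
#' rates `k_np * (TCa/perm50)^7.5` and `k_pn * (TCa/perm50)^-7.5` (capped
#' at `pn_cap`), and bound cross-bridges cycle through pre- and
#' post-rotation states with rates `f_app`, `g_app`, `h_f`, `h_b` and the
#' ATP-consuming detachment rate `g_xb` (all per ms, with the published
#' strain and overlap modifiers). Operation is isosarcometric at sarcomere
#' length `SL` (um); `x_0` is the cross-bridge power-stroke distortion.
#'
#' @param ... Named overrides of the defaults.
#' @return Named numeric vector of class `myofilament_parameters`.
#' @export
myofilament_parameters <- function(...) {
  p <- c(
    k_on = 50, k_off = 0.025,          # troponin Ca binding (Kd = 0.5 uM)
    k_np = 0.5, k_pn = 0.05,           # regulatory-unit switching, 1/ms
    perm50 = 0.45, n_perm_half = 7.5,  # cooperativity (Hill 15 overall)
    pn_cap = 5,                        # cap on the reverse switching rate
    f_app = 0.5, g_app = 0.07,         # attachment / detachment, 1/ms
    g_slmod = 6,
    h_f = 2, h_fmdc = 5, h_b = 0.4,    # rotation rates and strain modifier
    g_xb = 0.07,                       # ATP-consuming detachment, 1/ms
    sigma_p = 8, sigma_n = 1,
    x_0 = 0.007, phi = 2, SL = 2.2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown myofilament parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- unlist(dots)
  }
  structure(p[myo_par_order], class = "myofilament_parameters")
}

#' Initial (relaxed) myofilament state
#'
#' All regulatory units nonpermissive, no bound cross-bridges, zero
#' troponin occupancy, strains at their unloaded values.
#'
#' @param params [myofilament_parameters()].
#' @return Named state vector of class `myofilament_state`.
#' @export
myofilament_state <- function(params = myofilament_parameters()) {
  s <- cpp_myo_init(as.numeric(params))
  names(s) <- c("TCa_Tot", "N_xb", "P_xb", "XB_PreR", "XB_PostR",
                "xXB_PreR", "xXB_PostR")
  class(s) <- "myofilament_state"
  s
}

#' Advance the myofilament one step
#'
#' Forward-Euler update of the troponin, regulatory-unit and cross-bridge
#' ODEs at fixed cytosolic calcium. The four regulatory/cross-bridge
#' fractions are conservative: their sum stays 1 to integration tolerance.
#'
#' @param state [myofilament_state()] vector.
#' @param Ca_i Cytosolic calcium, mM (must be non-negative).
#' @param dt Step, ms (default 0.05 ms, well inside the stability bound of
#'   the fastest rate).
#' @param params [myofilament_parameters()].
#' @param n Number of steps.
#' @return Updated state vector.
#' @export
step_myofilament <- function(state, Ca_i, dt = 0.05,
                             params = myofilament_parameters(), n = 1) {
  if (Ca_i < 0) stop("Ca_i must be non-negative", call. = FALSE)
  out <- cpp_myo_step(as.numeric(state), as.numeric(params), Ca_i, dt,
                      as.integer(n))
  names(out) <- names(state)
  fr <- out[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")]
  if (any(fr < -1e-6) || any(fr > 1 + 1e-6)) {
    stop("cross-bridge fraction left [0, 1]", call. = FALSE)
  }
  class(out) <- "myofilament_state"
  out
}

#' Normalised active force of a myofilament state
#'
#' Force is the overlap-weighted sum of duty-fraction times mean distortion
#' over the two strongly bound states, normalised by `x_0` times the
#' maximal post-rotation duty fraction, so that optimal conditions (full
#' activation, full overlap, distortion at the power-stroke value) give 1.
#'
#' @inheritParams step_myofilament
#' @return Dimensionless force (>= 0 in normal operation).
#' @export
active_force <- function(state, params = myofilament_parameters()) {
  cpp_active_force(as.numeric(state), as.numeric(params))
}

#' Drive the myofilament with a calcium transient
#'
#' Integrates the cross-bridge model against a cytosolic calcium time
#' series (linearly interpolated), e.g. the `Ca_i` column of a
#' [pace_to_steady_state()] trace or a [synthetic_ca()] series.
#'
#' @param ca Data frame with columns `t` (ms) and `Ca_i` (mM).
#' @param duration Simulated time, ms; defaults to the calcium record
#'   length.
#' @param dt Integration step, ms.
#' @param record_dt Output sampling interval, ms.
#' @param params [myofilament_parameters()].
#' @param state Initial state; defaults to relaxed.
#' @return A `force_trace` tibble with `t`, `F_active`, `atp_flux`
#'   (instantaneous detachment flux, 1/ms), `Ca_i` and the state fractions;
#'   the final state is kept as an attribute.
#' @export
simulate_myofilament <- function(ca, duration = NULL, dt = 0.05,
                                 record_dt = 1,
                                 params = myofilament_parameters(),
                                 state = myofilament_state(params)) {
  stopifnot(all(c("t", "Ca_i") %in% names(ca)))
  if (any(ca$Ca_i < 0)) stop("calcium must be non-negative", call. = FALSE)
  if (is.null(duration)) duration <- max(ca$t) - min(ca$t)
  res <- cpp_run_myofilament(as.numeric(state), as.numeric(params),
                             ca$t - min(ca$t), ca$Ca_i, duration, dt,
                             record_dt)
  tr <- tibble::as_tibble(as.data.frame(res$trace))
  fin <- res$state
  names(fin) <- names(state)
  class(fin) <- "myofilament_state"
  structure(tr, class = c("force_trace", class(tr)),
            final_state = fin, params = params, dt = dt)
}

#' Beat-averaged ATP consumption rate
#'
#' The ATP turnover of cross-bridge cycling is the detachment flux through
#' the ATP-consuming transition, `g_xbT * XB_PostR`. This returns its time
#' average over the trace (optionally restricted to a window), converted to
#' events per second.
#'
#' @param force_trace A `force_trace` from [simulate_myofilament()].
#' @param window Optional `c(t0, t1)` window, ms.
#' @return ATP consumption rate, 1/s.
#' @export
atp_rate <- function(force_trace, window = NULL) {
  tr <- force_trace
  if (!is.null(window)) {
    tr <- tr[tr$t >= window[1] & tr$t <= window[2], ]
  }
  if (!nrow(tr)) stop("empty force trace (or window)", call. = FALSE)
  mean(tr$atp_flux) * 1000
}
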