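circ_par_order <- c(
  "V0_lv", "V0_la", "V0_rv", "V0_ra", "V0_sa", "V0_sv", "V0_pa", "V0_pv",
  "C_la", "C_ra", "C_sa", "C_sv", "C_pa", "C_pv",
  "R_mi", "R_ao", "R_sys", "R_vr", "R_tr", "R_pu", "R_pul", "R_pv"
)

#' Closed-loop circulation parameters
#'
#' Eight-compartment lumped circulation: left/right ventricles as
#' tension-driven varying-elastance chambers, passive atria, and systemic /
#' pulmonary arterial and venous compliances, connected through resistances
#' with diode valves (mitral, aortic, tricuspid, pulmonary). Compliances in
#' mL/mmHg, resistances in mmHg*s/mL, unstressed volumes `V0_*` in mL.
#'
#' `E_max_lv`, `E_min_lv` and `R_sys` were calibrated once so that the
#' wild-type sinus run at 100 bpm reproduces the reference stroke volume
#' and ejection fraction (59 mL, 54%); all parameters are then held fixed
#' across mutation conditions, so that only the cell-derived drive differs.
#'
#' @param ... Named overrides.
#' @return List of class `circulation_parameters` with the resistance /
#'   compliance vector plus elastance bounds and the force normalisation
#'   `F_ref`.
#' @export
circulation_parameters <- function(...) {
  p <- c(
    V0_lv = 10, V0_la = 5, V0_rv = 15, V0_ra = 5,
    V0_sa = 500, V0_sv = 2500, V0_pa = 80, V0_pv = 350,
    C_la = 10, C_ra = 12, C_sa = 1.6, C_sv = 60, C_pa = 5, C_pv = 16,
    R_mi = 0.004, R_ao = 0.008, R_sys = 0.85, R_vr = 0.03,
    R_tr = 0.004, R_pu = 0.008, R_pul = 0.1, R_pv = 0.02
  )
  extra <- list(
    E_max_lv = 2.8, E_min_lv = 0.17,
    E_max_rv = 0.6, E_min_rv = 0.045,
    F_ref = NA_real_,        # fixed at WT calibration by pump scenarios
    total_volume = 5000
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(p)) p[[nm]] <- dots[[nm]]
    else if (nm %in% names(extra)) extra[[nm]] <- dots[[nm]]
    else stop("unknown circulation parameter: ", nm, call. = FALSE)
  }
  structure(c(list(network = p[circ_par_order]), extra),
            class = "circulation_parameters")
}

#' Elastance drive from an active-force trace
#'
#' One-way electromechanical coupling: the normalised myofilament force
#' over one pacing period is mapped linearly onto the ventricular
#' elastance, `E(t) = E_min + (E_max - E_min) * F(t) / F_ref`. `F_ref` is
#' fixed once, at wild-type calibration, and reused for the mutant drives,
#' so weaker force produces proportionally weaker contraction.
#'
#' @param force_trace A `force_trace` spanning (at least) one period, or a
#'   data frame with `t` and `F_active`.
#' @param period Pacing period, ms.
#' @param params [circulation_parameters()]; its `F_ref` must be set (use
#'   the peak WT force).
#' @param n_periods Number of periods to tile (periodic drive), or `NULL`
#'   to use the trace once, untiled (irregular reentrant drive).
#' @param e_dt Sampling interval of the returned waveform, ms.
#' @return Tibble `t`, `E_lv`, `E_rv` sampled at `e_dt`.
#' @export
tension_to_elastance <- function(force_trace, period, params, n_periods = 1,
                                 e_dt = 1) {
  if (is.na(params$F_ref)) {
    stop("F_ref is not set; calibrate with the wild-type force peak first",
         call. = FALSE)
  }
  tt <- force_trace$t - min(force_trace$t)
  ff <- pmax(force_trace$F_active, 0)
  if (!is.null(n_periods)) {
    if (max(tt) < period - e_dt) {
      stop("force trace shorter than one period", call. = FALSE)
    }
    t_one <- seq(0, period, by = e_dt)
    f_one <- stats::approx(tt, ff, xout = pmin(t_one, max(tt)),
                           rule = 2)$y
    f_one[length(f_one)] <- f_one[1] # periodic closure
    f_all <- rep(f_one[-length(f_one)], n_periods)
    f_all <- c(f_all, f_one[1])
    t_all <- (seq_along(f_all) - 1) * e_dt
  } else {
    t_all <- seq(0, max(tt), by = e_dt)
    f_all <- stats::approx(tt, ff, xout = t_all, rule = 2)$y
  }
  act <- pmin(f_all / params$F_ref, 1.5)
  tibble::tibble(
    t = t_all,
    E_lv = params$E_min_lv + (params$E_max_lv - params$E_min_lv) * act,
    E_rv = params$E_min_rv + (params$E_max_rv - params$E_min_rv) * act)
}

#' Simulate the closed-loop circulation
#'
#' Forward-Euler update of the compliance-resistance network under the
#' given elastance waveforms. Volume is exchanged strictly pairwise, so
#' total blood volume is conserved to round-off; diode valves admit only
#' forward flow.
#'
#' @param elastance Tibble from [tension_to_elastance()] covering the whole
#'   run (`t`, `E_lv`, `E_rv` at uniform spacing).
#' @param params [circulation_parameters()].
#' @param duration Simulated time, ms; defaults to the elastance record.
#' @param dt Integration step, ms.
#' @param record_dt Output sampling, ms.
#' @param init_volumes Optional named initial compartment volumes, mL.
#' @return A `circulation_run` tibble: time, compartment pressures (mmHg),
#'   volumes (mL), total volume and valve flows (mL/s).
#' @export
simulate_circulation <- function(elastance, params, duration = NULL,
                                 dt = 0.25, record_dt = 1,
                                 init_volumes = NULL) {
  if (is.null(duration)) duration <- max(elastance$t)
  e_dt <- stats::median(diff(elastance$t))
  if (is.null(init_volumes)) {
    v0 <- params$network[paste0("V0_", c("lv", "la", "rv", "ra",
                                         "sa", "sv", "pa", "pv"))]
    spare <- params$total_volume - sum(v0)
    # distribute stressed volume with venous emphasis
    w <- c(lv = 0.035, la = 0.02, rv = 0.035, ra = 0.02,
           sa = 0.10, sv = 0.62, pa = 0.045, pv = 0.125)
    init_volumes <- v0 + spare * w
  }
  res <- cpp_run_circulation(as.numeric(init_volumes),
                             as.numeric(params$network),
                             elastance$E_lv, elastance$E_rv, e_dt,
                             duration, dt, record_dt)
  tr <- tibble::as_tibble(as.data.frame(res$trace))
  structure(tr, class = c("circulation_run", class(tr)),
            params = params, dt = dt,
            final_volumes = as.numeric(res$final_volumes))
}

#' Stroke work from a pressure-volume loop
#'
#' Loop area by the shoelace formula on the (V, P) polygon of one beat, or
#' by trapezoidal integration of P dV against the time parametrisation;
#' the two agree for a closed loop and serve as mutual checks.
#'
#' @param v,p Volume (mL) and pressure (mmHg) samples of one closed beat.
#' @param method `"shoelace"` or `"trapezoid"`.
#' @return Stroke work in mmHg*mL (positive for a counter-clockwise pumping
#'   loop in the V-P plane).
#' @export
stroke_work <- function(v, p, method = c("shoelace", "trapezoid")) {
  method <- match.arg(method)
  n <- length(v)
  stopifnot(length(p) == n, n >= 3)
  if (method == "shoelace") {
    j <- c(2:n, 1)
    0.5 * abs(sum(v * p[j] - v[j] * p))
  } else {
    j <- c(2:n, 1)
    abs(sum((p + p[j]) / 2 * (v[j] - v)))
  }
}

#' Pressure-volume loop metrics of a settled run
#'
#' Metrics of the final beat of a circulation run: end-diastolic and
#' end-systolic volume, stroke volume, ejection fraction, stroke work
#' (loop area), cardiac output at the pacing rate, and - when a force
#' trace is supplied - the beat-averaged ATP consumption rate of the
#' driving myofilament and the stroke-work/ATP ratio.
#'
#' @param run A `circulation_run`.
#' @param bcl Pacing period, ms.
#' @param force_trace Optional `force_trace` of the driving beat (for ATP).
#' @param require_settled Error if stroke volume still drifts more than 1%
#'   between the last two beats.
#' @return One-row `pv_loop_metrics` tibble.
#' @export
pv_metrics <- function(run, bcl, force_trace = NULL,
                       require_settled = TRUE) {
  t_end <- max(run$t)
  n_beats <- floor(t_end / bcl)
  if (n_beats < 3) stop("need at least 3 beats", call. = FALSE)
  beat_window <- function(k) {
    run[run$t > (k - 1) * bcl & run$t <= k * bcl, ]
  }
  sv_of <- function(b) max(b$V_lv) - min(b$V_lv)
  last <- beat_window(n_beats)
  prev <- beat_window(n_beats - 1)
  sv <- sv_of(last)
  drift <- abs(sv - sv_of(prev)) / max(sv, 1e-9)
  if (require_settled && drift > 0.01 && sv > 0.5) {
    stop("run not converged: stroke volume drift ",
         signif(100 * drift, 3), "% between final beats", call. = FALSE)
  }
  edv <- max(last$V_lv)
  esv <- min(last$V_lv)
  sw <- stroke_work(last$V_lv, last$P_lv)
  atp <- if (!is.null(force_trace)) {
    atp_rate(force_trace, window = c(max(force_trace$t) - bcl,
                                     max(force_trace$t)))
  } else {
    NA_real_
  }
  tibble::new_tibble(
    tibble::tibble(
      EDV = edv, ESV = esv, SV = edv - esv, EF = 100 * (edv - esv) / edv,
      SW = sw, CO = (edv - esv) * 60000 / bcl,
      peak_P_lv = max(last$P_lv), ATP = atp,
      SW_ATP = if (is.na(atp) || atp == 0) NA_real_ else sw / atp),
    class = "pv_loop_metrics")
}
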