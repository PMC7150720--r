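#' Default tissue diffusion coefficient
#'
#' Isotropic monodomain diffusion coefficient `D = 1/(rho * S * C_m)` in
#' cm^2/ms, calibrated once on a 1D epicardial cable (node spacing 0.025
#' cm, step 0.02 ms) so that a planar wild-type wave propagates at the
#' normal conduction velocity of 70 cm/s, then held fixed across mutation
#' conditions. `low_cv` gives the reduced-excitability medium used for
#' reentry initiation, calibrated the same way to about 22 cm/s.
#'
#' @name diffusion-defaults
#' @aliases D_NORMAL D_LOW_CV
#' @export D_NORMAL D_LOW_CV
NULL

# calibrated on the WT epicardial cable; see the methods vignette
D_NORMAL <- 0.00154
D_LOW_CV <- 0.00025

#' Build a tissue grid
#'
#' A 1D cable (or closed ring) or 2D sheet of ventricular myocytes coupled
#' by isotropic monodomain diffusion, with per-node transmural cell type
#' and mutation condition.
#'
#' @param nx,ny Grid dimensions (nodes); `ny = 1` gives a cable.
#' @param dx Node spacing, cm.
#' @param D Diffusion coefficient, cm^2/ms (see [diffusion-defaults]).
#' @param cell_types Per-node cell type (`"endo"`, `"mid"`, `"epi"`),
#'   recycled to `nx * ny`.
#' @param conditions Per-node mutation condition label, recycled.
#' @param periodic Close the cable into a ring (1D only).
#' @return A `tissue_grid` object.
#' @export
tissue_grid <- function(nx, ny = 1, dx = 0.025, D = D_NORMAL,
                        cell_types = "epi", conditions = "WT",
                        periodic = FALSE) {
  stopifnot(nx >= 3, ny >= 1, dx > 0, D >= 0)
  if (periodic && ny != 1) stop("periodic grids must be 1D", call. = FALSE)
  n <- nx * ny
  ct <- vapply(rep_len(cell_types, n), cell_type_code, integer(1))
  cond <- vapply(rep_len(conditions, n),
                 function(x) mutation_condition(x)$code, integer(1))
  states <- matrix(rep(cpp_default_state(), each = n), nrow = n)
  structure(
    list(nx = nx, ny = ny, dx = dx, D = D, periodic = periodic,
         cell_types = ct, conditions = cond, states = states, cuts = NULL),
    class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid> ", x$nx, if (x$ny > 1) paste0(" x ", x$ny) else
      if (x$periodic) " (ring)" else " (cable)",
      " nodes, dx ", x$dx, " cm, D ", signif(x$D, 4), " cm^2/ms\n", sep = "")
  invisible(x)
}

#' Transmural cable
#'
#' A 1D strand spanning the ventricular wall: an endocardial zone at one
#' end and an epicardial zone at the other (2 mm each, following the
#' transmural layout of the source anatomy), midmyocardium between.
#'
#' @param length_cm Cable length, cm.
#' @param endo_mm,epi_mm Thickness of the subendocardial and subepicardial
#'   zones, mm.
#' @inheritParams tissue_grid
#' @param condition Mutation condition for every node.
#' @return A `tissue_grid`.
#' @export
transmural_cable <- function(length_cm = 1.5, dx = 0.025, D = D_NORMAL,
                             condition = "WT", endo_mm = 2, epi_mm = 2) {
  nx <- round(length_cm / dx) + 1
  x_cm <- (seq_len(nx) - 1) * dx
  ct <- ifelse(x_cm <= endo_mm / 10, "endo",
               ifelse(x_cm >= length_cm - epi_mm / 10, "epi", "mid"))
  tissue_grid(nx, 1, dx, D, cell_types = ct, conditions = condition)
}

#' Closed 1D ring
#'
#' Periodic cable supporting anatomical reentry: a wave started
#' unidirectionally circulates indefinitely while its wavelength is shorter
#' than the circumference.
#'
#' @param circumference_cm Ring length, cm.
#' @inheritParams transmural_cable
#' @param cell_type Cell type for every node.
#' @return A `tissue_grid` with `periodic = TRUE`.
#' @export
ring_grid <- function(circumference_cm = 7, dx = 0.025, D = D_LOW_CV,
                      condition = "WT", cell_type = "epi") {
  nx <- round(circumference_cm / dx)
  tissue_grid(nx, 1, dx, D, cell_types = cell_type, conditions = condition,
              periodic = TRUE)
}

#' Simulate a tissue grid
#'
#' Explicit finite-difference monodomain integration with no-flux (or
#' periodic) boundaries: per-node ionic reaction (shared with the
#' single-cell integrator) plus voltage diffusion, under a schedule of
#' regional stimuli. The explicit-diffusion stability bound
#' `dt <= dx^2 / (2 * n_dim * D)` is asserted before the run starts.
#'
#' @param grid A [tissue_grid()].
#' @param duration Simulated time, ms.
#' @param stimuli Data frame with columns `t_on`, `dur`, `amp` and a
#'   list-column `nodes` of 1-based node indices.
#' @param dt Integration step, ms.
#' @param probes Node indices (1-based) whose voltage is recorded densely.
#' @param probe_dt,frame_dt Sampling intervals for probes and whole-field
#'   frames, ms.
#' @param map_window `c(t0, t1)` window in which per-node first activation
#'   (EAT) and repolarisation (EDT) times are collected.
#' @param threshold Activation threshold, mV.
#' @return A `tissue_run` object (list) with probe traces, frames, EAT/EDT
#'   vectors, per-node activation counts, excited-node counts per frame and
#'   the final states.
#' @export
simulate_tissue <- function(grid, duration, stimuli, dt = 0.02,
                            probes = integer(), probe_dt = 0.5,
                            frame_dt = 5, map_window = c(0, duration),
                            threshold = -40) {
  ndim <- if (grid$ny > 1) 2 else 1
  if (grid$D > 0 && dt > grid$dx^2 / (2 * ndim * grid$D)) {
    stop("explicit diffusion unstable: need dt <= ",
         signif(grid$dx^2 / (2 * ndim * grid$D), 3), " ms for dx = ",
         grid$dx, ", D = ", grid$D, call. = FALSE)
  }
  if (is.null(stimuli) || !nrow(stimuli)) {
    stimuli <- tibble::tibble(t_on = numeric(), dur = numeric(),
                              amp = numeric(), nodes = list())
  }
  pmat <- rbind(cell_parameters("endo"), cell_parameters("mid"),
                cell_parameters("epi"))
  scales <- vapply(0:2, ik1_conductance_scale, numeric(1))
  states <- grid$states
  if (!is.null(grid$cuts)) attr(states, "cuts") <- grid$cuts
  res <- cpp_run_tissue(
    states, pmat, grid$cell_types, grid$conditions, scales,
    grid$nx, grid$ny, grid$dx, grid$D, grid$periodic, duration, dt,
    stimuli$t_on, stimuli$dur, stimuli$amp,
    lapply(stimuli$nodes, function(x) as.integer(x) - 1L),
    as.integer(probes) - 1L, probe_dt, frame_dt,
    map_window[1], map_window[2], threshold)
  pm <- res$probe_v
  cm <- res$probe_ca
  colnames(pm) <- colnames(cm) <-
    c("t", paste0("node_", probes, recycle0 = TRUE))
  probe_tbl <- tibble::as_tibble(as.data.frame(pm))
  probe_ca_tbl <- tibble::as_tibble(as.data.frame(cm))
  structure(
    list(grid = grid, duration = duration, dt = dt, stimuli = stimuli,
         probes = probes, probe_v = probe_tbl, probe_ca = probe_ca_tbl,
         frames = res$frames, frame_t = as.numeric(res$frame_t),
         excited = as.numeric(res$excited),
         eat = as.numeric(res$eat), edt = as.numeric(res$edt),
         n_activations = as.integer(res$n_activations),
         last_activation = as.numeric(res$last_activation),
         final_states = res$final_states, threshold = threshold),
    class = "tissue_run")
}

#' @export
print.tissue_run <- function(x, ...) {
  cat("<tissue_run> ", x$grid$nx * x$grid$ny, " nodes, ", x$duration,
      " ms, ", nrow(x$stimuli), " stimuli\n", sep = "")
  invisible(x)
}

#' Conduction velocity between two probe positions
#'
#' Velocity of a planar wave from the difference in first-activation times
#' between two nodes a known distance apart. Probes should sit away from
#' the stimulated edge and the far boundary.
#'
#' @param run A `tissue_run` of a cable.
#' @param from,to Node indices (1-based).
#' @return Conduction velocity in cm/s. Errors with a propagation-failure
#'   message if either node never activated.
#' @export
measure_cv <- function(run, from, to) {
  eat <- run$eat
  if (is.na(eat[from]) || is.na(eat[to])) {
    stop("propagation failure: wave did not reach both probes",
         call. = FALSE)
  }
  d_cm <- abs(to - from) * run$grid$dx
  dt_ms <- abs(eat[to] - eat[from])
  if (dt_ms <= 0) stop("probes activated simultaneously", call. = FALSE)
  1000 * d_cm / dt_ms
}

#' Activation and deactivation maps
#'
#' Per-node electrical activation time (first upstroke crossing of the
#' activation threshold) and deactivation time (90%-repolarisation level
#' of that activation), plus the map summaries: the QRS-width surrogate
#' `max(EAT) - min(EAT)` and the QT-interval surrogate
#' `max(EDT) - min(EAT)`.
#'
#' @param run A `tissue_run` whose `map_window` covered one paced beat.
#' @return An `activation_maps` tibble (`node`, `x_cm`, `y_cm`, `eat`,
#'   `edt`) with attributes `qrs`, `qt`, `n_unactivated`. A warning is
#'   emitted if any node never activated; such nodes are excluded from the
#'   summaries.
#' @export
activation_maps <- function(run) {
  g <- run$grid
  n <- g$nx * g$ny
  node <- seq_len(n)
  x_cm <- ((node - 1) %% g$nx) * g$dx
  y_cm <- ((node - 1) %/% g$nx) * g$dx
  eat <- run$eat
  edt <- run$edt
  n_un <- sum(is.na(eat))
  if (n_un > 0) {
    warning(n_un, " node(s) never activated; excluded from map summaries")
  }
  ok <- !is.na(eat) & !is.na(edt)
  qrs <- max(eat[!is.na(eat)]) - min(eat[!is.na(eat)])
  qt <- max(edt[ok]) - min(eat[!is.na(eat)])
  structure(
    tibble::tibble(node = node, x_cm = x_cm, y_cm = y_cm, eat = eat,
                   edt = edt),
    class = c("activation_maps", "tbl_df", "tbl", "data.frame"),
    qrs = qrs, qt = qt, n_unactivated = n_un)
}

#' Cross-field S1-S2 spiral wave induction
#'
#' Standard two-pulse protocol on a 2D sheet: a planar S1 wave is launched
#' from the left edge; a premature S2 is delivered to the lower-left
#' quadrant while the S1 repolarisation tail crosses the sheet, producing
#' unidirectional block and (for suitably timed S2) a rotating spiral.
#'
#' @param sheet A 2D [tissue_grid()].
#' @param s2_time S2 onset, ms after the S1 at t = 0.
#' @param duration Total simulated time, ms.
#' @param persist_ms Reentry criterion: activity must persist this long
#'   after the S2 for the run to be flagged reentrant.
#' @param stim_amp Stimulus amplitude, pA/pF.
#' @param ... Passed to [simulate_tissue()].
#' @return A `tissue_run` with extra fields `reentrant` (logical) and
#'   `s2_time`.
#' @export
induce_spiral <- function(sheet, s2_time, duration = s2_time + 1200,
                          persist_ms = 1000, stim_amp = -52, ...) {
  stopifnot(sheet$ny > 1)
  nx <- sheet$nx
  ny <- sheet$ny
  left_edge <- as.integer(outer(1:2, (0:(ny - 1)) * nx, `+`))
  quad <- as.integer(outer(1:(nx %/% 2), (0:(ny %/% 2 - 1)) * nx, `+`))
  stimuli <- tibble::tibble(
    t_on = c(0, s2_time), dur = c(1, 2), amp = c(stim_amp, stim_amp),
    nodes = list(left_edge, quad))
  run <- simulate_tissue(sheet, duration, stimuli, ...)
  run$reentrant <- is_sustained(run, after = s2_time + persist_ms)
  run$s2_time <- s2_time
  run
}

# activity persisting to (at least) time `after`
is_sustained <- function(run, after) {
  any(run$excited[run$frame_t >= after] > 0) &&
    max(run$last_activation, na.rm = TRUE) >= after
}

#' Anatomical reentry on a ring
#'
#' Starts a unidirectional wave on a closed 1D ring by stimulating one
#' site while conduction across a neighbouring edge is transiently blocked
#' (the block is released once the antidromic direction is refractory),
#' then lets the wave circulate.
#'
#' @param ring A periodic [tissue_grid()] from [ring_grid()].
#' @param duration Simulated time, ms.
#' @param block_ms How long the initiation block stays closed, ms.
#' @param ... Passed to [simulate_tissue()]; probes default to four
#'   equally spaced nodes.
#' @return A `tissue_run` with field `reentrant`.
#' @export
ring_reentry <- function(ring, duration = 3000, block_ms = 250, ...) {
  stopifnot(isTRUE(ring$periodic))
  n <- ring$nx
  ring$cuts <- matrix(c(0, n - 1, block_ms), nrow = 1)
  stimuli <- tibble::tibble(t_on = 0, dur = 1, amp = -52,
                            nodes = list(1:4))
  args <- list(...)
  if (is.null(args$probes)) {
    args$probes <- unique(pmax(1L, as.integer(round(
      seq(1, n, length.out = 5)[1:4]))))
  }
  run <- do.call(simulate_tissue,
                 c(list(grid = ring, duration = duration,
                        stimuli = stimuli), args))
  run$reentrant <- is_sustained(run, after = duration - 50)
  run
}

#' Reentry wavelength, two estimators
#'
#' For a sustained reentrant run the conduction wavelength is estimated two
#' ways and both are reported: (i) local conduction velocity times local
#' APD measured at probe nodes, and (ii) the excited arc length - the mean
#' fraction of tissue above the excitation threshold times the path length.
#'
#' @param run A reentrant `tissue_run` on a ring (1D periodic grid).
#' @param window Analysis window `c(t0, t1)`, ms; defaults to the second
#'   half of the run.
#' @param threshold Excitation threshold for the arc estimator, mV.
#' @return One-row tibble: `wl_cv_apd`, `wl_arc` (cm), plus the ingredients
#'   `cv` (cm/s), `apd` (ms), `period` (ms).
#' @export
reentry_wavelength <- function(run, window = NULL, threshold = -60) {
  if (!isTRUE(run$reentrant)) {
    stop("run is not sustained reentry; wavelength undefined",
         call. = FALSE)
  }
  g <- run$grid
  if (g$ny != 1 || !g$periodic) {
    stop("wavelength estimators are defined for ring runs", call. = FALSE)
  }
  if (is.null(window)) window <- c(run$duration / 2, run$duration)
  circumference <- g$nx * g$dx

  # estimator (ii): excited arc
  frames <- run$frames
  sel <- run$frame_t >= window[1] & run$frame_t <= window[2]
  frac <- rowMeans(frames[sel, , drop = FALSE] > threshold)
  wl_arc <- mean(frac) * circumference

  # estimator (i): CV x APD at the probes
  pv <- run$probe_v
  pv <- pv[pv$t >= window[1] & pv$t <= window[2], ]
  probe_cols <- setdiff(names(pv), "t")
  acts <- lapply(probe_cols, function(cl) upstroke_times(pv$t, pv[[cl]]))
  period <- stats::median(unlist(lapply(acts, diff)))
  # lap time over the full circumference gives the mean CV
  cv <- 1000 * circumference / period
  apds <- unlist(lapply(probe_cols, function(cl) {
    m <- measure_apd(data.frame(t = pv$t, V = pv[[cl]]))
    m$apd[!is.na(m$apd)]
  }))
  apd <- stats::median(apds)
  tibble::tibble(wl_cv_apd = cv * apd / 1000, wl_arc = wl_arc,
                 cv = cv, apd = apd, period = period)
}

#' Dominant activation period at a probe
#'
#' Median interval between successive upstrokes at a probe node; the
#' rotation period of a sustained reentrant wave.
#'
#' @param run A `tissue_run` with probes.
#' @param window Analysis window, ms.
#' @return Period in ms (`NA` if fewer than two activations).
#' @export
dominant_period <- function(run, window = NULL) {
  pv <- run$probe_v
  if (!is.null(window)) pv <- pv[pv$t >= window[1] & pv$t <= window[2], ]
  probe_cols <- setdiff(names(pv), "t")
  iv <- unlist(lapply(probe_cols, function(cl) {
    diff(upstroke_times(pv$t, pv[[cl]]))
  }))
  if (!length(iv)) return(NA_real_)
  stats::median(iv)
}
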