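the <- new.env(parent = emptyenv())

#' Steady-beat calcium transient of a paced cell
#'
#' Paces a cell with the sinus protocol and returns the cytosolic calcium
#' of the final beat, time-referenced to the stimulus.
#'
#' @inheritParams pace_to_steady_state
#' @return Tibble `t` (0..bcl ms), `Ca_i` (mM).
#' @export
sinus_ca_transient <- function(condition = "WT", cell_type = "endo",
                               bcl = 600, n_beats = 10) {
  key <- paste("ca", condition, cell_type, bcl, n_beats, sep = "|")
  if (!is.null(the[[key]])) return(the[[key]])
  tr <- pace_to_steady_state(cell_type, condition, bcl = bcl,
                             n_beats = n_beats, record_beats = 1)
  t0 <- attr(tr, "stim_times")[1]
  out <- tibble::tibble(t = tr$t - t0, Ca_i = tr$Ca_i)
  the[[key]] <- out
  out
}

#' Steady-state active-force beat for a condition
#'
#' Runs the paced-cell calcium transient through the myofilament model for
#' several beats (to cross-bridge steady state) and returns the final
#' beat's force trace.
#'
#' @inheritParams sinus_ca_transient
#' @param myo_beats Myofilament equilibration beats.
#' @return A `force_trace` covering one beat (t in 0..bcl).
#' @export
sinus_force <- function(condition = "WT", cell_type = "endo", bcl = 600,
                        n_beats = 10, myo_beats = 8) {
  key <- paste("force", condition, cell_type, bcl, n_beats, myo_beats,
               sep = "|")
  if (!is.null(the[[key]])) return(the[[key]])
  ca <- sinus_ca_transient(condition, cell_type, bcl, n_beats)
  ca_tiled <- tibble::tibble(
    t = rep(seq_len(myo_beats) - 1, each = nrow(ca)) * bcl + rep(ca$t,
                                                                 myo_beats),
    Ca_i = rep(ca$Ca_i, myo_beats))
  ca_tiled <- ca_tiled[!duplicated(ca_tiled$t), ]
  ft <- simulate_myofilament(ca_tiled, duration = myo_beats * bcl,
                             record_dt = 1)
  last <- ft[ft$t >= (myo_beats - 1) * bcl, ]
  last$t <- last$t - (myo_beats - 1) * bcl
  out <- structure(last, class = class(ft),
                   final_state = attr(ft, "final_state"),
                   params = attr(ft, "params"))
  the[[key]] <- out
  out
}

#' Wild-type force normalisation for the elastance drive
#'
#' Peak of the wild-type endocardial steady-beat force at BCL 600 ms; the
#' fixed reference `F_ref` against which every condition's force is scaled
#' into elastance (one-time calibration, frozen across conditions).
#'
#' @return Peak normalised force (dimensionless).
#' @export
wt_force_reference <- function() {
  if (is.null(the$f_ref)) the$f_ref <- max(sinus_force("WT")$F_active)
  the$f_ref
}

#' Full electromechanical pump run for one condition
#'
#' The complete one-way coupling chain: paced-cell calcium, myofilament
#' force, elastance drive, closed-loop circulation, pressure-volume
#' metrics. Circulation parameters are identical across conditions; only
#' the force drive differs.
#'
#' The comparison design is acute onset: the circulation is first settled
#' under the wild-type drive (30 beats), and every condition - including
#' wild type - is then run for `n_beats` beats (default 10, i.e. 6 s at
#' BCL 600 ms, the length of the reference sinus protocol) from those
#' settled volumes, with metrics taken from the final beat. A
#' non-contracting ventricle therefore congests at its pre-failure filling
#' pressures rather than draining to the stagnation equilibrium, which is
#' what shifts the mutant pressure-volume loops rightward.
#'
#' @param condition Mutation condition.
#' @param n_beats Circulation beats after the wild-type settling phase.
#' @param bcl Pacing period, ms.
#' @param params [circulation_parameters()].
#' @param force Optional pre-computed driving `force_trace` (one beat); by
#'   default the condition's sinus beat.
#' @return List with `force`, `elastance`, `run` (`circulation_run`) and
#'   `metrics` ([pv_metrics()] row).
#' @export
simulate_pump <- function(condition = "WT", n_beats = 10, bcl = 600,
                          params = circulation_parameters(),
                          force = NULL) {
  if (is.null(force)) force <- sinus_force(condition, bcl = bcl)
  if (is.na(params$F_ref)) params$F_ref <- wt_force_reference()
  vols <- wt_settled_volumes(params, bcl)
  ela <- tension_to_elastance(force, period = bcl, params = params,
                              n_periods = n_beats)
  run <- simulate_circulation(ela, params, init_volumes = vols)
  metrics <- pv_metrics(run, bcl = bcl, force_trace = force,
                        require_settled = FALSE)
  list(force = force, elastance = ela, run = run, metrics = metrics,
       condition = mutation_condition(condition)$label)
}

# circulation volumes after 30 wild-type beats (common initial condition
# for the acute-onset comparison); memoised per parameter set
wt_settled_volumes <- function(params, bcl = 600) {
  key <- paste0("vols|", rlang::hash(params), "|", bcl)
  if (!is.null(the[[key]])) return(the[[key]])
  f_wt <- sinus_force("WT", bcl = bcl)
  ela <- tension_to_elastance(f_wt, period = bcl, params = params,
                              n_periods = 30)
  run <- simulate_circulation(ela, params)
  the[[key]] <- attr(run, "final_volumes")
  the[[key]]
}

#' Hemodynamic response to a reentrant drive
#'
#' Couples the calcium recorded at a probe node of a sustained ring-reentry
#' run into the myofilament and circulation stages, using the same frozen
#' circulation parameters and wild-type-settled initial volumes as the
#' sinus pump runs. The reentrant drive is fast and weak, so the left
#' ventricle barely cycles; its pressure fluctuation is compared against
#' the sinus drive of the same condition.
#'
#' @param condition Mutation condition.
#' @param ring_run Optional pre-computed reentrant `tissue_run`; by default
#'   the condition's ring-reentry scenario (3 s, 7 cm ring, low-CV medium).
#' @param params [circulation_parameters()].
#' @param settle_ms Leading portion of the calcium record used only to
#'   equilibrate the myofilament, ms.
#' @return List with `force`, `run`, `fluctuation` (max - min LV pressure
#'   over the final 1200 ms) and `sinus_fluctuation` (same measure under
#'   the condition's sinus drive).
#' @export
simulate_reentry_pump <- function(condition = "WT", ring_run = NULL,
                                  params = circulation_parameters(),
                                  settle_ms = 600) {
  if (is.null(ring_run)) {
    # fibrillatory activation is refractoriness-limited: per condition, the
    # drive comes from the tightest ring that still sustains circulation
    spec <- switch(mutation_condition(condition)$label,
                   WT = c(5, 320), WT_E299V = c(3.5, 135),
                   E299V = c(2.5, 85))
    key <- paste0("tightring|", mutation_condition(condition)$label)
    if (is.null(the[[key]])) {
      ring <- ring_grid(spec[1], 0.025, condition = condition)
      n <- ring$nx
      the[[key]] <- ring_reentry(ring, duration = 3000, block_ms = spec[2],
                                 probes = unique(as.integer(round(
                                   seq(1, n, length.out = 13)[1:12]))))
    }
    ring_run <- the[[key]]
  }
  # the reentrant wave activates different regions at different phases;
  # the chamber-level drive is the spatial mean of the regional forces
  pv <- ring_run$probe_ca
  probe_cols <- setdiff(names(pv), "t")
  forces <- lapply(probe_cols, function(cl) {
    simulate_myofilament(tibble::tibble(t = pv$t, Ca_i = pv[[cl]]),
                         record_dt = 1)$F_active
  })
  ft <- tibble::tibble(t = seq(0, by = 1, length.out = length(forces[[1]])),
                       F_active = Reduce(`+`, forces) / length(forces))
  ft <- ft[ft$t >= settle_ms, ]
  if (is.na(params$F_ref)) params$F_ref <- wt_force_reference()
  ela <- tension_to_elastance(ft, period = NA, params = params,
                              n_periods = NULL)
  run <- simulate_circulation(ela, params,
                              init_volumes = wt_settled_volumes(params))
  win <- c(max(run$t) - 1200, max(run$t))
  flu <- pressure_range(run, win)
  sinus <- simulate_pump(condition, params = params)
  flu_sinus <- pressure_range(sinus$run,
                              c(max(sinus$run$t) - 1200, max(sinus$run$t)))
  list(force = ft, run = run, fluctuation = flu,
       sinus_fluctuation = flu_sinus,
       condition = mutation_condition(condition)$label)
}

#' Left-ventricular pressure excursion in a window
#'
#' @param run A `circulation_run`.
#' @param window `c(t0, t1)`, ms.
#' @return `max(P_lv) - min(P_lv)` over the window, mmHg.
#' @export
pressure_range <- function(run, window) {
  x <- run$P_lv[run$t >= window[1] & run$t <= window[2]]
  max(x) - min(x)
}

#' Execute a scenario and collect its report
#'
#' Runs the pipeline stages required by a [make_scenario()] configuration
#' and returns a structured report of the headline metrics. When
#' `out_dir` is given, the configuration snapshot (JSON), the raw traces
#' (CSV) and the report (JSON) are written there, one directory per run.
#'
#' @param scenario A `scenario` or a scenario name.
#' @param out_dir Optional output directory.
#' @return A `run_report`: list with `name`, `condition`, `metrics`
#'   (named list), `config_hash`, `version`, and `files` written.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "scenario"))
  set.seed(scenario$seed)
  p <- scenario$protocol
  traces <- list()
  metrics <- switch(scenario$kind,
    sinus = {
      tr <- pace_to_steady_state(scenario$cell_type, scenario$condition,
                                 bcl = p$bcl, n_beats = p$n_beats,
                                 dt = p$dt, record_dt = p$record_dt)
      traces$trace <- tibble::as_tibble(tr)
      last <- tr[tr$t >= max(attr(tr, "stim_times")), ]
      list(apd90 = final_apd(tr), peak_ik1 = max(last$I_K1),
           v_rest = tr$V[1], ca_peak = max(last$Ca_i))
    },
    restitution = {
      per_ct <- lapply(scenario_cell_types, function(ct) {
        cur <- dynamic_restitution(
          ct, scenario$condition,
          bcl_start = if (ct == "mid") p$bcl_start_mid else p$bcl_start,
          bcl_stop = p$bcl_stop, bcl_step = p$bcl_step,
          n_equil = p$n_equil, n_measure = p$n_measure,
          alternans_threshold = p$alternans_threshold, dt = p$dt)
        traces[[paste0("curve_", ct)]] <<- tibble::as_tibble(cur)
        list(onset = detect_alternans(cur,
                                      threshold = p$alternans_threshold),
             max_slope = max(cur$slope, na.rm = TRUE))
      })
      names(per_ct) <- scenario_cell_types
      list(alternans_onset = lapply(per_ct, `[[`, "onset"),
           max_slope = lapply(per_ct, `[[`, "max_slope"))
    },
    cable = {
      cable <- transmural_cable(p$length_cm, p$dx, p$D, scenario$condition)
      nx <- cable$nx
      stimuli <- tibble::tibble(t_on = (seq_len(p$n_beats) - 1) * p$bcl,
                                dur = 1, amp = -52, nodes = list(1:2))
      run <- simulate_tissue(cable, p$n_beats * p$bcl, stimuli, dt = p$dt,
                             probes = c(round(nx / 3), round(2 * nx / 3)),
                             map_window = c((p$n_beats - 1) * p$bcl,
                                            p$n_beats * p$bcl))
      maps <- activation_maps(run)
      traces$maps <- tibble::as_tibble(maps)
      list(cv = measure_cv(run, round(nx / 3), round(2 * nx / 3)),
           qrs = attr(maps, "qrs"), qt = attr(maps, "qt"))
    },
    reentry = {
      ring <- ring_grid(p$circumference_cm, p$dx, p$D, scenario$condition)
      run <- ring_reentry(ring, duration = p$duration,
                          block_ms = p$block_ms, dt = p$dt)
      wl <- reentry_wavelength(run)
      traces$wavelength <- wl
      c(list(reentrant = run$reentrant), as.list(wl))
    },
    pump = {
      pump <- simulate_pump(scenario$condition, n_beats = p$n_beats,
                            bcl = p$bcl)
      traces$pv <- pump$run[, c("t", "P_lv", "V_lv", "P_sa")]
      as.list(pump$metrics)
    })
  report <- structure(
    list(name = scenario$name, condition = scenario$condition,
         kind = scenario$kind, metrics = metrics,
         config_hash = rlang::hash(scenario),
         version = as.character(utils::packageVersion("cardioem")),
         files = character()),
    class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- file.path(out_dir, "scenario.json")
    writeLines(scenario_to_json(scenario), cfg)
    files <- cfg
    for (nm in names(traces)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(traces[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    rep_file <- file.path(out_dir, "report.json")
    writeLines(jsonlite::toJSON(report[c("name", "condition", "kind",
                                         "metrics", "config_hash",
                                         "version")],
                                auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null"), rep_file)
    report$files <- c(files, rep_file)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$name, " (", x$condition, ")\n", sep = "")
  m <- x$metrics
  flat <- unlist(m)
  for (nm in names(flat)) {
    cat("  ", nm, ": ", format(flat[[nm]], digits = 5), "\n", sep = "")
  }
  invisible(x)
}

#' Reference-style pump comparison table
#'
#' Runs the three pump scenarios and tabulates the pressure-volume metrics
#' side by side, one row per condition, mirroring the study's summary
#' table of mechanical responses.
#'
#' @param n_beats Circulation beats per condition.
#' @return Tibble with one row per condition.
#' @export
pump_comparison <- function(n_beats = 10) {
  rows <- lapply(scenario_conditions, function(cond) {
    m <- simulate_pump(cond, n_beats = n_beats)$metrics
    dplyr::bind_cols(tibble::tibble(condition = cond), m)
  })
  dplyr::bind_rows(rows)
}
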