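#' Pace a cell to steady state at fixed cycle length
#'
#' Sinus-rhythm style pacing with square stimulus pulses at a fixed basic
#' cycle length. The default protocol paces for 10 beats at BCL 600 ms
#' (6 s of simulated time, the sinus protocol of the study design) and
#' retains the final two beats of the trace for measurement. One-to-one
#' capture is verified: every stimulus must elicit exactly one upstroke.
#'
#' @param cell_type `"endo"`, `"mid"` or `"epi"`.
#' @param condition Mutation condition.
#' @param bcl Basic cycle length, ms.
#' @param n_beats Number of paced beats (at least 2).
#' @param record_beats How many final beats to retain in the trace.
#' @param dt Integration step, ms.
#' @param record_dt Output sampling interval, ms.
#' @param record_currents Store all membrane currents.
#' @param cell Optional pre-built cell (state carried over from a previous
#'   protocol stage); defaults to a fresh resting cell.
#' @return A `paced_trace` tibble (see [simulate_cell()]) whose
#'   `stim_times` attribute contains only the retained beats.
#' @examples
#' \donttest{
#' tr <- pace_to_steady_state("epi", "E299V", n_beats = 4)
#' final_apd(tr)
#' }
#' @export
pace_to_steady_state <- function(cell_type = "endo", condition = "WT",
                                 bcl = 600, n_beats = 10, record_beats = 2,
                                 dt = 0.02, record_dt = 0.25,
                                 record_currents = FALSE, cell = NULL) {
  stopifnot(n_beats >= 2, record_beats >= 1, bcl > 0)
  if (is.null(cell)) cell <- make_cell(cell_type, condition)
  stim <- (seq_len(n_beats) - 1) * bcl
  record_from <- (n_beats - record_beats) * bcl
  tr <- simulate_cell(cell, duration = n_beats * bcl, stim_times = stim,
                      dt = dt, record_from = record_from,
                      record_dt = record_dt,
                      record_currents = record_currents)
  kept <- stim[stim >= record_from]
  attr(tr, "stim_times") <- kept
  attr(tr, "bcl") <- bcl
  attr(tr, "n_beats") <- n_beats
  m <- measure_apd(tr)
  n_expected <- length(kept)
  if (nrow(m) != n_expected) {
    stop("loss of 1:1 capture: ", nrow(m), " upstrokes for ", n_expected,
         " stimuli (failing beat index ",
         n_beats - record_beats + nrow(m) + 1, ")", call. = FALSE)
  }
  tr
}

#' Dynamic APD restitution curve
#'
#' Decremental pacing scan: the cell is conditioned at the sinus cycle
#' length, then paced at each BCL of the scan grid for `n_equil`
#' equilibration beats followed by `n_measure` measured beats, carrying the
#' state from one BCL to the next (the standard dynamic restitution
#' protocol). At each BCL the retained action potentials are summarised as
#' one APD record (or two when the response alternates); the diastolic
#' interval is BCL minus the preceding APD. The curve is truncated at loss
#' of capture (2:1 block) and the truncation is flagged.
#'
#' @inheritParams pace_to_steady_state
#' @param bcl_start,bcl_stop,bcl_step Scan grid, ms (descending from
#'   `bcl_start` to `bcl_stop` in steps of `bcl_step`).
#' @param n_equil Equilibration beats per BCL (not measured).
#' @param n_measure Measured beats per BCL.
#' @param conditioning_bcl,conditioning_beats Pre-scan conditioning.
#' @param alternans_threshold APD difference (ms) above which a sustained
#'   alternating pattern is classified as alternans.
#' @return A `restitution_curve` tibble with one row per BCL: `bcl`, `apd`
#'   (mean of the measured beats, or of the odd beats when alternating),
#'   `apd_alt` (even-beat APD when alternating, else `NA`), `di`, `alternans`
#'   (logical), `captured` (beats detected vs expected), and `slope`
#'   (d(APD)/d(DI) by central differences along the curve). Attributes:
#'   `protocol`, `cell_type`, `condition`, `truncated`, `apd_sequences`
#'   (list of per-BCL APD vectors, for [detect_alternans()]).
#' @export
dynamic_restitution <- function(cell_type = "endo", condition = "WT",
                                bcl_start = 400, bcl_stop = 200,
                                bcl_step = 10, n_equil = 30, n_measure = 8,
                                conditioning_bcl = 600,
                                conditioning_beats = 10,
                                alternans_threshold = 2, dt = 0.02,
                                record_dt = 0.5) {
  stopifnot(bcl_start > bcl_stop, bcl_step > 0, n_measure >= 4)
  cell <- make_cell(cell_type, condition)
  stim <- (seq_len(conditioning_beats) - 1) * conditioning_bcl
  tr <- simulate_cell(cell, conditioning_beats * conditioning_bcl, stim,
                      dt = dt, record_from = conditioning_beats *
                        conditioning_bcl, record_dt = record_dt)
  state <- attr(tr, "final_state")

  bcls <- seq(bcl_start, bcl_stop, by = -bcl_step)
  rows <- list()
  seqs <- list()
  truncated <- FALSE
  for (bcl in bcls) {
    nb <- n_equil + n_measure
    stim <- (seq_len(nb) - 1) * bcl
    cell$state <- state
    tr <- simulate_cell(cell, nb * bcl, stim, dt = dt,
                        record_from = (n_equil - 1) * bcl,
                        record_dt = record_dt)
    state <- attr(tr, "final_state")
    m <- measure_apd(tr)
    # drop the equilibration beat included for diastolic context and any
    # beat without a measurable APD
    apds <- m$apd[m$t_act >= n_equil * bcl - bcl / 2]
    apds <- apds[!is.na(apds)]
    seqs[[as.character(bcl)]] <- apds
    captured <- length(apds)
    if (captured < n_measure) {
      truncated <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        bcl = bcl, apd = NA_real_, apd_alt = NA_real_, di = NA_real_,
        alternans = NA, captured = captured)
      break
    }
    d <- diff(apds)
    alt <- alternating_pattern(apds, alternans_threshold)
    if (alt) {
      odd <- apds[seq(1, length(apds), by = 2)]
      even <- apds[seq(2, length(apds), by = 2)]
      apd1 <- mean(odd)
      apd2 <- mean(even)
    } else {
      apd1 <- mean(apds)
      apd2 <- NA_real_
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      bcl = bcl, apd = apd1, apd_alt = apd2,
      di = bcl - mean(apds), alternans = alt, captured = captured)
  }
  curve <- dplyr::bind_rows(rows)
  curve <- dplyr::arrange(curve, .data$bcl)
  ok <- !is.na(curve$apd)
  curve$slope <- NA_real_
  if (sum(ok) >= 3) {
    curve$slope[ok] <- restitution_slope(curve$di[ok], curve$apd[ok])
  }
  structure(curve,
            class = c("restitution_curve", class(curve)),
            protocol = "dynamic", cell_type = cell_type,
            condition = mutation_condition(condition)$label,
            truncated = truncated, apd_sequences = seqs,
            alternans_threshold = alternans_threshold)
}

# sustained alternation: last >= 4 inter-beat differences all exceed the
# threshold in magnitude with strictly alternating sign
alternating_pattern <- function(apds, threshold, n_required = 4) {
  d <- diff(apds)
  if (length(d) < n_required) return(FALSE)
  d <- utils::tail(d, n_required)
  all(abs(d) > threshold) && all(diff(sign(d)) != 0)
}

# d(APD)/d(DI) by central finite differences on an irregular grid
restitution_slope <- function(di, apd) {
  n <- length(di)
  slope <- rep(NA_real_, n)
  if (n < 2) return(slope)
  slope[1] <- (apd[2] - apd[1]) / (di[2] - di[1])
  slope[n] <- (apd[n] - apd[n - 1]) / (di[n] - di[n - 1])
  if (n > 2) {
    for (k in 2:(n - 1)) {
      slope[k] <- (apd[k + 1] - apd[k - 1]) / (di[k + 1] - di[k - 1])
    }
  }
  slope
}

#' S1-S2 restitution curve
#'
#' Standard-protocol variant: a train of S1 beats at fixed cycle length is
#' followed by a single premature S2; the S2 action potential duration is
#' plotted against its diastolic interval. Provided for completeness; the
#' dynamic protocol is the primary restitution measure here.
#'
#' @inheritParams pace_to_steady_state
#' @param s1_bcl S1 cycle length, ms.
#' @param n_s1 Number of S1 beats before each S2.
#' @param s2_intervals S1-S2 coupling intervals to scan, ms.
#' @return A `restitution_curve` tibble (protocol `"S1S2"`) with `bcl` the
#'   coupling interval.
#' @export
s1s2_restitution <- function(cell_type = "endo", condition = "WT",
                             s1_bcl = 600, n_s1 = 10,
                             s2_intervals = seq(600, 250, -25), dt = 0.02) {
  rows <- list()
  for (ci in s2_intervals) {
    cell <- make_cell(cell_type, condition)
    stim <- c((seq_len(n_s1) - 1) * s1_bcl, (n_s1 - 1) * s1_bcl + ci)
    tr <- simulate_cell(cell, (n_s1 - 1) * s1_bcl + ci + 1000, stim,
                        dt = dt, record_from = (n_s1 - 2) * s1_bcl,
                        record_dt = 0.5)
    m <- measure_apd(tr)
    if (nrow(m) < 3) next
    last <- m[nrow(m), ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      bcl = ci, apd = last$apd, apd_alt = NA_real_, di = last$di,
      alternans = FALSE, captured = 1L)
  }
  curve <- dplyr::arrange(dplyr::bind_rows(rows), .data$bcl)
  ok <- !is.na(curve$apd)
  curve$slope <- NA_real_
  if (sum(ok) >= 3) {
    curve$slope[ok] <- restitution_slope(curve$di[ok], curve$apd[ok])
  }
  structure(curve, class = c("restitution_curve", class(curve)),
            protocol = "S1S2", cell_type = cell_type,
            condition = mutation_condition(condition)$label,
            truncated = FALSE, apd_sequences = NULL,
            alternans_threshold = NA_real_)
}

#' Alternans onset in a restitution scan
#'
#' Scans the per-BCL APD sequences of a dynamic restitution curve from the
#' largest BCL downward and returns the largest BCL at which a sustained
#' alternating APD pattern (|APD_n - APD_(n-1)| above threshold with
#' alternating sign over at least four consecutive differences) is present.
#'
#' @param x A `restitution_curve` from [dynamic_restitution()], or a named
#'   list of per-BCL APD vectors.
#' @param threshold APD difference threshold, ms.
#' @param discard Number of additional leading beats to discard from each
#'   sequence before testing (the result must be invariant to this).
#' @return Onset BCL in ms, or `NA` if no alternans in the scanned range.
#' @export
detect_alternans <- function(x, threshold = 2, discard = 0) {
  seqs <- if (inherits(x, "restitution_curve")) {
    attr(x, "apd_sequences")
  } else {
    x
  }
  if (is.null(seqs)) stop("no per-BCL APD sequences available", call. = FALSE)
  bcls <- sort(as.numeric(names(seqs)), decreasing = TRUE)
  for (bcl in bcls) {
    apds <- seqs[[as.character(bcl)]]
    if (discard > 0 && length(apds) > discard) {
      apds <- apds[-seq_len(discard)]
    }
    if (length(apds) < 5) next
    if (alternating_pattern(apds, threshold)) return(bcl)
  }
  NA_real_
}
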