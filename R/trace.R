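new_paced_trace <- function(df, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(df, nm) <- attrs[[nm]]
  class(df) <- c("paced_trace", class(df))
  df
}

#' @export
print.paced_trace <- function(x, ...) {
  cat("<paced_trace> ", attr(x, "cell_type") %||% "?", " cell, ",
      attr(x, "condition") %||% "?", " condition, ",
      length(attr(x, "stim_times") %||% numeric()), " stimuli\n", sep = "")
  NextMethod()
}

# linear interpolation of the time at which V crosses `level`
# between samples i and i+1
interp_crossing <- function(t, v, i, level) {
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

# upward threshold crossings of a voltage series
upstroke_times <- function(t, v, threshold = -40) {
  idx <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  vapply(idx, function(i) interp_crossing(t, v, i, threshold), numeric(1))
}

#' Action potential durations in a paced trace
#'
#' Detects action potentials from upward threshold crossings of the
#' membrane potential and measures, for each, the duration to the given
#' repolarisation fraction. The repolarisation level is referenced to the
#' diastolic potential immediately before the upstroke and the peak of that
#' action potential; both crossing times are linearly interpolated between
#' samples, so the result is insensitive to the output sampling interval.
#'
#' @param trace A `paced_trace` (or any data frame with `t` and `V`
#'   columns, ms and mV).
#' @param beat_index Optional integer vector selecting beats (1-based, in
#'   order of activation); default all beats.
#' @param repol_fraction Repolarisation fraction defining the end of the
#'   action potential; 0.9 gives the conventional APD90.
#' @param threshold Activation threshold for upstroke detection, mV.
#' @return Tibble with one row per measured beat: `beat`, `t_act`
#'   (activation time), `apd` (ms, `NA` if the beat never repolarises
#'   before the record ends), `v_peak`, `v_dia`, and `di` (diastolic
#'   interval preceding the beat; `NA` for the first).
#' @export
measure_apd <- function(trace, beat_index = NULL, repol_fraction = 0.9,
                        threshold = -40) {
  t <- trace$t
  v <- trace$V
  idx <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  if (!length(idx)) {
    return(tibble::tibble(beat = integer(), t_act = numeric(),
                          apd = numeric(), v_peak = numeric(),
                          v_dia = numeric(), di = numeric()))
  }
  acts <- vapply(idx, function(i) interp_crossing(t, v, i, threshold),
                 numeric(1))
  n <- length(idx)
  apd <- v_peak <- v_dia <- rep(NA_real_, n)
  rep_end <- rep(NA_real_, n)
  dt_out <- stats::median(diff(t))
  for (k in seq_len(n)) {
    i0 <- idx[k]
    i1 <- if (k < n) idx[k + 1] else length(v)
    # diastolic reference: sample just before the upstroke
    back <- max(1, i0 - max(1L, round(2 / dt_out)))
    v_dia[k] <- min(v[back:i0])
    seg <- i0:i1
    v_peak[k] <- max(v[seg])
    ipk <- seg[which.max(v[seg])]
    level <- v_dia[k] + (1 - repol_fraction) * (v_peak[k] - v_dia[k])
    dn <- which(v[-1] < level & v[-length(v)] >= level)
    dn <- dn[dn >= ipk & dn <= i1]
    if (length(dn)) {
      rep_end[k] <- interp_crossing(t, v, dn[1], level)
      apd[k] <- rep_end[k] - acts[k]
    }
  }
  di <- c(NA_real_, acts[-1] - rep_end[-n])
  out <- tibble::tibble(beat = seq_len(n), t_act = acts, apd = apd,
                        v_peak = v_peak, v_dia = v_dia, di = di)
  if (!is.null(beat_index)) {
    out <- out[out$beat %in% beat_index, ]
  }
  out
}

#' APD of the final beat of a trace
#'
#' Convenience wrapper around [measure_apd()]; errors if the final beat has
#' not repolarised to the requested fraction before the record ends.
#'
#' @inheritParams measure_apd
#' @return APD in ms (scalar).
#' @export
final_apd <- function(trace, repol_fraction = 0.9) {
  m <- measure_apd(trace, repol_fraction = repol_fraction)
  if (!nrow(m)) stop("no action potentials detected in trace", call. = FALSE)
  a <- m$apd[nrow(m)]
  if (is.na(a)) {
    stop("final beat not repolarised to the requested fraction ",
         "within the recorded trace", call. = FALSE)
  }
  a
}
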