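# memoised simulation products shared across test files (deterministic)
.runs <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.runs[[key]])) .runs[[key]] <- force(expr)
  .runs[[key]]
}

# short paced trace (4 beats) for structural tests
short_trace <- function(cell_type = "epi", condition = "WT") {
  memo(paste0("short|", cell_type, "|", condition),
       pace_to_steady_state(cell_type, condition, n_beats = 4,
                            record_beats = 2))
}

# full sinus protocol trace (10 beats at BCL 600) with currents
sinus_trace <- function(cell_type, condition) {
  memo(paste0("sinus|", cell_type, "|", condition),
       pace_to_steady_state(cell_type, condition, record_currents = TRUE))
}

# dynamic restitution scan over the standard window; the midmyocardial
# scan starts above that cell's steady-state APD (direct 600 -> 400 pacing
# would meet immediate 2:1 block)
restitution_scan <- function(cell_type, condition) {
  memo(paste0("rest|", cell_type, "|", condition),
       dynamic_restitution(cell_type, condition,
                           bcl_start = if (cell_type == "mid") 550 else 400))
}

# common-geometry ring reentry (7 cm, low-CV medium)
ring_run <- function(condition) {
  memo(paste0("ring|", condition), {
    ring <- ring_grid(7, 0.025, condition = condition)
    ring_reentry(ring, duration = 3000, block_ms = 320)
  })
}

conditions3 <- c("WT", "WT_E299V", "E299V")
cell_types3 <- c("endo", "mid", "epi")
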