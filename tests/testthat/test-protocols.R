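test_that("APD of a constructed triangular action potential is exact", {
  # linear upstroke 2 ms, plateau-free linear repolarisation over 200 ms
  t <- seq(0, 400, by = 0.5)
  v_dia <- -85
  v_peak <- 35
  up_end <- 10
  down_end <- 210
  v <- ifelse(t < 8, v_dia,
       ifelse(t < up_end, v_dia + (v_peak - v_dia) * (t - 8) / 2,
       ifelse(t < down_end, v_peak - (v_peak - v_dia) * (t - up_end) / 200,
              v_dia)))
  m <- measure_apd(data.frame(t = t, V = v))
  expect_equal(nrow(m), 1)
  t_act <- 8 + 2 * (-40 - v_dia) / (v_peak - v_dia)
  t_end <- up_end + 200 * 0.9
  expect_equal(m$apd, t_end - t_act, tolerance = 1e-9)
  expect_equal(m$v_peak, v_peak)
})

test_that("APD is insensitive to the output sampling interval", {
  cell <- make_cell("epi", "WT")
  apd_of <- function(rd) {
    tr <- simulate_cell(cell, 1200, c(0, 600), dt = 0.02,
                        record_from = 600, record_dt = rd)
    final_apd(tr)
  }
  expect_lt(abs(apd_of(0.25) - apd_of(0.025)), 0.1)
})

test_that("two-beat pacing satisfies the DI bookkeeping identity", {
  for (cond in c("WT", "E299V")) {
    tr <- pace_to_steady_state("endo", cond, n_beats = 2, record_beats = 2)
    m <- measure_apd(tr)
    expect_equal(nrow(m), 2)
    # DI of beat 2 = BCL - APD of beat 1 (activation-referenced, so allow
    # the small latency difference between stimulus and threshold crossing)
    expect_equal(m$di[2], 600 - m$apd[1], tolerance = 1)
  }
})

test_that("loss of capture raises an informative error", {
  # 80-ms cycle length is far below any captured rate for the wild type
  expect_error(
    pace_to_steady_state("endo", "WT", bcl = 80, n_beats = 6,
                         record_beats = 6),
    "capture"
  )
})

test_that("unrepolarised final beats are reported", {
  # record only 150 ms of a WT action potential (APD ~280 ms)
  cell <- make_cell("epi", "WT")
  tr <- simulate_cell(cell, 150, 0, record_dt = 0.5)
  expect_error(final_apd(tr), "not repolarised")
})

test_that("slope estimator recovers a linear restitution relation", {
  di <- seq(20, 300, by = 10)
  apd <- 100 + 0.5 * di
  slopes <- cardioem:::restitution_slope(di, apd)
  expect_equal(slopes, rep(0.5, length(di)), tolerance = 1e-12)
})

test_that("alternans detection behaves on constructed sequences", {
  expect_true(is.na(detect_alternans(list(`300` = rep(200, 8)))))
  expect_equal(detect_alternans(list(`300` = c(205, 201, 200, 180, 200,
                                               180, 200, 180))), 300)
  # threshold respected
  expect_true(is.na(detect_alternans(
    list(`300` = c(200, 199, 200, 199, 200, 199)), threshold = 2)))
  # invariant to discarding additional equilibrated beats
  seqs <- list(`250` = c(210, 190, 210, 190, 210, 190, 210, 190))
  expect_equal(detect_alternans(seqs), 250)
  expect_equal(detect_alternans(seqs, discard = 2), 250)
})

test_that("dynamic restitution is monotone and truncates at block", {
  cur <- restitution_scan("endo", "E299V")
  ok <- !is.na(cur$apd)
  expect_true(all(diff(cur$apd[ok]) >= -0.5)) # APD non-increasing with BCL
  expect_true(all(cur$di[ok] >= 0))
  expect_false(attr(cur, "truncated")) # captures throughout 400..200
  g <- glance(cur)
  expect_lt(g$max_slope, 1)
  expect_true(is.na(g$alternans_onset))
})

test_that("central-difference slopes agree with a polynomial-fit oracle", {
  cur <- restitution_scan("endo", "WT_E299V")
  ok <- which(!is.na(cur$apd) & !cur$alternans)
  di <- cur$di[ok]
  apd <- cur$apd[ok]
  # independent oracle: local quadratic least squares over 5-point windows,
  # differentiated analytically at the centre point
  poly_slope <- function(k) {
    w <- max(1, k - 2):min(length(di), k + 2)
    fit <- stats::lm(apd[w] ~ stats::poly(di[w], 2, raw = TRUE))
    stats::coef(fit)[2] + 2 * stats::coef(fit)[3] * di[k]
  }
  interior <- 3:(length(di) - 2)
  po <- vapply(interior, poly_slope, numeric(1))
  cd <- cur$slope[ok][interior]
  expect_lt(max(abs(po - cd) / pmax(abs(po), 0.05)), 0.05)
})

test_that("the S1-S2 protocol yields a usable restitution curve", {
  cur <- s1s2_restitution("epi", "E299V", n_s1 = 4,
                          s2_intervals = seq(500, 300, -50))
  expect_gte(nrow(cur), 4)
  expect_true(all(diff(cur$apd) >= -1)) # APD grows with coupling interval
})
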