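test_that("regulatory and cross-bridge fractions are conserved", {
  p <- myofilament_parameters()
  st <- myofilament_state(p)
  # activate hard, then relax: conservation throughout 1e4 steps
  worst <- 0
  st1 <- st
  for (k in 1:100) {
    ca <- if (k <= 50) 2e-3 else 0
    st1 <- step_myofilament(st1, ca, dt = 0.05, params = p, n = 100)
    tot <- sum(st1[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")])
    worst <- max(worst, abs(tot - 1))
  }
  expect_lt(worst, 1e-8)
  expect_true(all(st1[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")] > -1e-12))
})

test_that("force is zero without calcium and decays to zero after removal", {
  p <- myofilament_parameters()
  st <- myofilament_state(p)
  expect_equal(active_force(st, p), 0)
  # activate, then hold Ca = 0 for two seconds
  st <- step_myofilament(st, 2e-3, dt = 0.05, params = p, n = 4000)
  expect_gt(active_force(st, p), 0.5)
  st <- step_myofilament(st, 0, dt = 0.05, params = p, n = 40000)
  expect_lt(active_force(st, p), 1e-4)
  expect_lt(st[["XB_PostR"]], 1e-4)
})

test_that("a saturating calcium step gives a monotone plateau below one", {
  p <- myofilament_parameters()
  ca <- data.frame(t = c(0, 4000), Ca_i = c(0.02, 0.02))
  ft <- simulate_myofilament(ca, duration = 4000, record_dt = 5)
  f <- ft$F_active
  expect_true(all(diff(f) > -1e-6))
  plateau <- tail(f, 1)
  expect_gt(plateau, 0.9)
  expect_lte(plateau, 1 + 1e-6)
  # plateau reached: last 10% of the run moves by < 0.1%
  expect_lt(plateau - f[round(0.9 * length(f))], 1e-3)
})

test_that("the force normalisation anchor equals one", {
  p <- myofilament_parameters(SL = 2.3) # full single overlap
  expect_equal(cardioem:::cpp_sovf_thick(2.3), 1, tolerance = 1e-12)
  st <- myofilament_state(p)
  ssb2 <- local({
    fapp <- p[["f_app"]]; gapp <- p[["g_app"]]; hf <- p[["h_f"]]
    hb <- p[["h_b"]]; gxb <- p[["g_xb"]]
    den <- fapp * hf + gxb * hf + gxb * gapp + hb * fapp + hb * gapp +
      gxb * fapp
    fapp * hf / den
  })
  st[["XB_PostR"]] <- ssb2
  st[["xXB_PostR"]] <- p[["x_0"]]
  st[["XB_PreR"]] <- 0
  expect_equal(active_force(st, p), 1, tolerance = 1e-12)
})

test_that("ATP turnover is the detachment flux and scales with g_xb", {
  p <- myofilament_parameters()
  st <- step_myofilament(myofilament_state(p), 2e-3, dt = 0.05,
                         params = p, n = 4000)
  p2 <- myofilament_parameters(g_xb = 2 * p[["g_xb"]])
  flux1 <- cardioem:::cpp_run_myofilament(
    as.numeric(st), as.numeric(p), c(0, 1), c(2e-3, 2e-3), 0, 0.05, 1
  )$trace[1, "atp_flux"]
  flux2 <- cardioem:::cpp_run_myofilament(
    as.numeric(st), as.numeric(p2), c(0, 1), c(2e-3, 2e-3), 0, 0.05, 1
  )$trace[1, "atp_flux"]
  expect_equal(flux2, 2 * flux1, tolerance = 1e-12)
  # zero occupancy -> zero rate
  ft0 <- simulate_myofilament(data.frame(t = c(0, 100), Ca_i = c(0, 0)),
                              duration = 100)
  expect_equal(atp_rate(ft0), 0)
  expect_error(atp_rate(ft0, window = c(500, 600)), "empty")
})

test_that("peak force is non-decreasing in calcium-transient amplitude", {
  p <- myofilament_parameters()
  t <- seq(0, 4 * 600, by = 1)
  peaks <- vapply(c(2e-4, 4e-4, 8e-4, 1.6e-3), function(a) {
    ca <- synthetic_ca(synthetic_ca_transient(amplitude = a), t)
    max(simulate_myofilament(ca, record_dt = 2)$F_active)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("negative calcium and escaping fractions are rejected", {
  expect_error(step_myofilament(myofilament_state(), -1), "non-negative")
  expect_error(
    simulate_myofilament(data.frame(t = 0:1, Ca_i = c(1e-4, -1e-4))),
    "non-negative"
  )
})

test_that("force-time integral per beat follows the condition ordering", {
  # shorter APD -> briefer calcium transient -> smaller force integral
  ftis <- vapply(conditions3, function(cond) {
    f <- sinus_force(cond)
    sum(f$F_active)
  }, numeric(1))
  expect_true(ftis[["WT"]] > ftis[["WT_E299V"]])
  expect_true(ftis[["WT_E299V"]] > ftis[["E299V"]])
})
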