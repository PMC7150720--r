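test_that("stroke work of a rectangular loop is its exact area", {
  v <- c(60, 120, 120, 60)
  p <- c(10, 10, 110, 110)
  expect_equal(stroke_work(v, p, "shoelace"), 6000)
  expect_equal(stroke_work(v, p, "trapezoid"), 6000)
})

test_that("constant elastance relaxes to a stationary no-flow state", {
  params <- circulation_parameters(F_ref = 1)
  ela <- tibble::tibble(t = seq(0, 60000, by = 5),
                        E_lv = params$E_min_lv, E_rv = params$E_min_rv)
  run <- simulate_circulation(ela, params, dt = 0.5, record_dt = 10)
  late <- run[run$t > 55000, ]
  expect_lt(diff(range(late$V_lv)), 0.01)
  expect_lt(max(abs(late$Q_ao)), 0.05)
  # total blood volume conserved to round-off over a minute
  expect_lt(diff(range(run$V_total)) / run$V_total[1], 1e-6)
})

test_that("valves behave as diodes", {
  pump <- simulate_pump("WT")
  run <- pump$run
  expect_true(all(run$Q_mi >= 0))
  expect_true(all(run$Q_ao >= 0))
  expect_true(all(run$Q_tr >= 0))
  expect_true(all(run$Q_pu >= 0))
  # mitral and aortic valves never conduct simultaneously at high flow
  expect_lt(min(pmin(run$Q_mi, run$Q_ao)), 1)
})

test_that("blood volume is conserved through a pumping minute", {
  params <- circulation_parameters(F_ref = wt_force_reference())
  ela <- tension_to_elastance(sinus_force("WT"), 600, params,
                              n_periods = 100)
  run <- simulate_circulation(ela, params)
  expect_lt(diff(range(run$V_total)) / run$V_total[1], 1e-6)
})

test_that("zero force maps to minimal elastance; peaks align with force", {
  params <- circulation_parameters(F_ref = 1)
  flat <- tibble::tibble(t = 0:600, F_active = 0)
  ela <- tension_to_elastance(flat, 600, params)
  expect_true(all(ela$E_lv == params$E_min_lv))
  f <- sinus_force("WT")
  params$F_ref <- max(f$F_active)
  ela <- tension_to_elastance(f, 600, params)
  expect_equal(max(ela$E_lv), params$E_max_lv, tolerance = 1e-6)
  expect_lt(abs(ela$t[which.max(ela$E_lv)] -
                f$t[which.max(f$F_active)]), 2)
  expect_error(tension_to_elastance(flat, 600, circulation_parameters()),
               "F_ref")
})

test_that("metrics are internally consistent and integrators agree", {
  pump <- simulate_pump("WT")
  m <- pump$metrics
  expect_equal(m$SV, m$EDV - m$ESV)
  expect_equal(m$EF, 100 * m$SV / m$EDV)
  expect_gte(m$EF, 0)
  expect_lte(m$EF, 100)
  expect_lte(m$SV, m$EDV)
  last <- pump$run[pump$run$t > max(pump$run$t) - 600, ]
  sw1 <- stroke_work(last$V_lv, last$P_lv, "shoelace")
  sw2 <- stroke_work(last$V_lv, last$P_lv, "trapezoid")
  expect_lt(abs(sw1 - sw2) / sw1, 0.005)
  # the pumping loop is traversed counter-clockwise in the V-P plane
  n <- nrow(last)
  j <- c(2:n, 1)
  signed <- 0.5 * sum(last$V_lv * last$P_lv[j] - last$V_lv[j] * last$P_lv)
  expect_gt(signed, 0)
})

test_that("unsettled runs are flagged when convergence is required", {
  params <- circulation_parameters(F_ref = wt_force_reference())
  ela <- tension_to_elastance(sinus_force("WT"), 600, params,
                              n_periods = 4)
  run <- simulate_circulation(ela, params)
  expect_error(pv_metrics(run, 600, require_settled = TRUE),
               "not converged")
})
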