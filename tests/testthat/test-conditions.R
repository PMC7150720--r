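test_that("I_K1 is zero at zero driving force for the wild type", {
  expect_equal(ik1_current(-86, -86, "WT"), 0)
  expect_equal(ik1_current(0, 0, "WT"), 0)
})

test_that("I_K1 curves match direct evaluation of their closed forms", {
  # independent evaluation of the printed expressions in R
  wt_raw <- function(u) 0.24731 * u / (0.86426 + exp(0.0904 * u - 0.06519))
  het_raw <- function(u) {
    0.11905 * (u + 2.4) / (0.04092 + exp(0.01732 * u - 0.36212))
  }
  e299v_raw <- function(u) {
    0.06634 * (u + 6.5) - 2.44009e-4 * u^2 - 0.51383
  }
  u <- c(-30, -6.5, 0, 10, 25, 60, 120)
  for (cond in conditions3) {
    sc <- mutation_condition(cond)$scale
    raw <- switch(cond, WT = wt_raw, WT_E299V = het_raw, E299V = e299v_raw)
    expect_equal(ik1_current(u - 86, -86, cond), sc * raw(u),
                 tolerance = 1e-12)
  }
  # regression fixture: pure mutant at 6.5 mV below E_K (hand evaluation)
  expect_equal(ik1_current(-6.5, 0, "E299V"), -0.52413938025,
               tolerance = 1e-10)
})

test_that("conductance scales reproduce the reported peak densities", {
  sweep <- seq(0, 130, by = 0.01)
  pk <- function(cond) max(ik1_current(sweep - 86, -86, cond))
  expect_equal(pk("WT"), 1.9, tolerance = 1e-6)
  expect_equal(pk("WT_E299V"), 2.3, tolerance = 1e-6)
  # the mutant curve is used as printed and predicts > 4 pA/pF
  expect_identical(mutation_condition("E299V")$scale, 1)
  expect_gt(pk("E299V"), 4)
})

test_that("I_K1 is continuous in V over the physiological range", {
  v <- seq(-120, 60, by = 0.01)
  for (cond in conditions3) {
    y <- ik1_current(v, -86, cond)
    expect_true(all(is.finite(y)))
    # no jump anywhere near the resolution of the grid
    expect_lt(max(abs(diff(y))), 0.05)
  }
})

test_that("unknown condition labels are rejected", {
  expect_error(mutation_condition("D172N"), "unknown mutation condition")
  expect_error(ik1_current(-60, -86, "wt"), "unknown mutation condition")
})
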