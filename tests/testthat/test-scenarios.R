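test_that("the catalogue covers the full experiment inventory", {
  cat_tbl <- scenario_catalogue()
  expect_equal(nrow(cat_tbl), 21) # 9 sinus + 4 x 3 per-condition runs
  expect_equal(sum(cat_tbl$kind == "sinus"), 9)
  for (k in c("restitution", "cable", "reentry", "pump")) {
    expect_equal(sum(cat_tbl$kind == k), 3)
  }
  expect_error(make_scenario("sinus-D172N-endo"), "valid names")
})

test_that("scenarios serialise and deserialise losslessly", {
  for (nm in c("sinus-WT-endo", "reentry-E299V", "pump-WT_E299V")) {
    s <- make_scenario(nm)
    s2 <- scenario_from_json(scenario_to_json(s))
    expect_identical(s2, s)
  }
  s <- make_scenario("reentry-E299V")
  expect_equal(s$protocol$duration, 10000)
  expect_equal(make_scenario("reentry-E299V", reduced = TRUE)$
                 protocol$duration, 2000)
})

test_that("synthetic calcium transients honour their parameters", {
  spec <- synthetic_ca_transient(baseline = 1e-4, amplitude = 6e-4,
                                 time_to_peak = 40, tau_decay = 80,
                                 period = 500)
  t <- seq(0, 1500, by = 0.1)
  ca <- synthetic_ca(spec, t)
  expect_true(all(ca$Ca_i >= 1e-4 - 1e-15))
  # peak value and position, in every period
  for (k in 0:2) {
    win <- ca[ca$t >= k * 500 & ca$t < (k + 1) * 500, ]
    expect_equal(max(win$Ca_i), 7e-4, tolerance = 1e-9)
    expect_equal(win$t[which.max(win$Ca_i)] - k * 500, 40,
                 tolerance = 0.11)
  }
  # zero amplitude degenerates to the baseline
  flat <- synthetic_ca(synthetic_ca_transient(amplitude = 0), t)
  expect_true(all(flat$Ca_i == 1e-4))
  expect_error(synthetic_ca_transient(amplitude = -1), "non-negative")
  expect_error(synthetic_ca_transient(baseline = 0), "positive")
})

test_that("sinus scenario reports match the underlying measurements", {
  rep1 <- run_scenario("sinus-E299V-epi")
  tr <- sinus_trace("epi", "E299V")
  expect_equal(rep1$metrics$apd90, final_apd(tr), tolerance = 1e-6)
  # deterministic rerun
  rep2 <- run_scenario("sinus-E299V-epi")
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$config_hash, rep2$config_hash)
})

test_that("run_scenario writes a complete audit trail", {
  out <- file.path(tempdir(), "cardioem-run")
  unlink(out, recursive = TRUE)
  rep <- run_scenario("sinus-WT-endo", out_dir = out)
  expect_true(file.exists(file.path(out, "scenario.json")))
  expect_true(file.exists(file.path(out, "trace.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  back <- jsonlite::fromJSON(file.path(out, "report.json"))
  expect_equal(back$metrics$apd90, rep$metrics$apd90, tolerance = 1e-9)
  tr <- utils::read.csv(file.path(out, "trace.csv"))
  expect_true(all(c("t", "V", "Ca_i", "I_K1") %in% names(tr)))
})

test_that("the comparison table is strictly ordered in the pump metrics", {
  tab <- pump_comparison()
  expect_equal(tab$condition, conditions3)
  for (col in c("SV", "EF", "SW", "CO", "peak_P_lv", "ATP")) {
    expect_true(all(diff(tab[[col]]) < 0), info = col)
  }
})
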