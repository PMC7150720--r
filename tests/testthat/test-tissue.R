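test_that("zero-diffusion tissue reproduces the single cell exactly", {
  g <- tissue_grid(5, 1, dx = 0.025, D = 0, cell_types = "epi",
                   conditions = "WT_E299V")
  stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:5))
  run <- simulate_tissue(g, 400, stim, probes = 3, probe_dt = 0.5)
  cell <- make_cell("epi", "WT_E299V")
  tr <- simulate_cell(cell, 400, 0, record_dt = 0.5)
  expect_lt(max(abs(run$probe_v$node_3 - tr$V)), 1e-6)
})

test_that("a uniform unstimulated grid stays uniform under diffusion", {
  g <- tissue_grid(8, 8, dx = 0.025, D = D_NORMAL)
  run <- simulate_tissue(g, 5, NULL, frame_dt = 1)
  spread <- apply(run$frames, 1, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("the explicit stability bound is enforced before running", {
  g <- tissue_grid(10, 10, dx = 0.01, D = D_NORMAL)
  expect_error(simulate_tissue(g, 1, NULL, dt = 0.02), "unstable")
})

test_that("conduction velocity scales as the square root of diffusion", {
  cv_of <- function(D) {
    g <- tissue_grid(160, 1, dx = 0.0125, D = D, cell_types = "epi")
    stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:8))
    run <- simulate_tissue(g, 60, stim, dt = 0.01)
    measure_cv(run, 53, 107)
  }
  cv1 <- cv_of(D_NORMAL)
  cv4 <- cv_of(4 * D_NORMAL)
  expect_gt(cv4, cv1) # monotone in D
  expect_lt(abs(cv4 / cv1 - 2), 0.1) # root scaling within 5%
})

test_that("zero diffusion gives propagation failure at distal probes", {
  g <- tissue_grid(40, 1, dx = 0.025, D = 0, cell_types = "epi")
  stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:2))
  run <- simulate_tissue(g, 50, stim)
  expect_error(measure_cv(run, 15, 30), "propagation failure")
})

test_that("planar-wave conduction velocity converges under grid refinement", {
  cv_of <- function(dx, dt) {
    g <- tissue_grid(round(2 / dx), 1, dx = dx, D = D_NORMAL,
                     cell_types = "epi")
    stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52,
                           nodes = list(1:ceiling(0.1 / dx)))
    run <- simulate_tissue(g, 60, stim, dt = dt)
    n <- g$nx
    measure_cv(run, round(n / 3), round(2 * n / 3))
  }
  # spatial refinement alone (shared time step isolates the dx error)
  cv_fine <- cv_of(0.00625, 0.0025)
  cv_finer <- cv_of(0.003125, 0.0025)
  expect_lt(abs(cv_finer - cv_fine) / cv_finer, 0.02)
})

test_that("degenerate geometry: an uncoupled node's QT equals its APD", {
  g <- tissue_grid(3, 1, dx = 0.025, D = 0, cell_types = "epi")
  stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:3))
  run <- simulate_tissue(g, 500, stim, probes = 2, probe_dt = 0.25)
  maps <- activation_maps(run)
  cell_apd <- final_apd(simulate_cell(make_cell("epi"), 500, 0,
                                      record_dt = 0.25))
  # EAT threshold crossing vs APD90 level: QT surrogate tracks the APD
  expect_lt(abs(attr(maps, "qt") - cell_apd), 2)
})

test_that("map summaries follow from constructed EAT/EDT arrays", {
  run <- list(grid = tissue_grid(4, 1, D = 0),
              eat = c(5, 10, 20, NA), edt = c(250, 260, 280, NA))
  expect_warning(maps <- activation_maps(run), "never activated")
  expect_equal(attr(maps, "qrs"), 15)
  expect_equal(attr(maps, "qt"), 275)
  expect_equal(attr(maps, "n_unactivated"), 1)
})

test_that("transmural cable QT surrogate is ordered across conditions", {
  qt_of <- function(cond) {
    cable <- transmural_cable(1.5, 0.025, D_NORMAL, cond)
    stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:2))
    run <- simulate_tissue(cable, 600, stim)
    suppressWarnings(attr(activation_maps(run), "qt"))
  }
  qts <- vapply(conditions3, qt_of, numeric(1))
  expect_true(qts[["WT"]] > qts[["WT_E299V"]])
  expect_true(qts[["WT_E299V"]] > qts[["E299V"]])
})

test_that("ring reentry sustains and the wavelength estimators agree", {
  run <- ring_run("E299V")
  expect_true(run$reentrant)
  wl <- reentry_wavelength(run)
  expect_lt(abs(wl$wl_cv_apd - wl$wl_arc) / wl$wl_cv_apd, 0.15)
  # a non-reentrant run refuses wavelength estimation
  dead <- run
  dead$reentrant <- FALSE
  expect_error(reentry_wavelength(dead), "not sustained")
})

test_that("planar wavelength on a cable equals CV times APD", {
  # low-CV medium so the pure-mutant wavelength fits inside the cable
  g <- tissue_grid(160, 1, dx = 0.025, D = D_LOW_CV, cell_types = "epi",
                   conditions = "E299V")
  stim <- tibble::tibble(t_on = 0, dur = 1, amp = -52, nodes = list(1:4))
  run <- simulate_tissue(g, 160, stim, frame_dt = 2)
  cv <- measure_cv(run, 40, 80) # cm/s
  apd <- final_apd(simulate_cell(make_cell("epi", "E299V"), 500, 0,
                                 record_dt = 0.5))
  # excited extent once the wave is fully developed and inside the domain,
  # thresholded at the same 90%-repolarisation level that defines the APD
  mid <- run$frames[run$frame_t == 130, ]
  v90 <- -86 + 0.1 * (max(mid) + 86)
  arc <- sum(mid > v90) * 0.025
  expect_lt(abs(arc - cv * apd / 1000) / arc, 0.1)
})

test_that("reentrant period is shorter under the mutation", {
  p_wt <- dominant_period(ring_run("WT"), c(1500, 3000))
  p_mut <- dominant_period(ring_run("E299V"), c(1500, 3000))
  expect_lt(p_mut, p_wt)
})

test_that("cross-field S2 induces a spiral in the vulnerable window only", {
  sheet <- tissue_grid(120, 120, dx = 0.025, D = D_LOW_CV,
                       cell_types = "epi", conditions = "E299V")
  hit <- induce_spiral(sheet, s2_time = 130, duration = 1230,
                       persist_ms = 900, frame_dt = 10)
  expect_true(hit$reentrant)
  # S2 after full recovery: two symmetric wavefronts, no reentry
  miss <- induce_spiral(sheet, s2_time = 400, duration = 950,
                        persist_ms = 400, frame_dt = 10)
  expect_false(miss$reentrant)
})
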