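test_that("rendering is deterministic under a seed", {
  sc <- scene_params()
  f1 <- render_frame(sc, z_offset = 3, seed = 99)
  f2 <- render_frame(sc, z_offset = 3, seed = 99)
  expect_identical(f1, f2)
})

test_that("noise-off frames carry exact expected counts", {
  sc <- scene_params(autofluor = 80, donor_peak = 960)
  fr <- render_frame(sc, noise = noise_config(FALSE))
  # far corner has no spot flux: exactly the autofluorescence floor
  expect_equal(fr$donor[1, 64], 80, tolerance = 1e-9)
  # peak pixel carries floor + in-focus peak brightness
  expect_equal(fr$donor[sc$neuron_y + 1, sc$neuron_x + 1], 80 + 960,
               tolerance = 1e-9)
})

test_that("defocus broadens the spot while conserving total flux", {
  sc <- scene_params()
  f0 <- render_frame(sc, z_offset = 0, noise = noise_config(FALSE))$acceptor
  f8 <- render_frame(sc, z_offset = 8, noise = noise_config(FALSE))$acceptor
  # peak falls with defocus
  expect_lt(max(f8), max(f0))
  # net (floor-subtracted) flux is conserved within the frame (spot well
  # inside, tails negligible)
  net0 <- sum(f0 - sc$autofluor); net8 <- sum(f8 - sc$autofluor)
  expect_equal(net8 / net0, 1, tolerance = 1e-3)
})

test_that("defocus response is symmetric in the sign of the offset", {
  sc <- scene_params()
  up <- render_frame(sc, z_offset = 6, noise = noise_config(FALSE))$donor
  dn <- render_frame(sc, z_offset = -6, noise = noise_config(FALSE))$donor
  expect_equal(up, dn, tolerance = 1e-12)
})

test_that("noise-off session ratio equals the ideal kinetics exactly", {
  sc <- scene_params()
  k <- response_kinetics(A = 0.25)
  s <- simulate_worm_session(sc, k, bleach = bleach_model(0, 0),
                             noise = noise_config(FALSE))
  tr <- extract_trace(s$timeseries, c(sc$neuron_x, sc$neuron_y))
  k_aligned <- response_kinetics(A = 0.25, t_on = s$truth$t_on,
                                 t_off = s$truth$t_off)
  expect_equal(tr$ratio, ideal_ratio(k_aligned, tr$time), tolerance = 1e-9)
})

test_that("channel intensities decay monotonically under bleaching (noise off)", {
  sc <- scene_params()
  s <- simulate_worm_session(sc, response_kinetics(A = 0),
                             bleach = bleach_model(0.01, 0.005),
                             noise = noise_config(FALSE))
  tr <- extract_trace(s$timeseries, c(sc$neuron_x, sc$neuron_y))
  expect_true(all(diff(tr$donor) < 0))
  expect_true(all(diff(tr$acceptor) < 0))
  # and the per-frame decrement follows exp(-lambda t) exactly
  expect_equal(tr$donor / tr$donor[1], exp(-0.01 * tr$time),
               tolerance = 1e-9)
})

test_that("dead worms respond with zero amplitude", {
  sc <- scene_params(viability = "dead")
  s <- simulate_worm_session(sc, response_kinetics(A = 0.4),
                             bleach = bleach_model(0, 0),
                             noise = noise_config(FALSE))
  expect_equal(s$truth$A, 0)
  tr <- extract_trace(s$timeseries, c(sc$neuron_x, sc$neuron_y))
  expect_equal(diff(range(tr$ratio)), 0, tolerance = 1e-9)
})

test_that("session truth records the plane nearest the true focus", {
  sc <- scene_params(z_true_um = 47)
  s <- simulate_worm_session(sc, z_plan = seq(0, 100, 5),
                             noise = noise_config(FALSE))
  expect_equal(s$truth$z_plane, which.min(abs(seq(0, 100, 5) - 47)))
})

test_that("sessions are reproducible from a seed", {
  sc <- scene_params()
  a <- simulate_worm_session(sc, seed = 7)
  b <- simulate_worm_session(sc, seed = 7)
  expect_identical(a$timeseries$donor, b$timeseries$donor)
  expect_identical(a$zstack$acceptor, b$zstack$acceptor)
})

test_that("random scenes respect the orientation contract", {
  set.seed(3)
  for (i in 1:20) {
    h <- random_scene("head_first")
    t <- random_scene("tail_first")
    expect_lt(h$neuron_x, 32)   # head half
    expect_gte(t$neuron_x, 32)  # tail half
  }
})

test_that("simulate_screen honors effect multipliers in the ground truth", {
  lay <- plate_layout(c("DRUG_A", "DRUG_B"))
  sim <- simulate_screen(lay, effects = c(DRUG_A = 0.5),
                         worms_per_well = 200, cv = 0,
                         qc_rates = c(tail_entry = 0, too_dim = 0,
                                      too_bright = 0, dead = 0),
                         peak_noise_sd = 0, slope_noise_sd = 0, seed = 4)
  tru <- sim$truth
  a <- tru[tru$compound %in% "DRUG_A", ]
  b <- tru[tru$compound %in% "DRUG_B", ]
  # CV = 0 and no measurement noise: every worm sits exactly at its cohort
  # mean, so the +50% multiplier is exact in the truth table
  expect_equal(unique(a$effect), 0.5)
  expect_equal(mean(a$true_peak) / mean(b$true_peak), 1.5, tolerance = 1e-12)
})

test_that("simulate_screen QC accounting matches configured rates", {
  lay <- plate_layout(sprintf("C%03d", 1:54))
  sim <- simulate_screen(lay, worms_per_well = 50, seed = 8)
  rec <- sim$records
  # every seeded worm is either analyzed or discarded with a reason
  expect_equal(nrow(rec), 60 * 50)  # 54 compound + 6 control wells
  expect_true(all(rec$qc_status %in%
    c("analyzed", "tail_entry", "too_dim", "too_bright", "dead")))
  # discard fraction near the configured 30%
  expect_equal(mean(rec$qc_status != "analyzed"), 0.3, tolerance = 0.035)
  # metrics only on analyzed worms
  expect_true(all(is.na(rec$peak[rec$qc_status != "analyzed"])))
  expect_true(all(is.finite(rec$peak[rec$qc_status == "analyzed"])))
})
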