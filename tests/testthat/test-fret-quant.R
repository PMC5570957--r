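test_that("trace construction flags non-positive donor frames", {
  tr <- fret_trace(0:4, c(10, 0, -1, 10, 10), c(15, 15, 15, 15, 15),
                   stim_window = c(1, 3))
  expect_equal(tr$excluded, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(tr$ratio[2:3])))
  expect_equal(tr$ratio[1], 1.5)
})

test_that("bleach rates are recovered exactly on noise-free decay", {
  tr <- oracle_trace(A = 0, lam_d = 0.005, lam_a = 0.002)
  tr <- correct_bleach(tr)
  expect_equal(unname(tr$lambda["donor"]), 0.005, tolerance = 1e-9)
  expect_equal(unname(tr$lambda["acceptor"]), 0.002, tolerance = 1e-9)
  expect_equal(tr$correction, "exp")
})

test_that("corrected null traces are flat to numerical precision", {
  tr <- oracle_trace(A = 0, lam_d = 0.008, lam_a = 0.003)
  tr <- percent_change(correct_bleach(tr))
  expect_lt(max(abs(tr$pct)), 1e-9)
})

test_that("correction leaves a bleach-free trace untouched", {
  tr <- oracle_trace(A = 0.3)
  out <- correct_bleach(tr)
  expect_equal(out$donor_corr, tr$donor, tolerance = 1e-9)
  expect_equal(out$ratio_corr, tr$ratio, tolerance = 1e-9)
  expect_equal(unname(out$lambda), c(0, 0), tolerance = 1e-9)
})

test_that("negative drifts fall back to the linear envelope", {
  t <- 0:89
  donor <- 400 + 0.5 * t          # rising drift: log-fit gives lambda < 0,
  acceptor <- 1.5 * donor         # clipped to 0, so exp route stays exact
  tr <- fret_trace(t, donor, acceptor, stim_window = c(40, 70))
  out <- correct_bleach(tr)
  expect_true(out$correction %in% c("exp", "linear"))
  expect_lt(diff(range(out$ratio_corr)), 1e-9)
})

test_that("uncorrectable traces are flagged, not silently dropped", {
  t <- 0:89
  donor <- rep(400, 90)
  acceptor <- rep(-50, 90)        # negative level: exponential and linear
  tr <- fret_trace(t, donor, acceptor, stim_window = c(40, 70))
  out <- correct_bleach(tr)       # envelopes both fail on the acceptor
  expect_true("bleach_correction_failed" %in% out$flags)
  expect_equal(out$correction, "none")
})

test_that("percent change uses the settled pre-stimulus baseline", {
  tr <- oracle_trace(A = 0.3)
  tr <- percent_change(correct_bleach(tr))
  expect_equal(tr$baseline, 1.5, tolerance = 1e-9)
  expect_equal(tr$baseline_window, c(30, 40))
  expect_lt(max(abs(tr$pct[tr$time < 40])), 1e-9)
})

test_that("metrics recover a linear ramp exactly with smoothing off", {
  # percent change rises linearly 0..20% over the pulse at 2 %/s
  t <- 0:59
  pct <- pmin(pmax(t - 20, 0), 10) * 2
  R0 <- 1.5
  donor <- rep(400, 60)
  acceptor <- donor * R0 * (1 + pct / 100)
  tr <- fret_trace(t, donor, acceptor, stim_window = c(20, 30))
  tr <- percent_change(correct_bleach(tr, baseline_window = c(0, 20)),
                       baseline_window = c(0, 20))
  m <- compute_metrics(tr, smooth_window = 1)
  expect_equal(m$peak, 20, tolerance = 1e-6)
  expect_equal(m$slope, 2, tolerance = 1e-6)
  expect_true(m$responder)
})

test_that("noise-free transient peak matches the closed form", {
  for (A in c(0.05, 0.2, 0.45)) {
    tr <- percent_change(correct_bleach(oracle_trace(A = A)))
    m <- compute_metrics(tr)
    expect_equal(m$peak, oracle_peak_pct(A, 5, 40, 70), tolerance = 0.01)
  }
})

test_that("metrics are invariant to overall intensity scale", {
  tr1 <- oracle_trace(A = 0.3, donor0 = 400)
  tr2 <- oracle_trace(A = 0.3, donor0 = 4e6)
  m1 <- compute_metrics(percent_change(correct_bleach(tr1)))
  m2 <- compute_metrics(percent_change(correct_bleach(tr2)))
  expect_equal(m1$peak, m2$peak, tolerance = 1e-9)
  expect_equal(m1$slope, m2$slope, tolerance = 1e-9)
})

test_that("flat traces give zero metrics and non-responder status", {
  tr <- percent_change(correct_bleach(oracle_trace(A = 0)))
  m <- compute_metrics(tr)
  expect_equal(m$peak, 0)
  expect_equal(m$slope, 0)
  expect_false(m$responder)
})

test_that("tracker follows a stationary neuron and flags lost frames", {
  sc <- scene_params()
  s <- simulate_worm_session(sc, noise = noise_config(FALSE))
  tpl <- make_template(sc)
  tk <- track_neuron(s$timeseries, c(sc$neuron_x, sc$neuron_y), tpl)
  expect_false(any(tk$lost))
  expect_true(all(abs(tk$cx - sc$neuron_x) <= 1))
  expect_true(all(abs(tk$cy - sc$neuron_y) <= 1))
  # a template matching nothing in the frame is lost everywhere and holds
  # the initial position
  junk <- matrix(c(1000, 0, 0, 0, 1000, 0, 0, 0, 1000), 3, 3)
  cfg <- detection_config(track_floor = 0.95)
  tk2 <- track_neuron(s$timeseries, c(40, 10), junk, cfg)
  expect_true(all(tk2$lost))
  expect_true(all(tk2$cx == 40 & tk2$cy == 10))
})

test_that("trace CSV round trip preserves the quantification result", {
  tr <- oracle_trace(A = 0.3, lam_d = 0.004, lam_a = 0.002)
  p <- file.path(tempdir(), "trace.csv")
  write_trace_csv(tr, p)
  back <- read_trace_csv(p)
  q1 <- quantify_trace(tr)
  q2 <- quantify_trace(back)
  expect_equal(q2$metrics$peak, q1$metrics$peak, tolerance = 1e-9)
  expect_equal(q2$metrics$slope, q1$metrics$slope, tolerance = 1e-9)
  file.remove(p)
})

test_that("quantify_trace runs the full chain in one call", {
  q <- quantify_trace(oracle_trace(A = 0.3, lam_d = 0.004))
  expect_s3_class(q$trace, "fret_trace")
  expect_s3_class(q$metrics, "transient_metrics")
  expect_equal(q$trace$correction, "exp")
  expect_equal(q$metrics$peak, oracle_peak_pct(0.3, 5, 40, 70),
               tolerance = 0.02 * oracle_peak_pct(0.3, 5, 40, 70))
})
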