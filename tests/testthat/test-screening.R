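test_that("adulthood phases bin as early / mid / late", {
  expect_equal(phase_bin(c(2, 5, 6, 7, 8, 9, 12, 18)),
               c("early", "early", "early", "mid", "mid", "late", "late",
                 "late"))
})

test_that("layout geometry reserves controls and medium-only wells", {
  lay <- plate_layout(sprintf("C%03d", 1:54))
  expect_equal(nrow(lay), 96)
  expect_equal(sum(lay$role == "compound"), 54)
  expect_equal(sum(lay$role == "vehicle_control"), 6)
  expect_equal(sum(lay$role == "medium_only"), 36)
  # controls sit in column 11, edges are medium-only
  expect_true(all(lay$col[lay$role == "vehicle_control"] == 11))
  expect_true(all(lay$role[lay$col %in% c(1, 12) |
                             lay$row %in% c("A", "H")] == "medium_only"))
})

test_that("layouts survive a YAML round trip", {
  lay <- plate_layout(c("tiagabine", "guanfacine"))
  p <- file.path(tempdir(), "layout.yaml")
  write_layout(lay, p)
  back <- read_layout(p)
  expect_equal(back$well, lay$well)
  expect_equal(back$role, lay$role)
  expect_equal(back$compound, lay$compound)
  expect_equal(back$conc_uM, lay$conc_uM)
  file.remove(p)
})

test_that("schedule interleaves a control after every block of compounds", {
  lay <- plate_layout(sprintf("C%03d", 1:54))
  plan <- schedule(lay, controls_every = 9)
  expect_equal(sum(plan$event == "control"), ceiling(54 / 9))
  # every compound well exactly once, never a medium-only well
  comp <- plan$well[plan$event == "compound"]
  expect_equal(sort(comp), sort(lay$well[lay$role == "compound"]))
  expect_false(any(plan$well %in% lay$well[lay$role == "medium_only"],
                   na.rm = TRUE))
  # a control visit closes each block of 9 compound wells
  ev <- plan$event
  expect_equal(which(ev == "control"), seq(10, 60, by = 10))
  # each compound is matched to the control visit closing its block
  first_block <- plan[1:9, ]
  expect_true(all(first_block$control_well == plan$well[10]))
})

test_that("wash events appear after every configured worm count", {
  lay <- plate_layout(sprintf("C%03d", 1:18))
  plan <- schedule(lay, controls_every = 9, wash_every_n_worms = 40,
                   worms_per_well = 15)
  # 18 compound + 2 control visits = 300 worms -> 7 washes
  expect_equal(sum(plan$event == "wash"), floor(300 / 40))
  # washes occur every ceiling(40/15) = 3rd well or earlier
  w <- which(plan$event == "wash")
  expect_true(all(diff(w) <= 4))
})

test_that("well summary accounts for every worm and computes SEM", {
  rec <- data.frame(
    well = "B2",
    qc_status = c("analyzed", "analyzed", "analyzed", "tail_entry", "dead"),
    peak = c(10, 20, 30, NA, NA), slope = c(1, 2, 3, NA, NA))
  s <- summarize_well(rec)
  expect_equal(s$n_analyzed, 3)
  expect_equal(s$n_tail_entry, 1)
  expect_equal(s$n_dead, 1)
  # [DERIVED] mean(10,20,30) = 20, SEM = sd/sqrt(3) = 10/sqrt(3)
  expect_equal(s$mean_peak, 20)
  expect_equal(s$sem_peak, 10 / sqrt(3))
  expect_false(s$empty)
  # accounting: seeded = analyzed + discards by reason
  expect_equal(s$n_analyzed + s$n_tail_entry + s$n_too_dim +
                 s$n_too_bright + s$n_dead + s$n_neuron_not_found, nrow(rec))
})

test_that("percent effect is the relative difference of group means", {
  treated <- data.frame(peak = c(30, 30, 30), slope = c(3, 3, 3),
                        age_day = 12, compound = "X")
  control <- data.frame(peak = c(20, 20, 20), slope = c(2, 2, 2),
                        age_day = 12)
  e <- compound_effect(treated, control)
  # [TRIVIAL] 100 * (30 - 20) / 20 = +50
  expect_equal(e$effect_peak_pct, 50)
  expect_equal(e$effect_slope_pct, 50)
  treated$peak <- c(12, 12, 12)
  e2 <- compound_effect(treated, control)
  expect_equal(e2$effect_peak_pct, -40)
})

test_that("effect calling refuses mismatched ages and degenerate groups", {
  treated <- data.frame(peak = c(30, 31), slope = c(3, 3), age_day = 12)
  control <- data.frame(peak = c(20, 21), slope = c(2, 2), age_day = 5)
  expect_error(compound_effect(treated, control), "ages must match")
  expect_error(compound_effect(treated[1, ],
                               transform(control, age_day = 12)), ">= 2")
})

test_that("hit calling partitions by sign and respects BH adjustment", {
  eff <- data.frame(
    compound = c("up", "down", "flat"),
    effect_peak_pct = c(60, -50, 1),
    p_peak = c(0.001, 0.002, 0.9))
  h <- call_hits(eff, alpha = 0.05)
  expect_equal(h$effects$classification, c("positive", "negative", "none"))
  expect_equal(unname(h$counts), c(1L, 1L, 1L))
  expect_equal(sum(h$fractions), 1)
  # BH keeps these calls (adjusted p = 0.003, 0.003, 0.9)
  hb <- call_hits(eff, alpha = 0.05, mt = "BH")
  expect_equal(hb$effects$classification, h$effects$classification)
  expect_equal(hb$effects$p_adj, p.adjust(eff$p_peak, "BH"))
})

test_that("screen effects flag an injected strong effect", {
  lay <- plate_layout(sprintf("C%03d", 1:18))
  sim <- simulate_screen(lay, effects = c(C001 = 1.0), worms_per_well = 20,
                         qc_rates = c(tail_entry = 0, too_dim = 0,
                                      too_bright = 0, dead = 0), seed = 10)
  eff <- screen_effects(sim$records, lay)
  expect_equal(nrow(eff), 18)
  e1 <- eff[eff$compound == "C001", ]
  expect_equal(e1$classification, "positive")
  expect_gt(e1$effect_peak_pct, 50)
  expect_lt(e1$p_peak, 0.001)
})

test_that("aging trajectory reports per-day summaries and contrasts", {
  set.seed(20)
  mk <- function(day, mu, n = 30)
    data.frame(age_day = day, qc_status = "analyzed",
               peak = rnorm(n, mu, 3), slope = rnorm(n, mu / 10, 0.3))
  rec <- rbind(mk(3, 30), mk(7, 25), mk(12, 12), mk(18, 5, n = 1))
  tr <- aging_trajectory(rec, contrasts = list(c(3, 12)))
  expect_equal(tr$dropped_days, 18)   # n = 1 day excluded
  expect_equal(tr$by_day$age_day, c(3, 7, 12))
  expect_equal(tr$by_day$phase, c("early", "mid", "late"))
  expect_lt(tr$anova_p_peak, 1e-6)
  expect_lt(tr$pairwise$p_peak[1], 1e-6)
  expect_lt(tr$pairwise$diff_peak[1], 0)  # decline with age
})

test_that("timecourse separates treatment from aging", {
  set.seed(21)
  mk <- function(day, mu, n = 25)
    data.frame(age_day = day, peak = rnorm(n, mu, 3))
  treated <- rbind(mk(3, 32), mk(9, 22))    # +~30% at both ages
  control <- rbind(mk(3, 25), mk(9, 17))
  tc <- two_group_timecourse(treated, control)
  expect_lt(tc$anova["treatment"], 1e-4)
  expect_lt(tc$anova["day"], 1e-4)
  expect_equal(tc$by_day$age_day, c(3, 9))
  expect_true(all(tc$by_day$p_bonf >= tc$by_day$p_raw))
  expect_true(all(tc$by_day$p_bonf <= 1))
})

test_that("dose response compares every dose against vehicle", {
  set.seed(22)
  mk <- function(conc, mu, n = 25)
    data.frame(conc_uM = conc, qc_status = "analyzed",
               peak = rnorm(n, mu, 2))
  rec <- rbind(mk(0, 20), mk(5, 24), mk(20, 30))
  dr <- dose_response(rec)
  expect_equal(dr$by_dose$conc_uM, c(0, 5, 20))
  expect_true(is.na(dr$by_dose$p_vs_vehicle[1]))
  expect_lt(dr$by_dose$p_vs_vehicle[3], 1e-6)
  expect_gt(dr$by_dose$effect_vs_vehicle_pct[3], 30)
  expect_lt(dr$anova_p, 1e-6)
  expect_error(dose_response(rec[rec$conc_uM > 0, ]), "vehicle")
})
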