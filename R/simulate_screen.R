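# per-worm peak/slope draws shared by simulate_cohort() and simulate_screen().
# amplitudes are truncated-normal around mean_A with coefficient of
# variation cv; measured metrics add Gaussian measurement noise. the
# generator's slope summary is the 10-90% secant of the saturating-
# exponential rise, 0.8 * peak / (tau_rise * ln 9).
draw_worm_metrics <- function(n, mean_A, cv, kinetics, peak_noise_sd,
                              slope_noise_sd) {
  k <- kinetics
  A <- pmax(0, stats::rnorm(n, mean = mean_A, sd = cv * mean_A))
  sat <- 1 - exp(-(k$t_off - k$t_on) / k$tau_rise)
  true_peak <- 100 * A * sat
  true_slope <- 0.8 * true_peak / (k$tau_rise * log(9))
  data.frame(
    true_A = A, true_peak = true_peak, true_slope = true_slope,
    peak = true_peak + stats::rnorm(n, sd = peak_noise_sd),
    slope = true_slope + stats::rnorm(n, sd = slope_noise_sd))
}

#' Simulate a cohort of per-worm transient metrics
#'
#' Draws per-worm response amplitudes around a cohort mean with a given
#' between-worm coefficient of variation and maps them through the
#' closed-form transient to peak (% change) and rising-phase slope (%/s),
#' optionally adding measurement noise. This is the statistics-level
#' generator used for aging, dose-response and plate-scale experiments
#' where rendering images per worm would add nothing.
#'
#' @param n Number of worms.
#' @param mean_A Cohort mean fractional amplitude.
#' @param cv Between-worm coefficient of variation of the amplitude.
#' @param kinetics A [response_kinetics()] supplying time constants and the
#'   stimulus window.
#' @param peak_noise_sd,slope_noise_sd Measurement noise (sd, in % and %/s);
#'   set to 0 for noise-free cohorts.
#' @param seed Optional integer seed.
#' @return Data frame with `true_A`, `true_peak`, `true_slope`, `peak`,
#'   `slope` (one row per worm).
#' @export
simulate_cohort <- function(n, mean_A = 0.3, cv = 0.3,
                            kinetics = response_kinetics(),
                            peak_noise_sd = 1, slope_noise_sd = 0.15,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_worm_metrics(n, mean_A, cv, kinetics, peak_noise_sd, slope_noise_sd)
}

#' Simulate a plate-scale screen with known ground truth
#'
#' Populates every compound and vehicle-control well of a layout with a
#' worm cohort. Control wells draw response amplitudes from the base
#' distribution; a compound well with effect multiplier `e` draws amplitudes
#' with mean `mean_A * (1 + e)`. Each worm is independently assigned a QC
#' class (analyzed, tail entry, too dim, too bright, dead) at the configured
#' rates; only analyzed worms carry measured metrics, matching an instrument
#' that discards unusable worms before recording. Dead worms have zero true
#' amplitude.
#'
#' @param layout A layout data frame (see [plate_layout()]).
#' @param effects Named numeric vector of per-compound effect multipliers
#'   (names are compound ids); missing compounds get 0. Multipliers must be
#'   > -1.
#' @param worms_per_well Worms seeded per scheduled well (>= 1).
#' @param mean_A,cv Base amplitude distribution (see [simulate_cohort()]).
#' @param kinetics A [response_kinetics()].
#' @param qc_rates Named rates for classes `tail_entry`, `too_dim`,
#'   `too_bright`, `dead`; their sum is the expected discard fraction
#'   (defaults give ~30%).
#' @param peak_noise_sd,slope_noise_sd Measurement noise; 0 disables.
#' @param age_day Day of adulthood recorded for every worm.
#' @param seed Optional integer seed.
#' @return List of class `"screen_sim"` with `records` (one row per worm:
#'   `worm_id`, `well`, `role`, `compound`, `conc_uM`, `age_day`,
#'   `qc_status`, `peak`, `slope`; metrics are `NA` unless analyzed) and
#'   `truth` (per-worm `true_A`, `true_peak`, `true_slope`, `qc_status`,
#'   per-well `effect` multiplier).
#' @export
simulate_screen <- function(layout, effects = NULL, worms_per_well = 15,
                            mean_A = 0.3, cv = 0.3,
                            kinetics = response_kinetics(),
                            qc_rates = c(tail_entry = 0.12, too_dim = 0.08,
                                         too_bright = 0.05, dead = 0.05),
                            peak_noise_sd = 1, slope_noise_sd = 0.15,
                            age_day = 12, seed = NULL) {
  validate_layout(layout)
  if (worms_per_well < 1) stop("worms_per_well must be >= 1")
  if (!is.null(effects)) {
    if (is.null(names(effects))) stop("effects must be named by compound id")
    if (any(effects <= -1)) stop("effect multipliers must be > -1")
  }
  if (sum(qc_rates) > 1) stop("qc rates must sum to <= 1")
  if (!is.null(seed)) set.seed(seed)

  wells <- layout[layout$role %in% c("compound", "vehicle_control"), ]
  classes <- c("analyzed", names(qc_rates))
  probs <- c(1 - sum(qc_rates), unname(qc_rates))

  # one vectorized draw over all worms of the plate
  nw <- nrow(wells) * worms_per_well
  wi <- rep(seq_len(nrow(wells)), each = worms_per_well)
  eff_by_well <- vapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    if (w$role == "compound" && !is.null(effects) &&
        w$compound %in% names(effects)) effects[[w$compound]] else 0
  }, numeric(1))
  eff <- eff_by_well[wi]
  qc <- sample(classes, nw, replace = TRUE, prob = probs)
  m <- draw_worm_metrics(nw, mean_A * (1 + eff), cv, kinetics,
                         peak_noise_sd, slope_noise_sd)
  dead <- qc == "dead"
  m$true_A[dead] <- 0; m$true_peak[dead] <- 0; m$true_slope[dead] <- 0
  analyzed <- qc == "analyzed"
  records <- data.frame(
    worm_id = sprintf("%s_w%02d", wells$well[wi],
                      rep(seq_len(worms_per_well), nrow(wells))),
    well = wells$well[wi], role = wells$role[wi],
    compound = wells$compound[wi], conc_uM = wells$conc_uM[wi],
    age_day = age_day, qc_status = qc,
    peak = ifelse(analyzed, m$peak, NA_real_),
    slope = ifelse(analyzed, m$slope, NA_real_),
    stringsAsFactors = FALSE)
  truth <- cbind(records[c("worm_id", "well", "compound", "qc_status")],
                 m[c("true_A", "true_peak", "true_slope")], effect = eff)
  structure(list(records = records, truth = truth, layout = layout),
            class = "screen_sim")
}

#' Write / read screen ground truth
#'
#' Ground truth is serialized losslessly as CSV (per-worm table) so a
#' simulated dataset can be regenerated, analyzed and scored in separate
#' processes.
#'
#' @param truth The `truth` data frame of a [simulate_screen()] result.
#' @param path CSV file path.
#' @return `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
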