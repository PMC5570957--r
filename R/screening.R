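#' Adulthood phase bin
#'
#' Days of adulthood are binned into an early (Day 2-5), mid (Day 7-8) and
#' late (Day 9 and older) phase. Day 6 is not named by the phase wording
#' and is binned as early; Day 1 likewise.
#'
#' @param age_day Numeric vector of days of adulthood.
#' @return Character vector: `"early"`, `"mid"` or `"late"`.
#' @export
phase_bin <- function(age_day) {
  ifelse(age_day >= 9, "late", ifelse(age_day >= 7, "mid", "early"))
}

#' Processing plan with interleaved controls and wash events
#'
#' Orders every compound well of the layout for processing; after each block
#' of `controls_every` compound wells a vehicle-control well is inserted
#' (cycling through the available control wells), so treated worms are
#' always compared against untreated worms of exactly the same age. Wash
#' events are inserted after every `wash_every_n_worms` processed worms when
#' a per-well worm count is given. Medium-only wells are never scheduled.
#'
#' @param layout A layout data frame (see [plate_layout()]).
#' @param controls_every Number of compound wells per interleaved control
#'   visit (>= 1).
#' @param wash_every_n_worms Optional worm count between automated washes.
#' @param worms_per_well Worms processed per well (needed for wash events).
#' @return Data frame plan with columns `step`, `event`
#'   (`compound`/`control`/`wash`), `well`, `compound` and `control_well`
#'   (the nearest preceding control visit each compound well is matched to).
#' @export
schedule <- function(layout, controls_every = 9, wash_every_n_worms = NULL,
                     worms_per_well = NULL) {
  validate_layout(layout)
  if (controls_every < 1) stop("controls_every must be >= 1")
  comp <- layout[layout$role == "compound", ]
  ctrl <- layout[layout$role == "vehicle_control", ]
  if (nrow(ctrl) == 0) stop("layout contains no vehicle-control well")

  events <- list()
  ci <- 0                                      # cycling control index
  for (b in seq_len(ceiling(nrow(comp) / controls_every))) {
    idx <- ((b - 1) * controls_every + 1):min(b * controls_every, nrow(comp))
    for (i in idx)
      events[[length(events) + 1]] <-
        list(event = "compound", well = comp$well[i],
             compound = comp$compound[i])
    ci <- ci %% nrow(ctrl) + 1
    events[[length(events) + 1]] <-
      list(event = "control", well = ctrl$well[ci], compound = NA_character_)
  }
  plan <- data.frame(step = seq_along(events),
                     event = vapply(events, `[[`, "", "event"),
                     well = vapply(events, `[[`, "", "well"),
                     compound = vapply(events, `[[`, "", "compound"),
                     stringsAsFactors = FALSE)

  # each compound well is matched to the nearest control visit in the plan
  # (the one closing its block)
  ctrl_steps <- which(plan$event == "control")
  plan$control_well <- NA_character_
  for (i in which(plan$event == "compound")) {
    nxt <- ctrl_steps[ctrl_steps > i][1]
    plan$control_well[i] <- plan$well[nxt]
  }

  if (!is.null(wash_every_n_worms)) {
    if (is.null(worms_per_well))
      stop("wash scheduling needs worms_per_well")
    worms <- 0; out <- list()
    for (i in seq_len(nrow(plan))) {
      out[[length(out) + 1]] <- plan[i, ]
      worms <- worms + worms_per_well
      while (worms >= wash_every_n_worms) {
        worms <- worms - wash_every_n_worms
        out[[length(out) + 1]] <-
          data.frame(step = NA, event = "wash", well = NA_character_,
                     compound = NA_character_, control_well = NA_character_)
      }
    }
    plan <- do.call(rbind, out)
    plan$step <- seq_len(nrow(plan))
    rownames(plan) <- NULL
  }
  plan
}

#' Per-well summary with QC accounting
#'
#' Only worms with QC status `analyzed` contribute to the means; discards
#' are tallied by reason. SEM is `sd/sqrt(n)` and requires `n >= 2`.
#'
#' @param records Data frame of worm records for one well (columns
#'   `qc_status`, `peak`, `slope`).
#' @return One-row data frame: `well`, `n_analyzed`, discard counts per
#'   reason, `mean_peak`, `sem_peak`, `mean_slope`, `sem_slope`, `empty`.
#' @export
summarize_well <- function(records) {
  if (nrow(records) == 0) stop("need >= 1 record")
  well <- records$well[1] %||% NA_character_
  a <- records[records$qc_status == "analyzed", ]
  reasons <- c("tail_entry", "too_dim", "too_bright", "dead",
               "neuron_not_found")
  tally <- vapply(reasons, function(r) sum(records$qc_status == r), 0L)
  names(tally) <- paste0("n_", reasons)
  out <- data.frame(well = well, n_analyzed = nrow(a), t(tally),
                    mean_peak = NA_real_, sem_peak = NA_real_,
                    mean_slope = NA_real_, sem_slope = NA_real_,
                    empty = nrow(a) == 0, stringsAsFactors = FALSE)
  if (nrow(a) > 0) {
    out$mean_peak <- mean(a$peak)
    out$mean_slope <- mean(a$slope)
    out$sem_peak <- sem(a$peak)
    out$sem_slope <- sem(a$slope)
  }
  out
}

#' Percent effect of a compound versus its matched control
#'
#' The effect on neuronal function is the percent difference of the treated
#' group mean from the age-matched control group mean,
#' `100 * (mu_treated - mu_control) / mu_control`, computed on per-worm
#' peaks (and secondarily on slopes). The p-value comes from a two-sided
#' Welch (unequal-variance) two-sample t-test on per-worm peaks.
#' Classification is `positive`/`negative` by effect sign when `p < alpha`,
#' else `none`; `dual_action` flags compounds that significantly increase
#' both peak and slope.
#'
#' @param treated,control Data frames of analyzed worm records (columns
#'   `peak`, `slope`, `age_day`; optionally `compound`), n >= 2 each, same
#'   age.
#' @param alpha Significance level.
#' @return One-row data frame: `compound`, `n_treated`, `n_control`,
#'   `effect_peak_pct`, `effect_slope_pct`, `p_peak`, `p_slope`,
#'   `classification`, `dual_action`.
#' @export
compound_effect <- function(treated, control, alpha = 0.05) {
  treated <- filter_analyzed(treated)
  control <- filter_analyzed(control)
  if (nrow(treated) < 2 || nrow(control) < 2)
    stop("both groups need >= 2 analyzed worms")
  if (!is.null(treated$age_day) && !is.null(control$age_day) &&
      !setequal(unique(treated$age_day), unique(control$age_day)))
    stop("treated and control ages must match")
  mu_c <- mean(control$peak)
  if (mu_c <= 0) stop("control mean peak must be > 0")
  eff_p <- 100 * (mean(treated$peak) - mu_c) / mu_c
  p_p <- welch_p(treated$peak, control$peak)
  eff_s <- p_s <- NA_real_
  if (!is.null(treated$slope) && !is.null(control$slope) &&
      all(is.finite(c(treated$slope, control$slope)))) {
    mu_cs <- mean(control$slope)
    eff_s <- if (mu_cs != 0) 100 * (mean(treated$slope) - mu_cs) / mu_cs
             else NA_real_
    p_s <- welch_p(treated$slope, control$slope)
  }
  cls <- if (is.na(p_p) || p_p >= alpha) "none"
         else if (eff_p > 0) "positive" else "negative"
  data.frame(
    compound = treated$compound[1] %||% NA_character_,
    n_treated = nrow(treated), n_control = nrow(control),
    effect_peak_pct = eff_p, effect_slope_pct = eff_s,
    p_peak = p_p, p_slope = p_s, classification = cls,
    dual_action = identical(cls, "positive") &&
      isTRUE(p_s < alpha) && isTRUE(eff_s > 0),
    stringsAsFactors = FALSE)
}

# keep only records that passed QC; records without a qc_status column are
# assumed pre-filtered
filter_analyzed <- function(df) {
  if (is.null(df$qc_status)) df
  else df[df$qc_status == "analyzed", , drop = FALSE]
}

# two-sided Welch t-test p-value; NA when either group is degenerate
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

#' Compound effects for a whole recorded screen
#'
#' Applies [compound_effect()] to every compound well of a screen's worm
#' records, each against the control well it is matched to by the
#' interleaved-control [schedule()] (the control visit closing its block of
#' compound wells, so both groups are the same age by construction).
#'
#' @param records Worm records (as from [simulate_screen()] or the
#'   pipeline): columns `well`, `qc_status`, `peak`, `slope`, `compound`.
#' @param layout The plate layout.
#' @param controls_every Compound wells per interleaved control visit.
#' @param alpha Significance level.
#' @param min_n Minimum analyzed worms per group; wells below it are skipped.
#' @return Data frame of [compound_effect()] rows (one per testable
#'   compound well) with a `well` column.
#' @export
screen_effects <- function(records, layout, controls_every = 9,
                           alpha = 0.05, min_n = 2) {
  plan <- schedule(layout, controls_every)
  comp <- plan[plan$event == "compound", ]
  records <- filter_analyzed(records)
  by_well <- split(records, records$well)
  out <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    tr <- by_well[[comp$well[i]]]
    ct <- by_well[[comp$control_well[i]]]
    if (is.null(tr) || is.null(ct) ||
        nrow(tr) < max(2, min_n) || nrow(ct) < max(2, min_n)) next
    eff <- compound_effect(tr, ct, alpha = alpha)
    eff$well <- comp$well[i]
    out[[i]] <- eff
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no testable compound wells")
  do.call(rbind, out)
}

#' Partition compound effects into hits
#'
#' Partitions a table of [compound_effect()] rows into positive, negative
#' and no-effect compounds, optionally after Benjamini-Hochberg adjustment
#' of the peak p-values (the screen's primary statistic). Fractions are
#' reported for a pie-chart style summary.
#'
#' @param effects Data frame of [compound_effect()] rows.
#' @param alpha Significance level.
#' @param mt `"none"` (raw p-values, the default) or `"BH"`.
#' @return List with the reclassified `effects` table, `counts` and
#'   `fractions` over `positive`/`negative`/`none`.
#' @export
call_hits <- function(effects, alpha = 0.05, mt = c("none", "BH")) {
  mt <- match.arg(mt)
  if (nrow(effects) == 0) stop("effects must be non-empty")
  p <- effects$p_peak
  p_adj <- if (mt == "BH") stats::p.adjust(p, method = "BH") else p
  effects$p_adj <- p_adj
  effects$classification <- ifelse(
    is.na(p_adj) | p_adj >= alpha, "none",
    ifelse(effects$effect_peak_pct > 0, "positive", "negative"))
  counts <- c(positive = sum(effects$classification == "positive"),
              negative = sum(effects$classification == "negative"),
              none = sum(effects$classification == "none"))
  list(effects = effects, counts = counts,
       fractions = counts / sum(counts), alpha = alpha, mt = mt)
}

#' Aging trajectory of transient metrics
#'
#' Per-day means and SEMs of peak and slope with phase labels, a one-way
#' ANOVA across days, and designated two-sided pairwise contrasts (Welch
#' t-tests).
#'
#' @param records Data frame of analyzed worm records with `age_day`,
#'   `peak`, `slope`.
#' @param contrasts List of day pairs to test, e.g.
#'   `list(c(3, 7), c(7, 18))`; `NULL` tests consecutive observed days.
#' @return List with `by_day` (summary table), `anova_p_peak`,
#'   `anova_p_slope`, and `pairwise` (one row per contrast, Welch p on peak
#'   and slope). Days with fewer than 2 worms are excluded and reported in
#'   `dropped_days`.
#' @export
aging_trajectory <- function(records, contrasts = NULL) {
  records <- filter_analyzed(records)
  n_by_day <- table(records$age_day)
  dropped <- as.numeric(names(n_by_day)[n_by_day < 2])
  records <- records[!records$age_day %in% dropped, ]
  days <- sort(unique(records$age_day))
  if (length(days) < 2) stop("need >= 2 days with n >= 2 each")

  by_day <- do.call(rbind, lapply(days, function(d) {
    r <- records[records$age_day == d, ]
    data.frame(age_day = d, phase = phase_bin(d), n = nrow(r),
               mean_peak = mean(r$peak), sem_peak = sem(r$peak),
               mean_slope = mean(r$slope), sem_slope = sem(r$slope))
  }))

  fday <- factor(records$age_day)
  an_p <- summary(stats::aov(records$peak ~ fday))[[1]][["Pr(>F)"]][1]
  an_s <- summary(stats::aov(records$slope ~ fday))[[1]][["Pr(>F)"]][1]

  if (is.null(contrasts) && length(days) >= 2)
    contrasts <- lapply(seq_len(length(days) - 1),
                        function(i) c(days[i], days[i + 1]))
  pairwise <- do.call(rbind, lapply(contrasts, function(pr) {
    a <- records[records$age_day == pr[1], ]
    b <- records[records$age_day == pr[2], ]
    data.frame(day_a = pr[1], day_b = pr[2],
               diff_peak = mean(b$peak) - mean(a$peak),
               p_peak = welch_p(b$peak, a$peak),
               diff_slope = mean(b$slope) - mean(a$slope),
               p_slope = welch_p(b$slope, a$slope))
  }))
  list(by_day = by_day, anova_p_peak = an_p, anova_p_slope = an_s,
       pairwise = pairwise, dropped_days = dropped)
}

#' Treated-versus-control time course
#'
#' Two-way (day x treatment) ANOVA on the peak, followed by per-day
#' two-sided comparisons with Bonferroni correction across the compared
#' days.
#'
#' @param treated,control Data frames of analyzed worm records with
#'   `age_day`, `peak`.
#' @return List with `anova` (p-values for day, treatment and interaction)
#'   and `by_day` (per-day effect, raw and Bonferroni-adjusted p). Days
#'   missing either group are dropped and listed in `dropped_days`.
#' @export
two_group_timecourse <- function(treated, control) {
  days <- intersect(unique(treated$age_day), unique(control$age_day))
  dropped <- setdiff(union(unique(treated$age_day), unique(control$age_day)),
                     days)
  ok <- days[vapply(days, function(d)
    sum(treated$age_day == d) >= 2 && sum(control$age_day == d) >= 2,
    logical(1))]
  dropped <- c(dropped, setdiff(days, ok))
  days <- sort(ok)
  if (length(days) == 0) stop("no day has both groups with n >= 2")

  df <- rbind(
    data.frame(day = treated$age_day, peak = treated$peak, group = "treated"),
    data.frame(day = control$age_day, peak = control$peak, group = "control"))
  df <- df[df$day %in% days, ]
  anova_p <- c(day = NA_real_, treatment = NA_real_, interaction = NA_real_)
  if (length(days) >= 2) {
    tab <- summary(stats::aov(peak ~ factor(day) * factor(group),
                              data = df))[[1]]
    anova_p <- c(day = tab[["Pr(>F)"]][1], treatment = tab[["Pr(>F)"]][2],
                 interaction = tab[["Pr(>F)"]][3])
  }
  k <- length(days)                            # Bonferroni family size
  by_day <- do.call(rbind, lapply(days, function(d) {
    tr <- treated[treated$age_day == d, ]; ct <- control[control$age_day == d, ]
    p <- welch_p(tr$peak, ct$peak)
    data.frame(age_day = d, phase = phase_bin(d),
               effect_peak_pct = 100 * (mean(tr$peak) - mean(ct$peak)) /
                 mean(ct$peak),
               p_raw = p, p_bonf = min(1, p * k))
  }))
  list(anova = anova_p, by_day = by_day, dropped_days = dropped)
}

#' Dose-response analysis
#'
#' Per-dose means and SEMs with a one-way ANOVA across doses and two-sided
#' pairwise Welch tests of every dose against the vehicle (zero-dose) group.
#'
#' @param records Data frame of analyzed worm records with `conc_uM` (0 for
#'   vehicle) and `peak`.
#' @return List with `by_dose` (mean/SEM/n and pairwise-vs-vehicle p per
#'   dose) and `anova_p`.
#' @export
dose_response <- function(records) {
  records <- filter_analyzed(records)
  doses <- sort(unique(records$conc_uM))
  if (!0 %in% doses) stop("missing vehicle (zero-dose) group")
  if (length(doses) < 2) stop("need >= 2 dose groups")
  veh <- records[records$conc_uM == 0, ]
  by_dose <- do.call(rbind, lapply(doses, function(d) {
    r <- records[records$conc_uM == d, ]
    data.frame(conc_uM = d, n = nrow(r), mean_peak = mean(r$peak),
               sem_peak = sem(r$peak),
               effect_vs_vehicle_pct =
                 100 * (mean(r$peak) - mean(veh$peak)) / mean(veh$peak),
               p_vs_vehicle = if (d == 0) NA_real_
                              else welch_p(r$peak, veh$peak))
  }))
  anova_p <- summary(stats::aov(peak ~ factor(conc_uM),
                                data = records))[[1]][["Pr(>F)"]][1]
  list(by_dose = by_dose, anova_p = anova_p)
}
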