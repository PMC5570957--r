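#' Run configuration
#'
#' Bundles the tunables of every pipeline stage. A run's effective
#' configuration is echoed into its output directory as `config.json`.
#'
#' @param timing A [protocol_timing()].
#' @param detection A [detection_config()].
#' @param quant Quantification settings: `baseline_span` (s of pre-stimulus
#'   baseline), `responder_threshold` (% change), `grace` (s past stimulus
#'   offset searched for the peak).
#' @param screening Screening settings: `alpha`, `controls_every`,
#'   `mt` (`"none"` or `"BH"`), optional `wash_every_n_worms`.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(timing = protocol_timing(),
                       detection = detection_config(),
                       quant = list(baseline_span = 10,
                                    responder_threshold = 2, grace = 5),
                       screening = list(alpha = 0.05, controls_every = 9,
                                        mt = "none",
                                        wash_every_n_worms = NULL),
                       seed = NULL) {
  structure(list(timing = timing, detection = detection, quant = quant,
                 screening = screening, seed = seed),
            class = "run_config")
}

#' Simulate a full plate dataset on disk
#'
#' Renders image-level worm sessions for every compound and vehicle-control
#' well of the layout and writes the directory layout the pipeline consumes:
#' `layout.yaml`, `template.tif` (cut from an ideal training worm),
#' `plate.json`, `wells/<well>/<worm>/{zstack,timeseries}.tif + sidecars +
#' truth.json`, and `ground_truth.csv`.
#'
#' Worm QC classes are sampled at the configured rates and drive the scene:
#' tail entries load tail-first, dim/bright worms carry scaled sensor
#' expression, dead worms respond with zero amplitude.
#'
#' @param dir Dataset root (created).
#' @param layout Layout data frame.
#' @param effects Named per-compound effect multipliers (> -1).
#' @param worms_per_well Worms seeded per scheduled well.
#' @param mean_A,cv Base amplitude distribution.
#' @param kinetics,bleach,timing,noise,z_plan Passed to
#'   [simulate_worm_session()].
#' @param qc_rates Named QC class rates (see [simulate_screen()]).
#' @param age_day Day of adulthood of the cohort.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return The dataset root, invisibly.
#' @export
simulate_plate_dir <- function(dir, layout, effects = NULL,
                               worms_per_well = 8, mean_A = 0.3, cv = 0.3,
                               kinetics = response_kinetics(),
                               bleach = bleach_model(),
                               timing = protocol_timing(),
                               noise = noise_config(),
                               z_plan = seq(0, 100, by = 5),
                               qc_rates = c(tail_entry = 0.12,
                                            too_dim = 0.08,
                                            too_bright = 0.05, dead = 0.05),
                               age_day = 12, seed = 1) {
  validate_layout(layout)
  if (!is.null(effects) && any(effects <= -1))
    stop("effect multipliers must be > -1")
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_layout(layout, file.path(dir, "layout.yaml"))
  write_template(make_template(scene_params()), file.path(dir, "template.tif"))
  jsonlite::write_json(list(age_day = age_day, seed = seed,
                            worms_per_well = worms_per_well),
                       file.path(dir, "plate.json"), auto_unbox = TRUE,
                       digits = NA)

  wells <- layout[layout$role %in% c("compound", "vehicle_control"), ]
  classes <- c("analyzed", names(qc_rates))
  probs <- c(1 - sum(qc_rates), unname(qc_rates))
  truth_rows <- list()
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    eff <- if (w$role == "compound" && !is.null(effects) &&
               w$compound %in% names(effects)) effects[[w$compound]] else 0
    for (j in seq_len(worms_per_well)) {
      qc <- sample(classes, 1, prob = probs)
      A_i <- max(0, stats::rnorm(1, mean_A * (1 + eff),
                                 cv * mean_A * (1 + eff)))
      scene <- random_scene(
        orientation = if (qc == "tail_entry") "tail_first" else "head_first",
        viability = if (qc == "dead") "dead" else "alive",
        expression = switch(qc, too_dim = "dim", too_bright = "bright",
                            "normal"))
      k <- kinetics; k$A <- A_i
      session <- simulate_worm_session(scene, k, bleach, timing,
                                       z_plan = z_plan, noise = noise)
      session$truth$qc_class <- qc
      session$truth$effect <- eff
      wid <- sprintf("w%02d", j)
      write_worm_session(session,
                         file.path(dir, "wells", w$well, wid))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        well = w$well, worm_id = wid, compound = w$compound,
        role = w$role, qc_class = qc, effect = eff, true_A = session$truth$A,
        true_peak = session$truth$true_peak_pct,
        z_plane = session$truth$z_plane,
        orientation = scene$orientation, stringsAsFactors = FALSE)
    }
  }
  write_ground_truth(do.call(rbind, truth_rows),
                     file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

# detection + quantification for one worm session; returns a one-row record
process_worm <- function(session, template, config) {
  det <- config$detection
  zs <- session$zstack
  rec <- list(qc_status = NA_character_, z_index = NA_integer_,
              x = NA_real_, y = NA_real_, max_score = NA_real_,
              baseline = NA_real_, peak = NA_real_, slope = NA_real_)

  cfg_head <- det; cfg_head$search_region <- det$head_region
  af <- autofocus_z(zs, template, cfg_head)
  if (!af$found) {
    cfg_tail <- det; cfg_tail$search_region <- det$tail_region
    if (autofocus_z(zs, template, cfg_tail)$found) {
      rec$qc_status <- "tail_entry"
    } else {
      rec$qc_status <- "neuron_not_found"
    }
    return(rec)
  }
  rec$z_index <- af$z_index; rec$x <- af$cx; rec$y <- af$cy
  rec$max_score <- max(af$scores)

  plane <- stack_frame(zs, af$z_index, det$template_channel)
  px <- disc_pixels(af$cx, af$cy, det$roi_radius, nrow(plane), ncol(plane))
  net <- mean(plane[px]) -
    stats::median(crop_region(plane, det$background_region))
  bq <- qc_brightness(net, det$brightness_bounds)
  if (bq != "pass") {
    rec$qc_status <- bq
    return(rec)
  }

  track <- track_neuron(session$timeseries, c(af$cx, af$cy), template, det)
  trace <- extract_trace(session$timeseries, track, det)
  q <- quantify_trace(
    trace,
    responder_threshold = config$quant$responder_threshold,
    grace = config$quant$grace)
  rec$baseline <- q$metrics$baseline
  rec$peak <- q$metrics$peak
  rec$slope <- q$metrics$slope
  # a worm with no measurable transient while on chip is scored dead
  rec$qc_status <- if (q$metrics$responder) "analyzed" else "dead"
  rec
}

#' Run the full analysis pipeline on a plate dataset
#'
#' Executes detection, quantification and screening over a dataset directory
#' (as produced by [simulate_plate_dir()] or by an instrument writing the
#' same layout): wells are visited per the interleaved-control schedule,
#' every worm is detected, oriented, focus-checked, QC'd, tracked and
#' quantified, and each compound well is compared with its matched control.
#' Malformed worm inputs are discarded with a logged reason and the run
#' continues. The run is fully deterministic given the inputs and
#' configuration — the run log uses event indices, not wall-clock time.
#'
#' @param root Dataset root directory.
#' @param config A [run_config()].
#' @param out_dir Output directory (default `<root>/analysis`): writes
#'   `records.csv`, `well_summary.csv`, `effects.csv`, `hits.json`,
#'   `run_log.txt` and `config.json`.
#' @return List of class `"screen_result"` with `records`, `well_summary`,
#'   `effects`, `hits`, `plan`, `log` and `status` (`"ok"` or `"empty"`).
#' @export
run_pipeline <- function(root, config = run_config(),
                         out_dir = file.path(root, "analysis")) {
  layout <- read_layout(file.path(root, "layout.yaml"))
  template <- read_template(file.path(root, "template.tif"))
  plate_meta <- if (file.exists(file.path(root, "plate.json")))
    jsonlite::read_json(file.path(root, "plate.json"), simplifyVector = TRUE)
  else list(age_day = NA_real_)
  plan <- schedule(layout, config$screening$controls_every,
                   config$screening$wash_every_n_worms,
                   plate_meta$worms_per_well)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  records <- list()
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    if (ev$event == "wash") { note("[%04d] wash", i); next }
    wdir <- file.path(root, "wells", ev$well)
    worm_dirs <- if (dir.exists(wdir)) sort(list.dirs(wdir, recursive = FALSE))
                 else character(0)
    note("[%04d] well %s started (%s, %d worms)", i, ev$well, ev$event,
         length(worm_dirs))
    for (wd in worm_dirs) {
      rec <- tryCatch({
        session <- read_worm_session(wd)
        process_worm(session, template, config)
      }, error = function(e) {
        list(qc_status = "malformed", z_index = NA_integer_, x = NA_real_,
             y = NA_real_, max_score = NA_real_, baseline = NA_real_,
             peak = NA_real_, slope = NA_real_)
      })
      rec <- c(list(well = ev$well, worm_id = basename(wd),
                    role = if (ev$event == "control") "vehicle_control"
                           else "compound",
                    compound = ev$compound,
                    control_well = ev$control_well,
                    age_day = plate_meta$age_day), rec)
      records[[length(records) + 1]] <- as.data.frame(rec,
                                                      stringsAsFactors = FALSE)
      if (rec$qc_status == "analyzed")
        note("[%04d] %s/%s analyzed peak=%.3f", i, ev$well, rec$worm_id,
             rec$peak)
      else
        note("[%04d] %s/%s discarded: %s", i, ev$well, rec$worm_id,
             rec$qc_status)
    }
    note("[%04d] well %s finished", i, ev$well)
  }

  if (length(records) == 0) {
    note("no worms processed")
    writeLines(log, file.path(out_dir, "run_log.txt"))
    res <- structure(list(records = NULL, well_summary = NULL,
                          effects = NULL, hits = NULL, plan = plan,
                          log = log, status = "empty"),
                     class = "screen_result")
    return(res)
  }
  records <- do.call(rbind, records)
  records$qc_status <- as.character(records$qc_status)

  wells <- unique(records$well)
  well_summary <- do.call(rbind, lapply(wells, function(w)
    summarize_well(records[records$well == w, ])))

  comp_wells <- unique(records$well[records$role == "compound"])
  alpha <- config$screening$alpha
  effects <- list()
  for (w in comp_wells) {
    tr <- records[records$well == w & records$qc_status == "analyzed", ]
    cw <- records$control_well[records$well == w][1]
    ct <- records[records$well == cw & records$qc_status == "analyzed", ]
    if (nrow(tr) < 2 || nrow(ct) < 2) {
      note("well %s skipped in effect calling (n treated=%d, control=%d)",
           w, nrow(tr), nrow(ct))
      next
    }
    eff <- compound_effect(tr, ct, alpha = alpha)
    eff$well <- w
    effects[[length(effects) + 1]] <- eff
  }
  effects <- if (length(effects)) do.call(rbind, effects) else NULL
  hits <- if (!is.null(effects))
    call_hits(effects, alpha = alpha, mt = config$screening$mt) else NULL

  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(well_summary, file.path(out_dir, "well_summary.csv"),
                   row.names = FALSE)
  if (!is.null(effects))
    utils::write.csv(hits$effects, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
  if (!is.null(hits))
    jsonlite::write_json(
      list(counts = as.list(hits$counts),
           fractions = as.list(hits$fractions),
           alpha = alpha, mt = config$screening$mt),
      file.path(out_dir, "hits.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(rapply(unclass(config), identity, how = "replace"),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  structure(list(records = records, well_summary = well_summary,
                 effects = if (is.null(hits)) NULL else hits$effects,
                 hits = hits, plan = plan, log = log, status = "ok"),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  if (x$status == "empty") { cat("<screen_result: empty run>\n"); return(invisible(x)) }
  cat(sprintf("<screen_result: %d worms, %d wells, %d compounds tested>\n",
              nrow(x$records), nrow(x$well_summary),
              if (is.null(x$effects)) 0L else nrow(x$effects)))
  if (!is.null(x$hits))
    cat(sprintf("  hits: %d positive / %d negative / %d none\n",
                x$hits$counts["positive"], x$hits$counts["negative"],
                x$hits$counts["none"]))
  invisible(x)
}
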