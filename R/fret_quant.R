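#' FRET trace container
#'
#' Per-frame donor/acceptor readout of one worm, the input to photobleach
#' correction and metric extraction. Intensities are background-subtracted
#' ROI means; the ratio is acceptor/donor, so calcium influx (a FRET
#' increase) raises it. Frames whose donor signal is non-positive cannot
#' carry a ratio and are flagged excluded.
#'
#' @param time Frame times (s), strictly increasing.
#' @param donor,acceptor Background-subtracted ROI mean intensities (counts).
#' @param stim_window `c(t_on, t_off)` stimulus window (s).
#' @param bg_donor,bg_acceptor Optional per-frame background levels (counts).
#' @return An object of class `"fret_trace"` with per-frame fields and a
#'   `ratio` series (`NA` on excluded frames).
#' @export
fret_trace <- function(time, donor, acceptor, stim_window,
                       bg_donor = NULL, bg_acceptor = NULL) {
  n <- length(time)
  stopifnot(length(donor) == n, length(acceptor) == n)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(stim_window) != 2 || stim_window[2] < stim_window[1])
    stop("stim_window must be c(t_on, t_off)")
  excluded <- !is.finite(donor) | donor <= 0 | !is.finite(acceptor)
  ratio <- ifelse(excluded, NA_real_, acceptor / donor)
  structure(list(time = time, donor = donor, acceptor = acceptor,
                 bg_donor = bg_donor, bg_acceptor = bg_acceptor,
                 ratio = ratio, excluded = excluded,
                 stim_window = stim_window,
                 donor_corr = NULL, acceptor_corr = NULL, ratio_corr = NULL,
                 lambda = NULL, correction = "none",
                 pct = NULL, baseline = NULL, flags = character(0)),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace %d frames, stim [%g, %g] s, correction: %s>\n",
              length(x$time), x$stim_window[1], x$stim_window[2],
              x$correction))
  invisible(x)
}

#' Track the neuron across a recording
#'
#' Per frame, the neuron position is the best ZNCC match of the template
#' within `track_radius` pixels of the previous position, so inter-frame
#' drift is bounded by the radius. Frames whose best score falls below
#' `track_floor` are flagged lost and hold the last good position.
#'
#' @param stack A time-axis [channel_stack()].
#' @param init_xy Initial neuron center `c(x, y)` (0-based px), from
#'   detection.
#' @param template A [neuron_template()] or matrix.
#' @param config A [detection_config()] (uses `track_radius`, `track_floor`,
#'   `template_channel`).
#' @return Data frame with one row per frame: `cx`, `cy`, `score`, `lost`.
#' @export
track_neuron <- function(stack, init_xy, template,
                         config = detection_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (stack$axis != "time") stop("tracking needs a time-axis stack")
  if (config$track_radius < 1) stop("track radius must be >= 1 px")
  tm <- as_template_matrix(template)
  th <- nrow(tm); tw <- ncol(tm)
  h <- dim(stack$donor)[2]; w <- dim(stack$donor)[3]
  r <- config$track_radius
  cx <- init_xy[1]; cy <- init_xy[2]
  n <- n_frames(stack)
  out <- data.frame(frame = seq_len(n), cx = NA_real_, cy = NA_real_,
                    score = NA_real_, lost = FALSE)
  for (i in seq_len(n)) {
    x0 <- max(0, floor(cx - (tw - 1) / 2 - r))
    y0 <- max(0, floor(cy - (th - 1) / 2 - r))
    x1 <- min(w, ceiling(cx + (tw - 1) / 2 + r) + 1)
    y1 <- min(h, ceiling(cy + (th - 1) / 2 + r) + 1)
    m <- match_template_ncc(stack_frame(stack, i, config$template_channel),
                            tm, region(x0, y0, x1, y1))
    if (m$score < config$track_floor) {
      out$lost[i] <- TRUE
      out$cx[i] <- cx; out$cy[i] <- cy; out$score[i] <- m$score
    } else {
      cx <- m$cx; cy <- m$cy
      out$cx[i] <- cx; out$cy[i] <- cy; out$score[i] <- m$score
    }
  }
  out
}

#' Extract a raw FRET trace from a stack pair
#'
#' Per frame and channel: mean intensity over a disc ROI centred on the
#' tracked neuron position, minus the median of the background region.
#'
#' @param stack A time-axis [channel_stack()].
#' @param positions Either a single center `c(x, y)` or a data frame with
#'   `cx`, `cy` per frame (as from [track_neuron()]).
#' @param config A [detection_config()] (uses `roi_radius` and
#'   `background_region`).
#' @return A [fret_trace()].
#' @export
extract_trace <- function(stack, positions, config = detection_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  n <- n_frames(stack)
  h <- dim(stack$donor)[2]; w <- dim(stack$donor)[3]
  if (is.numeric(positions) && length(positions) == 2)
    positions <- data.frame(cx = rep(positions[1], n),
                            cy = rep(positions[2], n))
  stopifnot(nrow(positions) == n)
  don <- acc <- bgd <- bga <- numeric(n)
  for (i in seq_len(n)) {
    px <- disc_pixels(positions$cx[i], positions$cy[i], config$roi_radius,
                      h, w)
    if (nrow(px) == 0 ||
        min(px) < 1 || max(px[, "row"]) > h || max(px[, "col"]) > w)
      stop("ROI disc outside the image")
    fd <- stack_frame(stack, i, "donor"); fa <- stack_frame(stack, i, "acceptor")
    bgd[i] <- stats::median(crop_region(fd, config$background_region))
    bga[i] <- stats::median(crop_region(fa, config$background_region))
    don[i] <- mean(fd[px]) - bgd[i]
    acc[i] <- mean(fa[px]) - bga[i]
  }
  fret_trace(stack_times(stack), don, acc,
             stim_window = stack$stim_window %||%
               stop("stack carries no stimulus window"),
             bg_donor = bgd, bg_acceptor = bga)
}

default_baseline_window <- function(trace, span = 10) {
  c(max(trace$time[1], trace$stim_window[1] - span), trace$stim_window[1])
}

# least-squares mono-exponential fit on a window; returns lambda >= 0 or
# NULL when the fit is not possible on these samples
fit_exp_decay <- function(t, y) {
  if (any(!is.finite(y)) || any(y <= 0)) return(NULL)
  fit <- stats::lm.fit(cbind(1, t), log(y))
  lam <- -fit$coefficients[[2]]
  if (!is.finite(lam)) return(NULL)
  max(0, lam)
}

#' Photobleaching correction
#'
#' Fits a mono-exponential decay `I(t) = I0 exp(-lambda t)` per channel by
#' least squares on log-intensities over the pre-stimulus baseline window
#' (`lambda` clipped at >= 0), divides each full series by its fitted
#' envelope `exp(-lambda t)`, and recomputes the ratio from the corrected
#' channels. If the exponential fit fails a linear envelope is fitted
#' instead; if both fail the trace is left uncorrected and flagged.
#'
#' The default fit window is the whole pre-stimulus period rather than the
#' short settled window used for the baseline ratio: the variance of a
#' fitted decay rate shrinks with the square of the window's time span, and
#' the fitted rate is extrapolated across the entire recording, so rate
#' estimation wants the longest pre-stimulus lever arm available.
#'
#' @param trace A [fret_trace()].
#' @param baseline_window `c(t0, t1)` (s); must precede the stimulus onset
#'   and contain at least 5 samples. Default: everything before onset.
#' @return The trace with `donor_corr`, `acceptor_corr`, `ratio_corr`,
#'   fitted `lambda` per channel, and the `correction` method used.
#' @export
correct_bleach <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "fret_trace"))
  bw <- baseline_window %||% c(trace$time[1], trace$stim_window[1])
  if (bw[2] > trace$stim_window[1] + 1e-9)
    stop("baseline window must precede stimulus onset")
  sel <- trace$time >= bw[1] & trace$time <= bw[2] & !trace$excluded
  if (sum(sel) < 5) stop("baseline window must contain >= 5 usable samples")
  t <- trace$time
  corr <- list(); lambda <- c(donor = 0, acceptor = 0); method <- "exp"
  for (ch in c("donor", "acceptor")) {
    y <- trace[[ch]]
    lam <- fit_exp_decay(t[sel], y[sel])
    if (!is.null(lam)) {
      lambda[[ch]] <- lam
      corr[[ch]] <- y * exp(lam * t)
    } else {
      lf <- stats::lm.fit(cbind(1, t[sel]), y[sel])
      a <- lf$coefficients[[1]]; b <- lf$coefficients[[2]]
      env <- a + b * t
      if (is.finite(a) && a > 0 && all(env > 0)) {
        method <- "linear"
        lambda[[ch]] <- NA_real_
        corr[[ch]] <- y * (a / env)
      } else {
        trace$flags <- c(trace$flags, "bleach_correction_failed")
        trace$donor_corr <- trace$donor
        trace$acceptor_corr <- trace$acceptor
        trace$ratio_corr <- trace$ratio
        trace$lambda <- c(donor = NA_real_, acceptor = NA_real_)
        trace$correction <- "none"
        return(trace)
      }
    }
  }
  trace$donor_corr <- corr$donor
  trace$acceptor_corr <- corr$acceptor
  trace$ratio_corr <- ifelse(trace$excluded, NA_real_,
                             corr$acceptor / corr$donor)
  trace$lambda <- lambda
  trace$correction <- method
  trace$bleach_window <- bw
  trace
}

#' Percent change from baseline
#'
#' The baseline ratio `B` is the mean corrected ratio over the baseline
#' window; the trace is then re-expressed as
#' `100 * (R(t) - B) / B` (% of baseline).
#'
#' @param trace A [fret_trace()] after [correct_bleach()] (an uncorrected
#'   trace falls back to its raw ratio).
#' @param baseline_window `c(t0, t1)` (s); default: the final 10 s before
#'   stimulus onset, after the light response has settled.
#' @return The trace with `pct` (percent-change series) and `baseline` (B).
#' @export
percent_change <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "fret_trace"))
  bw <- baseline_window %||% default_baseline_window(trace)
  r <- trace$ratio_corr %||% trace$ratio
  sel <- trace$time >= bw[1] & trace$time <= bw[2] & is.finite(r)
  if (!any(sel)) stop("no usable samples in the baseline window")
  B <- mean(r[sel])
  if (B <= 0) stop("baseline ratio must be > 0")
  trace$pct <- 100 * (r - B) / B
  trace$baseline <- B
  trace$baseline_window <- bw
  trace
}

#' Locate the rising phase of a transient
#'
#' The peak is the earliest maximum of the percent-change series within
#' `[t_on, t_off + grace]`; the onset is the last sample before the peak at
#' which the series is at or below 10% of the peak value (stimulus onset if
#' there is none). A perfectly flat series has no rising phase: onset and
#' peak collapse onto the stimulus-onset sample.
#'
#' Peak picking runs on a lightly smoothed copy of the series (centered
#' moving average of `smooth_window` frames): the raw per-frame maximum is a
#' positively biased peak estimator under shot noise, and a short moving
#' average removes most of that bias while leaving the transient shape
#' (tens of seconds) untouched. `smooth_window = 1` disables smoothing.
#'
#' @param trace A [fret_trace()] carrying a `pct` series.
#' @param grace Seconds past stimulus offset still searched for the peak
#'   (responses may peak shortly after the pulse ends).
#' @param smooth_window Odd moving-average width (frames) for peak picking.
#' @return List with `onset_idx`, `peak_idx` (1-based sample indices),
#'   `flat`, and `pct_smooth` (the series the indices refer to).
#' @export
rising_phase <- function(trace, grace = 5, smooth_window = 3) {
  stopifnot(inherits(trace, "fret_trace"), !is.null(trace$pct))
  t <- trace$time; p <- smooth_series(trace$pct, smooth_window)
  on <- trace$stim_window[1]; off <- trace$stim_window[2]
  if (on < t[1] || off > t[length(t)] + 1e-9)
    stop("stimulus window must lie inside the series")
  on_idx <- which(t >= on)[1]
  win <- which(t >= on & t <= off + grace & is.finite(p))
  if (length(win) == 0 || diff(range(p[is.finite(p)])) == 0)
    return(list(onset_idx = on_idx, peak_idx = on_idx, flat = TRUE,
                pct_smooth = p))
  peak_idx <- win[which.max(p[win])]            # earliest max
  pk <- p[peak_idx]
  before <- on_idx:peak_idx
  low <- before[is.finite(p[before]) & p[before] <= 0.1 * pk]
  onset_idx <- if (length(low)) max(low) else on_idx
  list(onset_idx = onset_idx, peak_idx = peak_idx, flat = FALSE,
       pct_smooth = p)
}

# sample window for the rising-phase slope fit: 10-90%-of-peak times from a
# saturating-exponential fit of the rise, falling back to first crossings,
# then to the whole onset-to-peak segment
slope_window <- function(t, p, stim_window, seg, slope_frac) {
  on <- stim_window[1]; off <- stim_window[2]
  rise <- which(t >= on & t <= off & is.finite(p))
  if (length(rise) >= 4) {
    df <- data.frame(tt = t[rise] - on, y = p[rise])
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ P * (1 - exp(-tt / tau)), data = df,
                 start = list(P = max(df$y), tau = (off - on) / 6),
                 control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tau <- stats::coef(fit)[["tau"]]
      if (is.finite(tau) && tau > 0) {
        pk_frac <- 1 - exp(-(off - on) / tau)
        t_lo <- on - tau * log(1 - slope_frac[1] * pk_frac)
        t_hi <- on - tau * log(1 - slope_frac[2] * pk_frac)
        w <- which(t >= t_lo & t <= t_hi)
        if (length(w) >= 3) return(w)
      }
    }
  }
  P <- p[seg[length(seg)]]
  lo <- seg[which(p[seg] >= slope_frac[1] * P)[1]]
  hi <- seg[which(p[seg] >= slope_frac[2] * P)[1]]
  if (!is.na(lo) && !is.na(hi) && hi - lo + 1 >= 3) lo:hi else seg
}

# centered moving average with shrinking windows at the edges; width 1 is
# the identity. NA samples are ignored within each window.
smooth_series <- function(p, width) {
  if (width <= 1) return(p)
  h <- floor(width / 2)
  n <- length(p)
  vapply(seq_len(n), function(i) {
    w <- p[max(1, i - h):min(n, i + h)]
    if (all(!is.finite(w))) NA_real_ else mean(w[is.finite(w)])
  }, numeric(1))
}

#' Transient metrics: peak and rising-phase slope
#'
#' Peak `P` is the maximum percent change of the rising phase; slope `S` is
#' the least-squares linear slope of the percent-change series over its
#' 10-90%-of-peak window. Flat traces give `P = S = 0`. A worm is a
#' responder when `P` exceeds the responder threshold.
#'
#' Locating the 90% point by direct threshold crossing is noisy — the curve
#' is nearly flat there, so small intensity noise moves the crossing by
#' seconds. The window is therefore localized by fitting a saturating-
#' exponential rise (the package's canonical transient shape) to the
#' smoothed rising segment and taking the 10% and 90% times of the fitted
#' curve; the slope itself is still a plain linear fit of the series inside
#' that window. When the parametric fit fails (e.g. a non-exponential rise)
#' the window falls back to first crossings, and to the onset-to-peak
#' segment when fewer than 3 samples remain.
#'
#' @param trace A [fret_trace()] with a `pct` series (see [quantify_trace()]
#'   for the full chain).
#' @param responder_threshold Minimum peak (% change) for a measurable
#'   response.
#' @param slope_frac Lower/upper fractions of the peak bounding the slope
#'   fit window.
#' @param grace,smooth_window Passed to [rising_phase()].
#' @return An object of class `"transient_metrics"`: `baseline`, `peak`,
#'   `slope`, `onset_idx`, `peak_idx`, `responder`, `flags`.
#' @export
compute_metrics <- function(trace, responder_threshold = 2,
                            slope_frac = c(0.1, 0.9), grace = 5,
                            smooth_window = 3) {
  rp <- rising_phase(trace, grace = grace, smooth_window = smooth_window)
  p <- rp$pct_smooth; t <- trace$time
  if (rp$flat) {
    m <- list(baseline = trace$baseline, peak = 0, slope = 0,
              onset_idx = rp$onset_idx, peak_idx = rp$peak_idx,
              responder = FALSE, flags = trace$flags)
    return(structure(m, class = "transient_metrics"))
  }
  P <- p[rp$peak_idx]
  seg <- rp$onset_idx:rp$peak_idx
  fitw <- slope_window(t, p, trace$stim_window, seg, slope_frac)
  fitw <- fitw[is.finite(p[fitw])]
  S <- if (length(fitw) >= 2)
    stats::lm.fit(cbind(1, t[fitw]), p[fitw])$coefficients[[2]] else 0
  structure(list(baseline = trace$baseline, peak = P, slope = S,
                 onset_idx = rp$onset_idx, peak_idx = rp$peak_idx,
                 responder = P > responder_threshold, flags = trace$flags),
            class = "transient_metrics")
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(
    "<transient_metrics peak=%.2f%% slope=%.3f %%/s baseline=%.3f %s>\n",
    x$peak, x$slope, x$baseline,
    if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' Full trace quantification chain
#'
#' [correct_bleach()], [percent_change()] and [compute_metrics()] in one
#' call.
#'
#' @param trace A raw [fret_trace()].
#' @param bleach_window Optional `c(t0, t1)` (s) for the bleach-rate fit.
#' @param baseline_window Optional `c(t0, t1)` (s) for the baseline ratio.
#' @param ... Passed to [compute_metrics()].
#' @return List with the augmented `trace` and the `metrics`.
#' @export
quantify_trace <- function(trace, bleach_window = NULL,
                           baseline_window = NULL, ...) {
  trace <- correct_bleach(trace, bleach_window)
  trace <- percent_change(trace, baseline_window)
  list(trace = trace, metrics = compute_metrics(trace, ...))
}

#' Read / write traces as CSV
#'
#' The trace CSV dialect: comma-separated with header, one row per frame
#' with columns `time`, `donor`, `acceptor` (background-subtracted) and the
#' stimulus window recorded in `t_on`/`t_off` columns (constant), enabling
#' trace-only quantification without image stacks.
#'
#' @param trace A [fret_trace()].
#' @param path CSV path.
#' @return `read_trace_csv()` returns a [fret_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time = trace$time, donor = trace$donor,
                   acceptor = trace$acceptor,
                   ratio = trace$ratio,
                   pct = if (is.null(trace$pct)) NA_real_ else trace$pct,
                   t_on = trace$stim_window[1], t_off = trace$stim_window[2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "donor", "acceptor", "t_on", "t_off")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  fret_trace(df$time, df$donor, df$acceptor,
             stim_window = c(df$t_on[1], df$t_off[1]))
}
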