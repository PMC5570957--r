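#' Neuron template
#'
#' A small 2-D patch (by default cut from the acceptor channel of a focused
#' training worm, see [make_template()]) that the correlation matcher slides
#' over the search region. A constant-valued patch has zero variance and is
#' rejected: its zero-normalized cross-correlation is undefined.
#'
#' @param patch Numeric matrix of counts.
#' @param note Free-text provenance note.
#' @return An object of class `"neuron_template"`.
#' @export
neuron_template <- function(patch, note = "") {
  patch <- as.matrix(patch)
  if (stats::var(as.vector(patch)) == 0)
    stop("constant template rejected (zero variance)")
  structure(list(patch = patch, size = dim(patch), note = note),
            class = "neuron_template")
}

as_template_matrix <- function(template) {
  if (inherits(template, "neuron_template")) return(template$patch)
  m <- as.matrix(template)
  if (stats::var(as.vector(m)) == 0)
    stop("constant template rejected (zero variance)")
  m
}

#' Detection configuration
#'
#' Tunables of the computer-vision layer. The correlation threshold defaults
#' to 0.5 on the zero-normalized scale; the stage travel defaults to
#' 0-100 µm. Regions default to a left/right split of the frame (the head of
#' a properly loaded worm occupies the left half) with a thin top strip as
#' the background region.
#'
#' @param corr_threshold Correlation threshold `c` in `[0, 1]`; a worm whose
#'   per-plane score vector never reaches `c` is rejected as
#'   `neuron_not_found`. In practice the threshold is retuned per age class
#'   because neuron brightness changes with age.
#' @param entry_threshold Mean-intensity excess (counts) over background
#'   that signals a worm entering the trap.
#' @param mode `"template"` (correlation matching; gravid worms, Day 5+) or
#'   `"edge"` (gradient/threshold/blob chain; larval to Day 4 worms). See
#'   [mode_for_age()].
#' @param img_width,img_height Frame geometry used to derive default regions.
#' @param search_region,head_region,tail_region,background_region,entry_region
#'   [region()] objects; `NULL` derives defaults from the frame geometry.
#' @param z_range Stage travel (µm).
#' @param brightness_bounds Background-subtracted neuron ROI mean bounds
#'   `c(low, high)` (counts) for [qc_brightness()].
#' @param template_channel Channel the matcher runs on.
#' @param min_blob_px,max_blob_px Blob size bounds for the edge detector.
#' @param min_gradient Minimum absolute Sobel gradient magnitude (counts)
#'   for the edge detector to consider a region structured at all. The Otsu
#'   threshold is relative to the strongest gradient present, so without an
#'   absolute floor a featureless region would yield spurious blobs from
#'   vanishing intensity ripples. The default sits well above the Sobel
#'   response to camera noise and far below any in-focus neuron edge.
#' @param roi_radius Neuron ROI disc radius (px) used for intensity readout.
#' @param track_radius Per-frame tracking search radius (px).
#' @param track_floor Score below which a tracked frame is flagged lost.
#' @return An object of class `"detection_config"`.
#' @export
detection_config <- function(corr_threshold = 0.5, entry_threshold = 50,
                             mode = c("template", "edge"),
                             img_width = 64, img_height = 64,
                             search_region = NULL, head_region = NULL,
                             tail_region = NULL, background_region = NULL,
                             entry_region = NULL,
                             z_range = c(0, 100),
                             brightness_bounds = c(300, 1800),
                             template_channel = c("acceptor", "donor"),
                             min_blob_px = 3, max_blob_px = 400,
                             min_gradient = 100,
                             roi_radius = 3, track_radius = 4,
                             track_floor = 0.2) {
  mode <- match.arg(mode)
  template_channel <- match.arg(template_channel)
  if (corr_threshold < 0 || corr_threshold > 1)
    stop("corr_threshold must lie in [0, 1]")
  if (brightness_bounds[1] >= brightness_bounds[2])
    stop("brightness_bounds must be ordered low < high")
  half <- floor(img_width / 2)
  structure(list(
    corr_threshold = corr_threshold, entry_threshold = entry_threshold,
    mode = mode, img_width = img_width, img_height = img_height,
    head_region = head_region %||% region(0, 0, half, img_height),
    tail_region = tail_region %||% region(half, 0, img_width, img_height),
    search_region = search_region %||% region(0, 0, half, img_height),
    background_region = background_region %||% region(0, 0, img_width, 6),
    entry_region = entry_region %||%
      region(img_width - 12, 6, img_width, img_height),
    z_range = z_range, brightness_bounds = brightness_bounds,
    template_channel = template_channel,
    min_blob_px = min_blob_px, max_blob_px = max_blob_px,
    min_gradient = min_gradient,
    roi_radius = roi_radius, track_radius = track_radius,
    track_floor = track_floor), class = "detection_config")
}

#' Detection mode for an age class
#'
#' Younger worms (larval stages to Day 4 adults) are located by edge
#' detection; gravid worms (Day 5 and older) by correlation template
#' matching.
#'
#' @param age_day Day of adulthood (0 or negative for larval stages).
#' @return `"edge"` or `"template"`.
#' @export
mode_for_age <- function(age_day) if (age_day <= 4) "edge" else "template"

#' Detect a worm entering the trap
#'
#' A worm is present when the mean intensity of the trap entry region
#' exceeds the mean of the background region by more than the threshold.
#'
#' @param frame Single-channel image matrix.
#' @param entry_region,background_region Disjoint [region()]s.
#' @param threshold Entry threshold (counts).
#' @return Logical: worm present.
#' @export
detect_entry <- function(frame, entry_region, background_region, threshold) {
  if (!regions_disjoint(entry_region, background_region))
    stop("entry and background regions must be disjoint")
  mean(crop_region(frame, entry_region)) -
    mean(crop_region(frame, background_region)) > threshold
}

# all-offset zero-normalized cross-correlation of a template against the
# admissible windows of a search region. offsets are template top-left
# positions, 0-based, enumerated row-block-wise (y slow, x fast) so the
# first maximum is the lexicographically smallest (y, x). constant windows
# score 0 by convention.
zncc_scan <- function(image, template, search_region = NULL) {
  tm <- as_template_matrix(template)
  th <- nrow(tm); tw <- ncol(tm)
  rg <- search_region %||% region(0, 0, ncol(image), nrow(image))
  if (rg$x1 > ncol(image) || rg$y1 > nrow(image))
    stop("search region extends outside the image")
  if (region_width(rg) < tw || region_height(rg) < th)
    stop("template larger than search region")
  xs <- rg$x0:(rg$x1 - tw)
  ys <- rg$y0:(rg$y1 - th)
  off <- expand.grid(x = xs, y = ys)          # x varies fastest => (y, x) order
  H <- nrow(image)
  base <- as.vector(outer(seq_len(th), (seq_len(tw) - 1) * H, "+"))
  idx <- outer(base, off$y + off$x * H, "+")
  W <- matrix(image[idx], nrow = th * tw)
  tc <- as.vector(tm) - mean(tm)
  tss <- sum(tc^2)
  WC <- W - rep(colMeans(W), each = th * tw)
  wss <- colSums(WC^2)
  num <- colSums(WC * tc)
  den <- sqrt(wss * tss)
  score <- ifelse(den > 0, num / den, 0)
  list(x = off$x, y = off$y, score = score, tw = tw, th = th)
}

#' Correlation-based template matching (ZNCC)
#'
#' Slides the template over every admissible position of the search region
#' and returns the location maximizing the zero-normalized
#' cross-correlation: both patch and window are mean-subtracted and
#' norm-divided, so scores live in `[-1, 1]` and are invariant to local
#' additive and multiplicative intensity changes. Ties are broken toward
#' the smallest `(y, then x)`. A constant window scores 0 by convention; a
#' constant template is rejected.
#'
#' @param image Single-channel image matrix.
#' @param template A [neuron_template()] or plain matrix, strictly smaller
#'   than the search region.
#' @param search_region Optional [region()]; default is the whole image.
#' @return List with `x`, `y` (0-based top-left of the best match), `cx`,
#'   `cy` (patch center), `score`, and `scores` (all scanned scores).
#' @export
match_template_ncc <- function(image, template, search_region = NULL) {
  s <- zncc_scan(image, template, search_region)
  best <- which.max(s$score)
  list(x = s$x[best], y = s$y[best],
       cx = s$x[best] + (s$tw - 1) / 2, cy = s$y[best] + (s$th - 1) / 2,
       score = s$score[best], scores = s$score)
}

#' Autofocus over a z-stack by per-plane correlation
#'
#' Computes the best ZNCC score of the template within the search region on
#' every plane of a focus stack — one correlation score per stage position.
#' The in-focus plane is the argmax (ties toward the lowest z). If every
#' score falls below the correlation threshold the neuron could not be
#' brought into focus and the worm is rejected (`found = FALSE`, the
#' "neuron not found" state).
#'
#' @param zstack A [channel_stack()] with `axis = "z"` and >= 2 planes.
#' @param template A [neuron_template()] or matrix.
#' @param config A [detection_config()]; uses `search_region`,
#'   `corr_threshold` and `template_channel`.
#' @return List with `found`, `z_index` (1-based plane), `z_um`, `x`, `y`,
#'   `cx`, `cy` (best-match position on the chosen plane) and `scores`
#'   (per-plane score vector, always length = number of planes).
#' @export
autofocus_z <- function(zstack, template, config = detection_config()) {
  stopifnot(inherits(zstack, "channel_stack"))
  if (zstack$axis != "z") stop("autofocus needs a z-axis stack")
  nz <- n_frames(zstack)
  if (nz < 2) stop("need >= 2 planes")
  scores <- numeric(nz)
  pos <- vector("list", nz)
  for (i in seq_len(nz)) {
    m <- match_template_ncc(stack_frame(zstack, i, config$template_channel),
                            template, config$search_region)
    scores[i] <- m$score
    pos[[i]] <- m
  }
  if (all(scores < config$corr_threshold))
    return(list(found = FALSE, z_index = NA_integer_, z_um = NA_real_,
                x = NA_real_, y = NA_real_, cx = NA_real_, cy = NA_real_,
                scores = scores))
  zi <- which.max(scores)
  b <- pos[[zi]]
  list(found = TRUE, z_index = zi, z_um = zstack$z_values_um[zi],
       x = b$x, y = b$y, cx = b$cx, cy = b$cy, scores = scores)
}

#' Edge-detection neuron localization
#'
#' The chain for young worms whose neuron lacks a stable template: Sobel
#' gradient magnitude over the search region, Otsu threshold on the
#' gradient, connected components, then the centroid of the component
#' maximizing total intensity (mean intensity x area) within the configured
#' size bounds.
#'
#' @param image Single-channel image matrix.
#' @param search_region A [region()] at least `min_blob_px` large.
#' @param config A [detection_config()].
#' @return List with `x`, `y` (0-based centroid) and `area`, or `NULL` when
#'   no component passes.
#' @export
detect_neuron_edge <- function(image, search_region = NULL,
                               config = detection_config()) {
  rg <- search_region %||% region(0, 0, ncol(image), nrow(image))
  if (region_width(rg) * region_height(rg) < config$min_blob_px)
    stop("search region smaller than the minimum blob size")
  crop <- crop_region(image, rg)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(crop, kx)
  gy <- EBImage::filter2(crop, t(kx))
  grad <- sqrt(gx^2 + gy^2)
  gmax <- max(grad)
  if (gmax <= config$min_gradient) return(NULL)
  g01 <- grad / gmax
  thr <- EBImage::otsu(g01, range = c(0, 1))
  mask <- EBImage::fillHull(g01 > thr)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(NULL)
  best <- NULL; best_score <- -Inf
  for (l in seq_len(nlab)) {
    sel <- which(lab == l, arr.ind = TRUE)
    area <- nrow(sel)
    if (area < config$min_blob_px || area > config$max_blob_px) next
    score <- sum(crop[sel])                   # mean intensity x area
    if (score > best_score) {
      best_score <- score
      best <- list(x = mean(sel[, 2]) - 1 + rg$x0,
                   y = mean(sel[, 1]) - 1 + rg$y0, area = area)
    }
  }
  best
}

#' Head/tail orientation from the labeled neuron
#'
#' Runs the configured detector in the head-side region; success means the
#' worm was loaded head-first. Otherwise the tail-side region is tried
#' (tail entry, to be discarded); otherwise no neuron is detectable.
#'
#' @param x A single image matrix, or a z-axis [channel_stack()] (the
#'   detector then runs per plane via [autofocus_z()]).
#' @param template Template for `mode = "template"`.
#' @param config A [detection_config()]; supplies the disjoint
#'   `head_region`/`tail_region`, the mode and the threshold.
#' @return `"head"`, `"tail"` or `"none"`.
#' @export
classify_orientation <- function(x, template = NULL,
                                 config = detection_config()) {
  if (!regions_disjoint(config$head_region, config$tail_region))
    stop("head and tail regions must be disjoint")
  hit <- function(rg) {
    if (inherits(x, "channel_stack")) {
      cfg <- config; cfg$search_region <- rg
      autofocus_z(x, template, cfg)$found
    } else if (config$mode == "template") {
      match_template_ncc(x, template, rg)$score >= config$corr_threshold
    } else {
      !is.null(detect_neuron_edge(x, rg, config))
    }
  }
  if (hit(config$head_region)) "head"
  else if (hit(config$tail_region)) "tail"
  else "none"
}

#' Brightness quality control
#'
#' Worms that are too bright or too dim do not elicit measurable responses
#' and are discarded before recording.
#'
#' @param intensity Background-subtracted neuron ROI mean intensity (counts).
#' @param bounds Ordered `c(low, high)` bounds.
#' @return `"too_dim"`, `"pass"` or `"too_bright"`.
#' @export
qc_brightness <- function(intensity, bounds = c(300, 1800)) {
  if (bounds[1] >= bounds[2]) stop("bounds must be ordered low < high")
  if (intensity < bounds[1]) "too_dim"
  else if (intensity > bounds[2]) "too_bright"
  else "pass"
}
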