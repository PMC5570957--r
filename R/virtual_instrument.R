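#' Scene parameters for the virtual instrument
#'
#' Describes a trapped worm's head with a single fluorescently labeled
#' neuron, as rendered by [render_frame()]. The neuron is an isotropic 2-D
#' Gaussian spot whose width grows linearly with defocus while its total
#' flux is conserved (energy-preserving blur), superimposed on a uniform
#' worm-body autofluorescence floor.
#'
#' Default brightnesses split a total baseline flux between the channels in
#' proportion to the resting acceptor/donor ratio, so `acceptor_peak /
#' donor_peak` equals the baseline ratio of the kinetics used with the scene.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size_um Pixel size (µm/px).
#' @param neuron_x,neuron_y Neuron center, 0-based pixel coordinates
#'   (x = column, y = row).
#' @param z_true_um True focal position of the neuron within the stage range
#'   (µm); must lie inside `z_range`.
#' @param donor_peak,acceptor_peak In-focus peak brightness per channel at
#'   baseline ratio, before expression scaling (counts).
#' @param psf_sigma_px Gaussian spot sigma at perfect focus (px).
#' @param defocus_coef Spot-sigma growth per micrometre of defocus (px/µm).
#' @param autofluor Uniform worm-body autofluorescence level (counts).
#' @param orientation `"head_first"` or `"tail_first"`. By contract the
#'   neuron of a tail-first worm sits in the tail-side half of the frame.
#' @param viability `"alive"` or `"dead"`. Dead worms respond with zero
#'   amplitude.
#' @param expression Sensor expression class: `"dim"`, `"normal"` or
#'   `"bright"`; scales both channel brightnesses by `expression_scales`.
#' @param expression_scales Named multipliers for the three expression
#'   classes.
#' @param z_range Configured stage travel (µm).
#' @return An object of class `"scene_params"`.
#' @export
scene_params <- function(width = 64, height = 64, pixel_size_um = 0.4,
                         neuron_x = 18, neuron_y = 32, z_true_um = 50,
                         donor_peak = 960, acceptor_peak = 1440,
                         psf_sigma_px = 1.8, defocus_coef = 0.25,
                         autofluor = 80,
                         orientation = c("head_first", "tail_first"),
                         viability = c("alive", "dead"),
                         expression = c("normal", "dim", "bright"),
                         expression_scales = c(dim = 0.25, normal = 1, bright = 4),
                         z_range = c(0, 100)) {
  orientation <- match.arg(orientation)
  viability <- match.arg(viability)
  expression <- match.arg(expression)
  if (z_true_um < z_range[1] || z_true_um > z_range[2])
    stop("z_true_um must lie within z_range")
  if (donor_peak < 0 || acceptor_peak < 0 || autofluor < 0)
    stop("brightness must be >= 0")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (defocus_coef < 0) stop("defocus_coef must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size_um = pixel_size_um,
                 neuron_x = neuron_x, neuron_y = neuron_y,
                 z_true_um = z_true_um,
                 donor_peak = donor_peak, acceptor_peak = acceptor_peak,
                 psf_sigma_px = psf_sigma_px, defocus_coef = defocus_coef,
                 autofluor = autofluor, orientation = orientation,
                 viability = viability, expression = expression,
                 expression_scale = unname(expression_scales[expression]),
                 z_range = z_range),
            class = "scene_params")
}

#' Random scene for a loaded worm
#'
#' Draws neuron position and true focus uniformly. Head-first worms carry
#' the neuron in the left (head-side) half of the frame, tail-first worms in
#' the right half; the margins keep the spot and its search window inside
#' the frame.
#'
#' @param orientation,viability,expression Passed to [scene_params()].
#' @param z_band Range from which `z_true_um` is drawn (µm).
#' @param ... Further arguments to [scene_params()].
#' @return A [scene_params()] object.
#' @export
random_scene <- function(orientation = c("head_first", "tail_first"),
                         viability = "alive", expression = "normal",
                         z_band = c(20, 80), ...) {
  orientation <- match.arg(orientation)
  x <- if (orientation == "head_first") stats::runif(1, 10, 26)
       else stats::runif(1, 38, 54)
  scene_params(neuron_x = x, neuron_y = stats::runif(1, 20, 44),
               z_true_um = stats::runif(1, z_band[1], z_band[2]),
               orientation = orientation, viability = viability,
               expression = expression, ...)
}

#' Per-channel exponential photobleaching model
#'
#' Channel intensity envelopes decay as `I(t) = I0 * exp(-lambda * t)`.
#'
#' @param lambda_donor,lambda_acceptor Bleach rates (1/s, >= 0).
#' @return An object of class `"bleach_model"`.
#' @export
bleach_model <- function(lambda_donor = 0.004, lambda_acceptor = 0.002) {
  if (lambda_donor < 0 || lambda_acceptor < 0) stop("bleach rates must be >= 0")
  structure(list(lambda_donor = lambda_donor,
                 lambda_acceptor = lambda_acceptor),
            class = "bleach_model")
}

#' Recording protocol timing
#'
#' One load-focus-stimulate-record-unload cycle. The defaults reproduce a
#' 100 s per-worm protocol: 5 s loading, 40 s pre-stimulation exposure to
#' settle the calcium baseline, 50 s of stimulation/recording containing a
#' 30 s stimulus pulse, and 5 s unloading.
#'
#' @param load_s,prestim_s,record_s,unload_s Phase durations (s).
#' @param stim_pulse_s Stimulus pulse duration (s); the pulse starts at the
#'   end of the pre-stimulation phase and must fit inside the recording.
#' @param frame_interval_s Camera frame interval (s).
#' @return An object of class `"protocol_timing"`.
#' @export
protocol_timing <- function(load_s = 5, prestim_s = 40, record_s = 50,
                            unload_s = 5, stim_pulse_s = 30,
                            frame_interval_s = 1) {
  vals <- c(load_s, prestim_s, record_s, unload_s, stim_pulse_s,
            frame_interval_s)
  if (any(vals < 0)) stop("durations must be >= 0")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (stim_pulse_s > record_s)
    stop("stimulus pulse must lie inside the recording window")
  structure(list(load_s = load_s, prestim_s = prestim_s, record_s = record_s,
                 unload_s = unload_s, stim_pulse_s = stim_pulse_s,
                 frame_interval_s = frame_interval_s),
            class = "protocol_timing")
}

#' Camera noise configuration
#'
#' Poisson shot noise on the expected counts plus additive Gaussian read
#' noise; noisy frames are quantized to integer counts as a real camera
#' would. With `enabled = FALSE` frames carry the exact expected counts
#' (continuous values), which the construction-identity tests rely on.
#'
#' @param enabled Logical; turn all noise off for ideal frames.
#' @param read_sd Read-noise standard deviation (counts).
#' @return An object of class `"noise_config"`.
#' @export
noise_config <- function(enabled = TRUE, read_sd = 6) {
  if (read_sd < 0) stop("read_sd must be >= 0")
  structure(list(enabled = isTRUE(enabled), read_sd = read_sd),
            class = "noise_config")
}

#' Render one dual-channel frame
#'
#' The neuron is rendered as a 2-D Gaussian of sigma
#' `psf_sigma_px + defocus_coef * |z_offset|`; defocus conserves total spot
#' flux, so the peak amplitude falls as `(sigma_focus / sigma_z)^2`.
#' Channel amplitudes are further scaled by per-channel `bleach_factor` and
#' `channel_scale`; geometry is identical in both channels.
#'
#' @param scene A [scene_params()] object.
#' @param z_offset Stage position minus true focus (µm).
#' @param bleach_factor Named per-channel multipliers `c(donor=, acceptor=)`.
#' @param channel_scale Named per-channel multipliers (e.g. the
#'   donor/acceptor partition of the instantaneous FRET ratio).
#' @param noise A [noise_config()].
#' @param seed Optional integer; when given, the frame is rendered under
#'   `set.seed(seed)` so identical calls are bit-identical.
#' @return List with `donor` and `acceptor` `height x width` matrices.
#' @export
render_frame <- function(scene, z_offset = 0,
                         bleach_factor = c(donor = 1, acceptor = 1),
                         channel_scale = c(donor = 1, acceptor = 1),
                         noise = noise_config(), seed = NULL) {
  stopifnot(inherits(scene, "scene_params"))
  if (!is.null(seed)) set.seed(seed)
  sigma <- scene$psf_sigma_px + scene$defocus_coef * abs(z_offset)
  if (sigma <= 0) stop("spot width must be > 0")
  amp_z <- (scene$psf_sigma_px / sigma)^2
  gx <- exp(-((seq_len(scene$width) - 1 - scene$neuron_x)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(scene$height) - 1 - scene$neuron_y)^2) / (2 * sigma^2))
  spot <- outer(gy, gx)                       # height x width
  out <- list()
  for (ch in c("donor", "acceptor")) {
    peak <- scene[[paste0(ch, "_peak")]] * scene$expression_scale
    expected <- scene$autofluor +
      peak * channel_scale[[ch]] * bleach_factor[[ch]] * amp_z * spot
    if (noise$enabled) {
      counts <- stats::rpois(length(expected), lambda = expected) +
        stats::rnorm(length(expected), sd = noise$read_sd)
      counts <- round(pmin(pmax(counts, 0), 65535))
      expected <- matrix(counts, nrow = scene$height)
    }
    out[[ch]] <- expected
  }
  out
}

#' Cut a neuron template from an ideal in-focus rendering
#'
#' Renders the scene's neuron noise-free and in focus, then cuts a square
#' patch of the acceptor channel centred on it — the software equivalent of
#' drawing a box around the focused neuron of a training worm.
#'
#' @param scene A [scene_params()] object.
#' @param size Odd patch side length (px).
#' @param channel Channel to cut the patch from.
#' @return A `size x size` matrix of counts.
#' @export
make_template <- function(scene = scene_params(), size = 9,
                          channel = c("acceptor", "donor")) {
  channel <- match.arg(channel)
  if (size %% 2 == 0) stop("template size must be odd")
  fr <- render_frame(scene, z_offset = 0, noise = noise_config(FALSE))[[channel]]
  cy <- round(scene$neuron_y); cx <- round(scene$neuron_x)
  h <- (size - 1) / 2
  if (cy - h < 0 || cx - h < 0 ||
      cy + h >= scene$height || cx + h >= scene$width)
    stop("template does not fit around the neuron")
  fr[(cy - h + 1):(cy + h + 1), (cx - h + 1):(cx + h + 1)]
}

# donor/acceptor partition of a ratio series: total flux is bleach-only.
# donor_scale * donor_peak and acceptor_scale * acceptor_peak give channel
# amplitudes whose ratio equals r at every sample when
# acceptor_peak/donor_peak = R0.
ratio_partition <- function(r, R0) {
  list(donor = (1 + R0) / (1 + r),
       acceptor = (r / R0) * (1 + R0) / (1 + r))
}

#' Simulate one worm session (z-stack + recording) with ground truth
#'
#' Emulates one load-focus-stimulate-record cycle: a focus stack swept over
#' `z_plan` at the pre-bleach state, then a time-series recording at the
#' true focal plane. Channel amplitudes follow a donor/acceptor partition of
#' the ideal ratio — the acceptor/donor ratio equals [ideal_ratio()] before
#' noise — each multiplied by its exponential bleach envelope. Dead worms
#' respond with zero amplitude.
#'
#' The stimulus window is aligned to the protocol: onset at `prestim_s`,
#' offset `stim_pulse_s` later, overriding the kinetics' own `t_on`/`t_off`.
#'
#' @param scene A [scene_params()] object.
#' @param kinetics A [response_kinetics()] object.
#' @param bleach A [bleach_model()].
#' @param timing A [protocol_timing()].
#' @param z_plan Stage positions for the focus stack (µm); must span the
#'   scene's z-range with at least 2 planes.
#' @param noise A [noise_config()].
#' @param seed Optional integer seed for reproducible rendering.
#' @return List with `zstack` and `timeseries` ([channel_stack()] objects)
#'   and `truth`, the per-worm ground-truth record.
#' @export
simulate_worm_session <- function(scene = scene_params(),
                                  kinetics = response_kinetics(),
                                  bleach = bleach_model(),
                                  timing = protocol_timing(),
                                  z_plan = seq(0, 100, by = 5),
                                  noise = noise_config(), seed = NULL) {
  stopifnot(inherits(scene, "scene_params"),
            inherits(kinetics, "response_kinetics"))
  if (length(z_plan) < 2) stop("z_plan needs at least 2 planes")
  if (!is.null(seed)) set.seed(seed)

  k <- kinetics
  k$t_on <- timing$prestim_s
  k$t_off <- timing$prestim_s + timing$stim_pulse_s
  if (scene$viability == "dead") k$A <- 0

  h <- scene$height; w <- scene$width

  # focus stack: all planes share the t = 0 bleach state and baseline ratio
  nz <- length(z_plan)
  zd <- array(0, c(nz, h, w)); za <- zd
  for (i in seq_len(nz)) {
    fr <- render_frame(scene, z_offset = z_plan[i] - scene$z_true_um,
                       noise = noise)
    zd[i, , ] <- fr$donor; za[i, , ] <- fr$acceptor
  }
  zstack <- channel_stack(zd, za, axis = "z", z_values_um = z_plan,
                          pixel_size_um = scene$pixel_size_um)

  # recording at the focal plane
  nt <- floor((timing$prestim_s + timing$record_s) / timing$frame_interval_s)
  times <- (seq_len(nt) - 1) * timing$frame_interval_s
  ratio <- ideal_ratio(k, times)
  part <- ratio_partition(ratio, k$R0)
  td <- array(0, c(nt, h, w)); ta <- td
  for (i in seq_len(nt)) {
    bf <- c(donor = exp(-bleach$lambda_donor * times[i]),
            acceptor = exp(-bleach$lambda_acceptor * times[i]))
    cs <- c(donor = part$donor[i], acceptor = part$acceptor[i])
    fr <- render_frame(scene, z_offset = 0, bleach_factor = bf,
                       channel_scale = cs, noise = noise)
    td[i, , ] <- fr$donor; ta[i, , ] <- fr$acceptor
  }
  timeseries <- channel_stack(td, ta, axis = "time",
                              frame_interval_s = timing$frame_interval_s,
                              pixel_size_um = scene$pixel_size_um,
                              stim_window = c(k$t_on, k$t_off))

  truth <- list(
    neuron_x = scene$neuron_x, neuron_y = scene$neuron_y,
    z_true_um = scene$z_true_um,
    z_plane = which.min(abs(z_plan - scene$z_true_um)),
    orientation = scene$orientation, viability = scene$viability,
    expression = scene$expression,
    R0 = k$R0, A = k$A, tau_rise = k$tau_rise, tau_decay = k$tau_decay,
    t_on = k$t_on, t_off = k$t_off,
    lambda_donor = bleach$lambda_donor,
    lambda_acceptor = bleach$lambda_acceptor,
    true_peak_pct = peak_percent(k))

  list(zstack = zstack, timeseries = timeseries, truth = truth)
}
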