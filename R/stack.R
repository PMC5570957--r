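#' Dual-channel image stack
#'
#' The unit of data the instrument produces per worm: a donor-channel and an
#' acceptor-channel array of frames sharing geometry and acquisition
#' metadata. The frame axis is either time (a recording) or z (a focus
#' stack); the axis kind is set exactly once at construction.
#'
#' @param donor,acceptor Numeric arrays of dimension `frames x height x
#'   width` with non-negative counts; both channels must share a shape.
#' @param axis `"time"` or `"z"`.
#' @param frame_interval_s Frame interval in seconds (time axis only).
#' @param z_values_um Stage positions in micrometres, one per frame
#'   (z axis only).
#' @param pixel_size_um Pixel size (µm/px).
#' @param exposure_ms Camera exposure (ms); metadata only.
#' @param stim_window Optional `c(t_on, t_off)` stimulus window in seconds.
#' @return An object of class `"channel_stack"`.
#' @export
channel_stack <- function(donor, acceptor, axis = c("time", "z"),
                          frame_interval_s = NULL, z_values_um = NULL,
                          pixel_size_um = 0.4, exposure_ms = 80,
                          stim_window = NULL) {
  axis <- match.arg(axis)
  if (!identical(dim(donor), dim(acceptor)))
    stop("donor and acceptor channels must share shape")
  if (length(dim(donor)) != 3) stop("expected frames x height x width arrays")
  if (min(donor) < 0 || min(acceptor) < 0) stop("counts must be non-negative")
  if (axis == "time" && is.null(frame_interval_s))
    stop("time-axis stacks need frame_interval_s")
  if (axis == "z") {
    if (is.null(z_values_um)) stop("z-axis stacks need z_values_um")
    if (length(z_values_um) != dim(donor)[1])
      stop("z_values_um must have one value per frame")
  }
  structure(list(donor = donor, acceptor = acceptor, axis = axis,
                 frame_interval_s = frame_interval_s,
                 z_values_um = z_values_um,
                 pixel_size_um = pixel_size_um, exposure_ms = exposure_ms,
                 stim_window = stim_window),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("<channel_stack axis=%s frames=%d %dx%d px>\n",
              x$axis, d[1], d[2], d[3]))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [channel_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$donor)[1]

#' Extract one frame of one channel as a matrix
#' @param stack A [channel_stack()].
#' @param i Frame index (1-based).
#' @param channel `"donor"` or `"acceptor"`.
#' @return A `height x width` matrix.
#' @export
stack_frame <- function(stack, i, channel = c("acceptor", "donor")) {
  channel <- match.arg(channel)
  stack[[channel]][i, , ]
}

#' Time base of a time-axis stack
#' @param stack A [channel_stack()] with `axis = "time"`.
#' @return Numeric vector of frame times (s), starting at 0.
#' @export
stack_times <- function(stack) {
  if (stack$axis != "time") stop("not a time-axis stack")
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s
}
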