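#' Write / read a dual-channel stack as multi-page TIFF + JSON sidecar
#'
#' The TIFF dialect is plain multi-page 16-bit grayscale with pages
#' interleaved donor-first (page 2k-1 = donor frame k, page 2k = acceptor
#' frame k); counts are clamped to `[0, 65535]` and rounded on write.
#' Acquisition metadata travels in a JSON sidecar; a sidecar missing a
#' required field is a hard error naming the field.
#'
#' @param stack A [channel_stack()].
#' @param tif_path Path of the multi-page TIFF.
#' @param meta_path Path of the JSON sidecar; defaults to the TIFF path with
#'   a `.json` extension.
#' @return `read_stack()` returns the reconstructed [channel_stack()].
#' @export
write_stack <- function(stack, tif_path, meta_path = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  meta_path <- meta_path %||% sub("\\.tiff?$", ".json", tif_path)
  n <- n_frames(stack)
  pages <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    pages[[2 * i - 1]] <- round(pmin(pmax(stack$donor[i, , ], 0), 65535)) / 65535
    pages[[2 * i]] <- round(pmin(pmax(stack$acceptor[i, , ], 0), 65535)) / 65535
  }
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 16,
                  compression = "none")
  meta <- list(axis = stack$axis, pixel_size_um = stack$pixel_size_um,
               exposure_ms = stack$exposure_ms,
               channels = c("donor", "acceptor"),
               page_order = "donor_first",
               frame_interval_s = stack$frame_interval_s,
               z_values_um = stack$z_values_um,
               stim_window = stack$stim_window)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], meta_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_stack
#' @export
read_stack <- function(tif_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.tiff?$", ".json", tif_path)
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("axis", "pixel_size_um"))
    if (is.null(meta[[f]])) stop("sidecar lacks required field: ", f)
  if (meta$axis == "time" && is.null(meta$frame_interval_s))
    stop("sidecar lacks required field: frame_interval_s")
  if (meta$axis == "z" && is.null(meta$z_values_um))
    stop("sidecar lacks required field: z_values_um")
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (length(pages) %% 2 != 0)
    stop("odd page count: expected donor/acceptor interleaved pages")
  n <- length(pages) / 2
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  donor <- array(0, c(n, h, w)); acceptor <- donor
  for (i in seq_len(n)) {
    donor[i, , ] <- round(pages[[2 * i - 1]] * 65535)
    acceptor[i, , ] <- round(pages[[2 * i]] * 65535)
  }
  channel_stack(donor, acceptor, axis = meta$axis,
                frame_interval_s = meta$frame_interval_s,
                z_values_um = meta$z_values_um,
                pixel_size_um = meta$pixel_size_um,
                exposure_ms = meta$exposure_ms %||% 80,
                stim_window = meta$stim_window)
}

#' Write / read a template patch as TIFF
#'
#' @param template Matrix or [neuron_template()].
#' @param path TIFF path.
#' @return `read_template()` returns a [neuron_template()].
#' @export
write_template <- function(template, path) {
  m <- as_template_matrix(template)
  tiff::writeTIFF(round(pmin(pmax(m, 0), 65535)) / 65535, path,
                  bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  neuron_template(round(tiff::readTIFF(path) * 65535),
                  note = paste("read from", basename(path)))
}

#' Write one simulated worm session to a directory
#'
#' Produces `zstack.tif`, `timeseries.tif`, a shared `meta.json` (both
#' sidecars under `zstack`/`timeseries` keys) and `truth.json`.
#'
#' @param session A [simulate_worm_session()] result.
#' @param dir Output directory (created).
#' @return `read_worm_session()` returns a list with `zstack`, `timeseries`,
#'   `truth`.
#' @export
write_worm_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(session$zstack, file.path(dir, "zstack.tif"),
              file.path(dir, "zstack.json"))
  write_stack(session$timeseries, file.path(dir, "timeseries.tif"),
              file.path(dir, "timeseries.json"))
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_worm_session
#' @export
read_worm_session <- function(dir) {
  list(zstack = read_stack(file.path(dir, "zstack.tif"),
                           file.path(dir, "zstack.json")),
       timeseries = read_stack(file.path(dir, "timeseries.tif"),
                               file.path(dir, "timeseries.json")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
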