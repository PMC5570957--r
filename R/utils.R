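#' Rectangular image region
#'
#' Regions are half-open rectangles in 0-based pixel coordinates with
#' `x` = column and `y` = row, origin at the top-left: a region covers
#' columns `[x0, x1)` and rows `[y0, y1)`.
#'
#' @param x0,y0 Inclusive top-left corner (0-based).
#' @param x1,y1 Exclusive bottom-right corner.
#' @return An object of class `"nsc_region"`.
#' @export
region <- function(x0, y0, x1, y1) {
  stopifnot(length(x0) == 1, length(y0) == 1, length(x1) == 1, length(y1) == 1)
  if (x1 <= x0 || y1 <= y0) stop("empty region: need x1 > x0 and y1 > y0")
  if (x0 < 0 || y0 < 0) stop("region coordinates must be >= 0")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "nsc_region")
}

#' @export
print.nsc_region <- function(x, ...) {
  cat(sprintf("<region x=[%d,%d) y=[%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

region_width  <- function(rg) rg$x1 - rg$x0
region_height <- function(rg) rg$y1 - rg$y0

# extract the pixels of a region from a height x width matrix
crop_region <- function(img, rg) {
  if (rg$x1 > ncol(img) || rg$y1 > nrow(img))
    stop("region extends outside the image")
  img[(rg$y0 + 1):rg$y1, (rg$x0 + 1):rg$x1, drop = FALSE]
}

regions_disjoint <- function(a, b) {
  a$x1 <= b$x0 || b$x1 <= a$x0 || a$y1 <= b$y0 || b$y1 <= a$y0
}

# boolean disc mask centred on (cx, cy) (0-based pixel coords) of given
# radius; returns the matrix of covered (row, col) 1-based indices
disc_pixels <- function(cx, cy, radius, height, width) {
  r0 <- max(0L, floor(cy - radius)); r1 <- min(height - 1L, ceiling(cy + radius))
  c0 <- max(0L, floor(cx - radius)); c1 <- min(width  - 1L, ceiling(cx + radius))
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each  = r1 - r0 + 1L)
  keep <- (rows - cy)^2 + (cols - cx)^2 <= radius^2
  cbind(row = rows[keep] + 1L, col = cols[keep] + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard error of the mean; NA for n < 2
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
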