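#' Ratiometric image stack
#'
#' Container for a time-ordered stack of 2-D ratio images (e.g. mKate2/mKOk
#' FRET ratio representing PKA activity), together with the physical metadata
#' needed downstream: pixel size in micrometres per pixel and frame interval
#' in minutes. Invalid pixels (for example where the denominator channel fell
#' to or below the background level) are stored as `NA` and excluded from all
#' downstream statistics.
#'
#' Frames are indexed `[row, col, frame]`. Physical coordinates are in
#' micrometres with the origin at the centre of the top-left pixel, so a pixel
#' at `[i, j]` sits at `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`.
#' Time is in minutes with frame 1 at `t = 0`.
#'
#' @param frames 3-D numeric array `[row, col, frame]` of ratio values; all
#'   finite values must be positive, `NA` marks invalid pixels.
#' @param pixel_size Pixel size, um/px (> 0).
#' @param frame_interval Frame interval, min (> 0).
#' @param provenance `"raw"` or `"normalized"` (after minimum-projection
#'   normalization).
#' @return An object of class `ratio_stack`.
#' @export
ratio_stack <- function(frames, pixel_size, frame_interval,
                        provenance = c("raw", "normalized")) {
  provenance <- match.arg(provenance)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array [row, col, frame]")
  if (dim(frames)[3] < 2L)
    stop("a ratio stack needs at least 2 frames")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (min)")
  v <- frames[is.finite(frames)]
  if (length(v) == 0L)
    stop("all pixels are invalid")
  if (any(v <= 0))
    stop("ratio values must be positive (use NA for invalid pixels)")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, provenance = provenance),
    class = "ratio_stack")
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "ratio_stack: %d x %d px, %d frames (%s)\n  pixel size %.3g um/px, frame interval %.3g min, field %.3g x %.3g um, %.3g min\n",
    d[1], d[2], d[3], x$provenance, x$pixel_size, x$frame_interval,
    d[2] * x$pixel_size, d[1] * x$pixel_size, (d[3] - 1) * x$frame_interval))
  invisible(x)
}

#' Frame acquisition times of a stack
#'
#' @param stack A `ratio_stack`.
#' @return Numeric vector of times in minutes, frame 1 at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - 1) * stack$frame_interval
}

# squared distance (um^2) of every pixel from a physical point c(x, y)
pixel_dist2 <- function(nrow, ncol, pixel_size, center) {
  xs <- (seq_len(ncol) - 1) * pixel_size
  ys <- (seq_len(nrow) - 1) * pixel_size
  outer((ys - center[2])^2, (xs - center[1])^2, `+`)
}
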