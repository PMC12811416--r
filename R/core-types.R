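#' Spatial and temporal calibration of an acquisition
#'
#' Bundles the physical pixel size (per axis, in micrometers) and, for
#' time-lapse movies, the frame interval in seconds. Every physical-unit
#' quantity in the package (micrometers, seconds, square micrometers) is
#' derived solely through a `calibration` object, so setting both pixel
#' sizes and the frame interval to 1 makes all outputs numerically equal
#' to pixel/frame quantities.
#'
#' @param pixel_size_x_um Micrometers per pixel along x (columns). Must be
#'   strictly positive.
#' @param pixel_size_y_um Micrometers per pixel along y (rows). Defaults to
#'   the x pixel size (isotropic sampling).
#' @param frame_interval_s Seconds per frame for movies; `NULL` for still
#'   images. Any movie-time conversion requires it to be present.
#' @return An object of class `calibration`.
#' @examples
#' calibration(0.2)                      # isotropic still image, 0.2 um/px
#' calibration(0.1, frame_interval_s = 0.5)  # 2 fps movie
#' @export
calibration <- function(pixel_size_x_um,
                        pixel_size_y_um = pixel_size_x_um,
                        frame_interval_s = NULL) {
  stopifnot(is.numeric(pixel_size_x_um), length(pixel_size_x_um) == 1L,
            is.numeric(pixel_size_y_um), length(pixel_size_y_um) == 1L)
  if (!is.finite(pixel_size_x_um) || pixel_size_x_um <= 0 ||
      !is.finite(pixel_size_y_um) || pixel_size_y_um <= 0)
    stop("pixel sizes must be strictly positive and finite")
  if (!is.null(frame_interval_s)) {
    stopifnot(is.numeric(frame_interval_s), length(frame_interval_s) == 1L)
    if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
      stop("frame_interval_s must be strictly positive and finite")
  }
  structure(list(pixel_size_x_um = as.numeric(pixel_size_x_um),
                 pixel_size_y_um = as.numeric(pixel_size_y_um),
                 frame_interval_s = if (is.null(frame_interval_s)) NULL
                                    else as.numeric(frame_interval_s)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g x %g um/px", x$pixel_size_x_um,
              x$pixel_size_y_um))
  if (!is.null(x$frame_interval_s))
    cat(sprintf(", %g s/frame", x$frame_interval_s))
  cat("\n")
  invisible(x)
}

is_calibration <- function(x) inherits(x, "calibration")

# Fails unless x/y pixel sizes are equal; ops that measure along oblique
# paths in pixel steps (Sholl arcs, skeletons, profile sampling) need this.
require_isotropic <- function(cal, what = "this operation") {
  if (abs(cal$pixel_size_x_um - cal$pixel_size_y_um) >
      1e-12 * cal$pixel_size_x_um)
    stop(what, " requires isotropic pixel calibration (got ",
         cal$pixel_size_x_um, " x ", cal$pixel_size_y_um, " um/px)")
  cal$pixel_size_x_um
}

require_frame_interval <- function(cal) {
  if (is.null(cal$frame_interval_s))
    stop("calibration has no frame_interval_s; required for movie-time ",
         "conversions")
  cal$frame_interval_s
}

#' Calibrated 2-D grayscale image
#'
#' A thin container around a numeric matrix of intensities (arbitrary
#' units) plus its [calibration()]. The raster convention throughout the
#' package: x = column, y = row, origin at the top-left pixel, y increasing
#' downward; pixel centers sit at integer coordinates starting at 1.
#'
#' @param values Numeric matrix, at least 2x2, finite, nonnegative.
#' @param calibration A [calibration()] object.
#' @return Object of class `image2d` with fields `values` and `calibration`.
#' @export
image2d <- function(values, calibration) {
  stopifnot(is.matrix(values), is_calibration(calibration))
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("image must be at least 2x2")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("image values must all be finite")
  if (any(values < 0))
    stop("image values must be nonnegative")
  structure(list(values = values, calibration = calibration),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, range [%g, %g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Calibrated binary mask
#'
#' @param values Logical matrix (or coercible 0/1 numeric), same shape
#'   contract as [image2d()].
#' @param calibration A [calibration()] object.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, calibration) {
  stopifnot(is.matrix(values), is_calibration(calibration))
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("mask must be at least 2x2")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1")
    values <- values > 0
  }
  structure(list(values = values, calibration = calibration),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Calibrated time-lapse movie
#'
#' Frames are stored as a 3-D array indexed `[row, col, frame]`; all frames
#' share one shape and one calibration. The duration convention is
#' `total_time_s = n_frames * frame_interval_s`, so a 3-minute acquisition
#' at 2 frames per second is 360 frames spanning 180 s.
#'
#' @param frames Numeric 3-D array `[row, col, frame]` with at least two
#'   frames, or a list of equally shaped matrices.
#' @param calibration A [calibration()] with a frame interval.
#' @return Object of class `movie` with fields `frames`, `calibration`.
#' @export
movie <- function(frames, calibration) {
  stopifnot(is_calibration(calibration))
  require_frame_interval(calibration)
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all frames must have identical shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2L)
    stop("a movie needs at least 2 frames")
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames)))
    stop("movie values must all be finite")
  structure(list(frames = frames, calibration = calibration),
            class = "movie")
}

#' Number of frames of a movie
#' @param m A [movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(m) {
  stopifnot(inherits(m, "movie"))
  dim(m$frames)[3]
}

#' Total acquisition time of a movie in seconds
#'
#' Uses the convention `n_frames * frame_interval_s` (360 frames at 0.5 s
#' span 180 s).
#' @param m A [movie()].
#' @return Duration in seconds.
#' @export
total_time_s <- function(m) {
  n_frames(m) * require_frame_interval(m$calibration)
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie> %d x %d px, %d frames, %g s\n",
              dim(x$frames)[1], dim(x$frames)[2], n_frames(x),
              total_time_s(x)))
  invisible(x)
}

#' Polyline region of interest
#'
#' An ordered open polyline in pixel coordinates with a sampling width in
#' micrometers, used for axial intensity profiles and kymograph lines
#' (the acquisition protocol draws a 1-um-wide segmented line).
#'
#' @param vertices Two-column matrix or data.frame of (x, y) pixel
#'   coordinates, at least two rows, consecutive vertices distinct.
#' @param width_um Sampling width in micrometers (> 0), default 1.
#' @return Object of class `polyline_roi`.
#' @export
polyline_roi <- function(vertices, width_um = 1) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, is.numeric(vertices))
  colnames(vertices) <- c("x", "y")
  if (nrow(vertices) < 2L)
    stop("a polyline needs at least 2 vertices")
  if (!all(is.finite(vertices)))
    stop("vertices must be finite")
  d <- diff(vertices)
  if (any(rowSums(d^2) == 0))
    stop("consecutive vertices must be distinct")
  stopifnot(is.numeric(width_um), length(width_um) == 1L)
  if (!is.finite(width_um) || width_um <= 0)
    stop("width_um must be strictly positive")
  structure(list(vertices = vertices, width_um = as.numeric(width_um)),
            class = "polyline_roi")
}

#' @export
print.polyline_roi <- function(x, ...) {
  cat(sprintf("<polyline_roi> %d vertices, width %g um\n",
              nrow(x$vertices), x$width_um))
  invisible(x)
}

# Path length of a polyline in pixels (isotropic pixel units).
roi_path_length_px <- function(roi) {
  d <- diff(roi$vertices)
  sum(sqrt(rowSums(d^2)))
}
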