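# File I/O: TIFF images and movies, polyline ROIs, result tables.
#
# Reading goes through tiff::readTIFF, which returns integer TIFFs at
# their stored values (as.is) and IEEE-float TIFFs verbatim. Writing uses
# a minimal uncompressed grayscale 32-bit-float TIFF writer because the
# tiff package only stores integer sample formats; float32 storage is what
# makes write/read round trips exact after the float cast.

# ---- float32 TIFF writer -------------------------------------------------

# Write one IFD + strip for a matrix; pages chained for multi-page files.
# Little-endian, one strip per page, SampleFormat = IEEE float.
write_float_tiff <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: per page, pixel data then its IFD
  sizes <- vapply(pages, function(m) 4L * nrow(m) * ncol(m), 1L)
  data_offsets <- 8L + cumsum(c(0L, (sizes + ifd_size)[-length(sizes)]))
  ifd_offsets <- data_offsets + sizes
  writeBin(ifd_offsets[1], con, size = 4, endian = "little")
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    stopifnot(is.matrix(m))
    h <- nrow(m); w <- ncol(m)
    data_off <- data_offsets[i]
    # row-major pixel data
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3L) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)            # ImageWidth
    entry(257L, 4L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)     # StripOffsets
    entry(278L, 4L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, 4L * h * w)   # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    # offset of next IFD (0 terminates)
    next_off <- if (i < length(pages)) ifd_offsets[i + 1L] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

# readTIFF with integer values preserved; float pages come back verbatim.
read_tiff_raw <- function(path, all = FALSE) {
  tryCatch(tiff::readTIFF(path, all = all, as.is = TRUE),
           error = function(e) tiff::readTIFF(path, all = all))
}

# ---- images and movies ---------------------------------------------------

#' Read a single-page grayscale TIFF as a calibrated image
#'
#' Integer TIFFs are returned at their stored intensity values; float
#' TIFFs verbatim. Multi-channel pages are rejected unless a channel is
#' selected explicitly.
#'
#' @param path Path to an existing single-page grayscale TIFF
#'   (8/16/32-bit integer or 32-bit float).
#' @param calibration A [calibration()] object.
#' @param channel Optional 1-based channel index for multi-channel pages.
#' @return An [image2d()].
#' @export
read_image <- function(path, calibration, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is_calibration(calibration))
  v <- read_tiff_raw(path)
  if (length(dim(v)) == 3L) {
    if (is.null(channel))
      stop("multi-channel page; pass `channel` to select one")
    stopifnot(channel >= 1L, channel <= dim(v)[3])
    v <- v[, , channel]
  }
  storage.mode(v) <- "double"
  image2d(v, calibration)
}

#' Write a calibrated image as a 32-bit float grayscale TIFF
#'
#' @param image An [image2d()] or [binary_mask()] (written as 0/1).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image2d") || inherits(image, "binary_mask"))
  v <- image$values
  if (is.logical(v)) { v <- v * 1 }
  write_float_tiff(list(v), path)
}

#' Read a multi-page TIFF as a calibrated movie
#'
#' @param path Path to a multi-page grayscale TIFF; pages must be
#'   identically shaped and are taken in storage order.
#' @param calibration A [calibration()] with a frame interval.
#' @return A [movie()] with `n_frames` equal to the page count.
#' @export
read_movie <- function(path, calibration) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is_calibration(calibration))
  pages <- read_tiff_raw(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("movie TIFF must contain at least 2 pages")
  if (any(vapply(pages, function(p) length(dim(p)), 1L) != 2L))
    stop("multi-channel movie pages are not supported")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("movie pages differ in shape")
  movie(lapply(pages, function(p) { storage.mode(p) <- "double"; p }),
        calibration)
}

#' Write a movie as a multi-page 32-bit float TIFF
#'
#' @param m A [movie()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  pages <- lapply(seq_len(n_frames(m)), function(i) m$frames[, , i])
  write_float_tiff(pages, path)
}

# ---- ROIs and tables -----------------------------------------------------

#' Load a polyline ROI from CSV or JSON
#'
#' CSV input holds `x,y` pixel coordinates (header optional); the sampling
#' width defaults to 1 um, the width of the segmented line used for axial
#' profiles. JSON input holds `vertices` (list of `[x, y]`) and optionally
#' `width_um`.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A [polyline_roi()].
#' @export
load_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$vertices)) stop("JSON ROI needs a `vertices` field")
    v <- matrix(as.numeric(as.matrix(j$vertices)), ncol = 2)
    w <- if (is.null(j$width_um)) 1 else as.numeric(j$width_um)
    return(polyline_roi(v, w))
  }
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.csv(path, header = header)
  if (ncol(tab) < 2L) stop("ROI CSV needs two columns (x, y)")
  v <- as.matrix(tab[, 1:2])
  if (!is.numeric(v) || anyNA(v)) stop("non-numeric ROI vertices")
  polyline_roi(v, 1)
}

#' Write an ROI as CSV
#' @param roi A [polyline_roi()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "polyline_roi"))
  utils::write.csv(as.data.frame(roi$vertices), path, row.names = FALSE)
  invisible(path)
}

#' Write flat records as a CSV table
#'
#' Accepts a data.frame or a list of homogeneous named lists/vectors.
#' Columns follow the field order of the first record; numbers are
#' rendered with full double precision so re-reading reproduces values.
#'
#' @param records Data.frame, or list of records with identical names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    stopifnot(is.list(records))
    if (length(records) == 0L)
      stop("cannot infer a header from an empty record list; ",
           "pass a 0-row data.frame instead")
    nms <- names(records[[1]])
    if (is.null(nms)) stop("records must be named")
    ok <- vapply(records, function(r) identical(names(r), nms), TRUE)
    if (!all(ok)) stop("heterogeneous records: field names differ")
    records <- do.call(rbind,
                       lapply(records, function(r) as.data.frame(r)))
  }
  num <- vapply(records, is.double, TRUE)
  out <- records
  out[num] <- lapply(records[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path)
}
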