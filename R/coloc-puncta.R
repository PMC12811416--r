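# Manders colocalization coefficients for two-channel images and puncta
# counting within a mask.

#' Thresholded Manders colocalization coefficients
#'
#' M1 is the fraction of channel-1 intensity (summed over pixels where
#' channel 1 exceeds its threshold) located in pixels where channel 2
#' also exceeds its threshold; M2 is symmetric. This is the thresholded
#' variant - both numerator and denominator respect the reference
#' channel's threshold - matching protocols that apply identical
#' thresholding parameters to each channel before computing the
#' coefficients. The variant id is recorded in the result.
#'
#' @param ch1,ch2 Same-shape [image2d()]s.
#' @param thr1,thr2 Intensity thresholds for channels 1 and 2; keep them
#'   fixed across a batch for comparability.
#' @return `list(M1, M2, thr1, thr2, variant = "thresholded")`.
#' @export
manders <- function(ch1, ch2, thr1, thr2) {
  stopifnot(inherits(ch1, "image2d"), inherits(ch2, "image2d"))
  a <- ch1$values; b <- ch2$values
  if (!all(dim(a) == dim(b))) stop("channel shapes differ")
  a1 <- a > thr1; b1 <- b > thr2
  den1 <- sum(a[a1]); den2 <- sum(b[b1])
  if (den1 == 0) stop("no channel-1 signal above thr1")
  if (den2 == 0) stop("no channel-2 signal above thr2")
  list(M1 = sum(a[a1 & b1]) / den1,
       M2 = sum(b[a1 & b1]) / den2,
       thr1 = thr1, thr2 = thr2, variant = "thresholded")
}

#' Count puncta whose centroids fall inside a mask
#'
#' The image is optionally matched-filtered (Gaussian smoothing, sigma
#' `smooth_sigma_px`), thresholded, and 8-connected components with area
#' inside `[min_area_px, max_area_px]` are taken as puncta; a punctum
#' belongs to the mask if its intensity centroid lies on a true mask
#' pixel (deterministic for boundary-straddling dots). Density is count
#' per mask area.
#'
#' @param image An [image2d()].
#' @param mask A non-empty [binary_mask()] of the same shape (e.g. the
#'   beta3-tubulin axonal area).
#' @param threshold Intensity threshold applied after smoothing.
#' @param min_area_px,max_area_px Component area limits in pixels.
#' @param smooth_sigma_px Matched-filter sigma; 0 disables. Default 1.
#' @param labels Optional integer matrix of labeled regions (e.g. cell
#'   bodies); adds per-region centroid counts.
#' @return `list(count, mask_area_um2, density_per_um2,
#'   per_region_counts)`.
#' @export
count_puncta <- function(image, mask, threshold,
                         min_area_px = 2, max_area_px = 200,
                         smooth_sigma_px = 1, labels = NULL) {
  stopifnot(inherits(image, "image2d"), inherits(mask, "binary_mask"))
  mv <- mask$values
  if (!any(mv)) stop("mask is empty")
  if (!all(dim(image$values) == dim(mv))) stop("image/mask shapes differ")
  v <- if (smooth_sigma_px > 0)
    gaussian_smooth2d(image$values, smooth_sigma_px) else image$values
  lab <- label8(v > threshold)
  cal <- mask$calibration
  area_um2 <- sum(mv) * cal$pixel_size_x_um * cal$pixel_size_y_um
  count <- 0L
  cx_in <- numeric(0); cy_in <- numeric(0)
  if (max(lab) > 0) {
    ny <- nrow(v)
    idx <- which(lab > 0)
    comp <- lab[idx]
    rows <- ((idx - 1L) %% ny) + 1L
    cols <- ((idx - 1L) %/% ny) + 1L
    wts <- v[idx]
    sizes <- tabulate(comp)
    sw <- vapply(split(wts, comp), sum, numeric(1))
    cy <- vapply(split(wts * rows, comp), sum, numeric(1)) / sw
    cx <- vapply(split(wts * cols, comp), sum, numeric(1)) / sw
    ok_area <- sizes >= min_area_px & sizes <= max_area_px
    ri <- pmin(pmax(round(cy), 1L), nrow(mv))
    ci <- pmin(pmax(round(cx), 1L), ncol(mv))
    inside <- mv[cbind(ri, ci)]
    sel <- ok_area & inside
    count <- sum(sel)
    cx_in <- cx[sel]; cy_in <- cy[sel]
  }
  per_region <- NULL
  if (!is.null(labels) && count > 0) {
    reg <- labels[cbind(pmin(pmax(round(cy_in), 1L), nrow(labels)),
                        pmin(pmax(round(cx_in), 1L), ncol(labels)))]
    per_region <- table(factor(reg[reg > 0],
                               levels = seq_len(max(labels))))
  }
  list(count = as.integer(count), mask_area_um2 = area_um2,
       density_per_um2 = count / area_um2,
       per_region_counts = per_region)
}
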