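# Sholl analysis of binarized axon fields: intersections with concentric
# semicircles at fixed radial spacing, plus distance-bin summation.

#' Parameters for semicircular Sholl sampling
#'
#' Defaults follow the outgrowth protocol: semicircles every 2 um out to
#' 1500 um (1200 um is the other radius used depending on the
#' experiment), summed within 0-500, 500-1000 and 1000-1500 um bins.
#'
#' @param center `c(x, y)` center in pixels (the microgroove exit).
#' @param direction Unit-ish vector defining the sampled half-plane
#'   `{p : (p - center) . direction >= 0}`; default `c(1, 0)`.
#' @param radius_step_um Radial sampling interval (um), default 2.
#' @param r_max_um Maximum radius (um), default 1500.
#' @param bin_edges_um Strictly increasing bin edges, last `<= r_max_um`;
#'   default `c(0, 500, 1000, 1500)`.
#' @return Object of class `sholl_params`.
#' @export
sholl_params <- function(center, direction = c(1, 0),
                         radius_step_um = 2, r_max_um = 1500,
                         bin_edges_um = c(0, 500, 1000, 1500)) {
  stopifnot(length(center) == 2L, length(direction) == 2L)
  if (radius_step_um <= 0) stop("radius_step_um must be positive")
  if (r_max_um < radius_step_um) stop("r_max_um must be >= radius_step_um")
  if (sum(direction^2) == 0) stop("direction must be a nonzero vector")
  if (any(diff(bin_edges_um) <= 0))
    stop("bin_edges_um must be strictly increasing")
  if (max(bin_edges_um) > r_max_um + 1e-9)
    stop("bin edges exceed r_max_um")
  structure(list(center = as.numeric(center),
                 direction = as.numeric(direction) /
                   sqrt(sum(direction^2)),
                 radius_step_um = radius_step_um, r_max_um = r_max_um,
                 bin_edges_um = bin_edges_um),
            class = "sholl_params")
}

#' Threshold an image into a binary mask
#'
#' With a numeric `threshold_spec`, the mask is `image > threshold`
#' (identical fixed thresholds across conditions mirror the acquisition
#' protocol). With `"otsu"`, Otsu's criterion picks the threshold from a
#' 256-bin histogram; the chosen value is recorded in the
#' `threshold_value` attribute either way.
#'
#' @param image An [image2d()].
#' @param threshold_spec A single number, or `"otsu"`.
#' @return A [binary_mask()] with attribute `threshold_value`.
#' @export
binarize <- function(image, threshold_spec) {
  stopifnot(inherits(image, "image2d"))
  v <- image$values
  if (is.character(threshold_spec)) {
    threshold_spec <- match.arg(threshold_spec, "otsu")
    rng <- range(v)
    if (diff(rng) == 0)
      stop("automatic threshold undefined on a constant image; ",
           "use a fixed threshold")
    thr <- EBImage::otsu(EBImage::Image((v - rng[1]) / diff(rng)),
                         range = c(0, 1), levels = 256)
    thr <- rng[1] + thr * diff(rng)
  } else {
    stopifnot(is.numeric(threshold_spec), length(threshold_spec) == 1L)
    thr <- threshold_spec
  }
  out <- binary_mask(v > thr, image$calibration)
  attr(out, "threshold_value") <- thr
  out
}

#' Count intersections of a mask with concentric semicircles
#'
#' For each radius, the 1-px-wide semicircular arc (restricted to the
#' half-plane of `params$direction`) is discretized at sub-pixel angular
#' steps and the number of connected runs of foreground pixels along the
#' arc is counted - i.e. the number of distinct processes crossing that
#' semicircle, the quantity the outgrowth protocol reports. Pixels
#' outside the image count as background.
#'
#' @param mask A [binary_mask()] with isotropic calibration.
#' @param params A [sholl_params()]; `center` must lie inside the image.
#' @return Object of class `sholl_profile`: list with `radii_um`
#'   (step, 2 step, ..., <= r_max), integer `counts`, and `params`.
#' @export
sholl_intersections <- function(mask, params) {
  stopifnot(inherits(mask, "binary_mask"), inherits(params, "sholl_params"))
  px <- require_isotropic(mask$calibration, "sholl_intersections")
  mv <- mask$values
  ny <- nrow(mv); nx <- ncol(mv)
  cx <- params$center[1]; cy <- params$center[2]
  if (cx < 1 || cx > nx || cy < 1 || cy > ny)
    stop("center lies outside the image")
  phi0 <- atan2(params$direction[2], params$direction[1])
  radii <- seq(params$radius_step_um, params$r_max_um,
               by = params$radius_step_um)
  counts <- integer(length(radii))
  for (k in seq_along(radii)) {
    r_px <- radii[k] / px
    dtheta <- 0.25 / r_px
    theta <- seq(phi0 - pi / 2, phi0 + pi / 2, by = dtheta)
    xs <- round(cx + r_px * cos(theta))
    ys <- round(cy + r_px * sin(theta))
    keep <- c(TRUE, diff(xs) != 0 | diff(ys) != 0)
    xs <- xs[keep]; ys <- ys[keep]
    inside <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    fg <- logical(length(xs))
    fg[inside] <- mv[cbind(ys[inside], xs[inside])]
    rl <- rle(fg)
    counts[k] <- sum(rl$values)
  }
  structure(list(radii_um = radii, counts = counts, params = params),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> %d radii (%g..%g um), total %d intersections\n",
              length(x$radii_um), min(x$radii_um), max(x$radii_um),
              sum(x$counts)))
  invisible(x)
}

#' Sum Sholl intersections within distance bins
#'
#' Bin membership is half-open `(lo, hi]`, so a radius equal to an edge
#' belongs to the lower-labeled bin exactly once and contiguous bins
#' conserve the total count.
#'
#' @param profile A `sholl_profile` from [sholl_intersections()].
#' @param bin_edges_um Strictly increasing edges; defaults to the edges in
#'   the profile's params.
#' @return Data.frame with columns `lo_um`, `hi_um`, `sum`.
#' @export
bin_sums <- function(profile, bin_edges_um = NULL) {
  stopifnot(inherits(profile, "sholl_profile"))
  edges <- bin_edges_um %||% profile$params$bin_edges_um
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (max(edges) > max(profile$radii_um) + 1e-9)
    stop("bin edges exceed the sampled radius range")
  lo <- edges[-length(edges)]; hi <- edges[-1]
  sums <- vapply(seq_along(lo), function(i)
    sum(profile$counts[profile$radii_um > lo[i] &
                       profile$radii_um <= hi[i]]), numeric(1))
  data.frame(lo_um = lo, hi_um = hi, sum = sums)
}
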