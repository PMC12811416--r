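# Axial fluorescence profiles of distal axons: extraction along a
# tip-first polyline, background subtraction, the two visualization
# baseline corrections, integrated fold change and terminal fraction.

#' Construct an intensity profile object
#'
#' @param distances_um Strictly increasing distances from the axon tip,
#'   starting at 0.
#' @param values Mean intensity (a.u.) at each distance.
#' @param corrected Correction mode id: `"none"`, `"tip_anchor"` or
#'   `"distal_window"`.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(distances_um, values, corrected = "none") {
  stopifnot(length(distances_um) == length(values),
            length(distances_um) >= 2L)
  if (distances_um[1] != 0 || any(diff(distances_um) <= 0))
    stop("distances must increase strictly from 0")
  structure(list(distances_um = as.numeric(distances_um),
                 values = as.numeric(values), corrected = corrected),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> 0..%g um, %d samples, correction: %s\n",
              max(x$distances_um), length(x$values), x$corrected))
  invisible(x)
}

# Exact integral of the piecewise-linear interpolant of a profile over
# [0, upper]; trapezoidal rule with an interpolated cut at `upper`.
profile_integral <- function(profile, upper = NULL) {
  d <- profile$distances_um; v <- profile$values
  if (!is.null(upper)) {
    if (upper <= 0) return(0)
    upper <- min(upper, max(d))
    if (!any(d == upper)) {
      vu <- stats::approx(d, v, xout = upper)$y
      keep <- d < upper
      d <- c(d[keep], upper); v <- c(v[keep], vu)
    } else {
      keep <- d <= upper
      d <- d[keep]; v <- v[keep]
    }
  }
  sum(diff(d) * (v[-1] + v[-length(v)]) / 2)
}

#' Extract an axial intensity profile along a tip-first polyline
#'
#' The path is sampled every pixel of arc length starting at the first
#' vertex (the axon tip); at each sample the image is averaged across the
#' perpendicular sampling width (`roi$width_um`, the protocol's 1-um-wide
#' segmented line) using three evenly spaced bilinear probes per
#' micrometer of width. Distances accumulate true geometric arc length
#' and are reported in micrometers from the tip.
#'
#' @param image An [image2d()] with isotropic calibration.
#' @param roi A [polyline_roi()] whose first vertex is the axon tip and
#'   whose path length is at least `length_um`.
#' @param length_um Profile span from the tip; default 50 um.
#' @return An uncorrected [intensity_profile()].
#' @export
extract_profile <- function(image, roi, length_um = 50) {
  stopifnot(inherits(image, "image2d"), inherits(roi, "polyline_roi"))
  px <- require_isotropic(image$calibration, "extract_profile")
  path_um <- roi_path_length_px(roi) * px
  if (path_um + 1e-9 < length_um)
    stop(sprintf("ROI path (%.2f um) shorter than requested %g um",
                 path_um, length_um))
  s <- sample_polyline(roi$vertices, step_px = 1,
                       max_len_px = length_um / px)
  w_px <- roi$width_um / px
  n_off <- max(1L, round(3 * roi$width_um))
  off <- if (n_off == 1L) 0 else seq(-w_px / 2, w_px / 2,
                                     length.out = n_off)
  vals <- matrix(0, length(off), length(s$x))
  for (i in seq_along(off)) {
    # perpendicular = tangent rotated 90 degrees
    xx <- s$x - off[i] * s$ty
    yy <- s$y + off[i] * s$tx
    vals[i, ] <- interp_bilinear(image$values, xx, yy)
  }
  intensity_profile(s$s_px * px, colMeans(vals))
}

#' Background-corrected region intensity
#'
#' Mirrors the somatic/whole-cell quantification: a background value
#' measured in a cell-free area is subtracted from the region's mean
#' intensity, and total fluorescence is the corrected mean times the
#' region area.
#'
#' @param mean_intensity Raw mean intensity of the region (a.u.).
#' @param area_um2 Region area in square micrometers (> 0).
#' @return Object of class `region_intensity` with fields
#'   `mean_intensity`, `area_um2`, `total_intensity`.
#' @export
region_intensity <- function(mean_intensity, area_um2) {
  stopifnot(area_um2 > 0)
  structure(list(mean_intensity = mean_intensity, area_um2 = area_um2,
                 total_intensity = mean_intensity * area_um2),
            class = "region_intensity")
}

#' Subtract a measured background value
#'
#' Profiles have the background removed elementwise; regions from the
#' mean (total recomputed). Negative results are preserved - clipping
#' would bias downstream integrals and fold changes.
#'
#' @param x An [intensity_profile()] or [region_intensity()].
#' @param bg_value Finite nonnegative scalar measured from a cell-free
#'   region.
#' @return Same type as `x`.
#' @export
subtract_background <- function(x, bg_value) {
  stopifnot(is.numeric(bg_value), length(bg_value) == 1L,
            is.finite(bg_value), bg_value >= 0)
  if (inherits(x, "intensity_profile")) {
    x$values <- x$values - bg_value
    return(x)
  }
  if (inherits(x, "region_intensity")) {
    return(region_intensity(x$mean_intensity - bg_value, x$area_um2))
  }
  stop("x must be an intensity_profile or region_intensity")
}

#' Apply a visualization baseline correction to a profile
#'
#' `tip_anchor` subtracts the value at 0 um (axon tip) so the corrected
#' profile is exactly zero at the tip (the convention used for
#' beta3-tubulin traces). `distal_window` subtracts the mean over the
#' distal window (default 45-50 um from the tip, the convention for
#' Rtn-1), making the corrected mean over that window zero. Corrected
#' profiles are for plotting only and must not enter fold-change
#' computation; correcting twice is an error.
#'
#' @param profile An uncorrected [intensity_profile()].
#' @param mode `"tip_anchor"` or `"distal_window"`.
#' @param window_um `c(lo, hi)` window for `distal_window`; default
#'   `c(45, 50)`.
#' @return Corrected [intensity_profile()] (with `corrected` set).
#' @export
correct_baseline <- function(profile,
                             mode = c("tip_anchor", "distal_window"),
                             window_um = c(45, 50)) {
  stopifnot(inherits(profile, "intensity_profile"))
  mode <- match.arg(mode)
  if (profile$corrected != "none")
    stop("profile is already corrected (", profile$corrected, ")")
  if (mode == "tip_anchor") {
    base <- profile$values[1]
  } else {
    sel <- profile$distances_um >= window_um[1] &
      profile$distances_um <= window_um[2]
    if (!any(sel)) stop("no samples inside the distal window")
    base <- mean(profile$values[sel])
  }
  intensity_profile(profile$distances_um, profile$values - base,
                    corrected = mode)
}

#' Integrated intensity of a profile
#'
#' Trapezoidal integral of the profile over its span (or `[0, upper]`).
#'
#' @param profile An [intensity_profile()].
#' @param upper Optional upper integration limit (um).
#' @return Integral in a.u. x um.
#' @export
integrated_intensity <- function(profile, upper = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  profile_integral(profile, upper)
}

#' Per-profile integrated fold change against a control group
#'
#' Each profile's trapezoidal integral over `[0, over_um]` is divided by
#' the mean integral of the control profiles - the quantity reported per
#' axon in the intensity experiments. Inputs must be background-subtracted
#' and uncorrected (baseline corrections are visualization-only).
#'
#' @param treated,control Lists of uncorrected [intensity_profile()]s.
#' @param over_um Integration span; default 50 um.
#' @return `list(fold_treated, fold_control, control_mean_integral)`.
#' @export
integrated_fold_change <- function(treated, control, over_um = 50) {
  chk <- function(p) {
    stopifnot(inherits(p, "intensity_profile"))
    if (p$corrected != "none")
      stop("fold change must use uncorrected profiles")
    p
  }
  ti <- vapply(treated, function(p) profile_integral(chk(p), over_um),
               numeric(1))
  ci <- vapply(control, function(p) profile_integral(chk(p), over_um),
               numeric(1))
  cm <- mean(ci)
  if (cm <= 0) stop("control mean integral must be positive")
  list(fold_treated = ti / cm, fold_control = ci / cm,
       control_mean_integral = cm)
}

#' Percentage of profile intensity within the terminal window
#'
#' The growth-cone fraction: 100 times the integral over the first
#' `window_um` micrometers divided by the integral over the whole
#' profile. Requires a nonnegative total (background-subtracted input).
#'
#' @param profile An [intensity_profile()].
#' @param window_um Terminal window; default 10 um.
#' @return Percentage in `[0, 100]` for nonnegative profiles.
#' @export
terminal_fraction <- function(profile, window_um = 10) {
  stopifnot(inherits(profile, "intensity_profile"))
  total <- profile_integral(profile)
  if (total <= 0) stop("profile total must be positive")
  100 * profile_integral(profile, window_um) / total
}
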