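# Kymograph quantification of microtubule plus-end comets: temporal
# difference-of-Gaussians separation of mobile from static fluorescence,
# kymograph construction along an axonal line, and conversion of dashes
# to track length, lifetime and growth rate.

#' Parameters for mobile/static separation
#'
#' Two Gaussian blurs along the time axis: a narrow one (default sigma 4
#' frames) passing mobile structures, a wide one (default 50 frames)
#' capturing the static background; their difference isolates movement.
#'
#' @param sigma_mobile Sigma of the mobile-pass blur, in frames.
#' @param sigma_static Sigma of the static-estimate blur, in frames;
#'   must exceed `sigma_mobile`.
#' @return Object of class `separation_params`.
#' @export
separation_params <- function(sigma_mobile = 4, sigma_static = 50) {
  if (!(sigma_mobile > 0 && sigma_static > 0))
    stop("sigmas must be positive")
  if (sigma_mobile >= sigma_static)
    stop("sigma_mobile must be smaller than sigma_static")
  structure(list(sigma_mobile = sigma_mobile,
                 sigma_static = sigma_static, axis = "time"),
            class = "separation_params")
}

# FFT-based Gaussian difference filter along the third (time) dimension,
# reflect boundary. Kernels are normalized to unit sum so constant
# series map to zero exactly (up to float error).
dog_time_filter <- function(frames, sigma_mobile, sigma_static) {
  d <- dim(frames)
  n <- d[3]
  # kernel support capped by the series length so short movies (already
  # warned about upstream) remain filterable; normalization keeps the
  # constant-to-zero property either way
  R <- min(ceiling(4 * sigma_static), n - 1L)
  P <- R
  km <- stats::dnorm(seq(-R, R), sd = sigma_mobile)
  ks <- stats::dnorm(seq(-R, R), sd = sigma_static)
  dk <- km / sum(km) - ks / sum(ks)
  N <- n + 2 * P
  kpad <- numeric(N)
  kpad[1] <- dk[R + 1]
  kpad[2:(R + 1)] <- dk[(R + 2):(2 * R + 1)]
  kpad[(N - R + 1):N] <- dk[1:R]
  Fk <- stats::fft(kpad)
  X <- matrix(frames, d[1] * d[2], n)
  out <- matrix(0, d[1] * d[2], n)
  idx <- c(P:1, 1:n, n:(n - P + 1))
  chunk <- max(1L, floor(4e6 / N))
  starts <- seq(1L, nrow(X), by = chunk)
  for (s0 in starts) {
    s1 <- min(s0 + chunk - 1L, nrow(X))
    Xp <- t(X[s0:s1, idx, drop = FALSE])          # N x npix
    Y <- Re(stats::mvfft(stats::mvfft(Xp) * Fk, inverse = TRUE)) / N
    out[s0:s1, ] <- t(Y[(P + 1):(P + n), , drop = FALSE])
  }
  array(out, dim = d)
}

#' Separate mobile from static fluorescence in a movie
#'
#' Each pixel's time series is blurred twice along the time axis
#' (Gaussian, reflect boundary) and the static estimate subtracted from
#' the mobile one: `out = G_sigma_mobile(series) - G_sigma_static(series)`.
#' Spatial content within a frame is untouched. A time-constant movie
#' maps to (numerically) zero; negative values are preserved.
#'
#' @param m A [movie()].
#' @param params A [separation_params()].
#' @return A `movie` of the separated (signed) signal, carried in a
#'   plain list-compatible structure with the same calibration.
#' @export
separate_mobile_static <- function(m, params = separation_params()) {
  stopifnot(inherits(m, "movie"), inherits(params, "separation_params"))
  nf <- n_frames(m)
  if (nf <= 2 * params$sigma_static)
    warning("movie has only ", nf, " frames; static sigma ",
            params$sigma_static, " is poorly constrained")
  out <- dog_time_filter(m$frames, params$sigma_mobile,
                         params$sigma_static)
  structure(list(frames = out, calibration = m$calibration),
            class = "movie")
}

#' Build a kymograph along a polyline
#'
#' Row `t` holds the intensity along the path at frame `t`, averaged
#' across the perpendicular sampling width like [extract_profile()].
#' Columns advance along the path at one-pixel arc steps; the x axis is
#' distance (um per column = pixel size), the y axis time (s per row =
#' frame interval). Total time follows the movie convention
#' `n_rows * time_step_s`.
#'
#' @param m A [movie()] (typically after [separate_mobile_static()]).
#' @param roi A [polyline_roi()] within frame bounds; 30-50 um lines are
#'   the protocol's usual choice, but any length is accepted.
#' @return Object of class `kymograph`: `values` (rows = time, cols =
#'   distance), `space_step_um`, `time_step_s`, `n_rows`, `total_time_s`.
#' @export
build_kymograph <- function(m, roi) {
  stopifnot(inherits(m, "movie"), inherits(roi, "polyline_roi"))
  px <- require_isotropic(m$calibration, "build_kymograph")
  dt <- require_frame_interval(m$calibration)
  s <- sample_polyline(roi$vertices, step_px = 1)
  w_px <- roi$width_um / px
  n_off <- max(1L, round(3 * roi$width_um))
  off <- if (n_off == 1L) 0 else seq(-w_px / 2, w_px / 2,
                                     length.out = n_off)
  nf <- n_frames(m)
  ns <- length(s$x)
  vals <- matrix(0, nf, ns)
  xs <- outer(-s$ty, off)  # ns x n_off perpendicular x-offsets
  ys <- outer(s$tx, off)
  sx <- as.vector(s$x + xs)
  sy <- as.vector(s$y + ys)
  for (k in seq_len(nf)) {
    v <- interp_bilinear(m$frames[, , k], sx, sy)
    vals[k, ] <- rowMeans(matrix(v, ns, n_off))
  }
  structure(list(values = vals, space_step_um = px, time_step_s = dt,
                 n_rows = nf, total_time_s = nf * dt),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d rows x %d cols, %g um/col, %g s/row\n",
              x$n_rows, ncol(x$values), x$space_step_um, x$time_step_s))
  invisible(x)
}

#' A traced comet dash on a kymograph
#'
#' Endpoints are continuous kymograph coordinates (x = distance in
#' columns, y = time in rows); orientation is normalized so time
#' increases from the first to the second endpoint.
#'
#' @param x0,y0,x1,y1 Endpoint coordinates in kymograph pixels.
#' @return Object of class `dash` with endpoints, pixel length `L_px`
#'   and angle `theta_rad` to the x axis.
#' @export
dash <- function(x0, y0, x1, y1) {
  if (y1 < y0) { tmp <- c(x0, y0); x0 <- x1; y0 <- y1; x1 <- tmp[1]; y1 <- tmp[2] }
  L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (L <= 0) stop("dash endpoints coincide")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, L_px = L,
                 theta_rad = atan2(y1 - y0, abs(x1 - x0))),
            class = "dash")
}

#' Convert a dash to comet parameters
#'
#' Track length is the horizontal projection of the dash calibrated to
#' micrometers; lifetime is the vertical projection divided by the total
#' kymograph height and multiplied by the total acquisition time (so a
#' full-height dash of a 3-min movie lives 180 s); growth rate is track
#' length over lifetime. Projections are computed from endpoint deltas,
#' which equals the length-times-cosine/sine formulation exactly for
#' isotropic kymograph pixels and stays correct when the axes are
#' calibrated differently. Retrograde dashes keep their signed
#' displacement in `dx_um` but track length uses the magnitude.
#'
#' @param d A [dash()] with `y1 > y0`.
#' @param kymo The [build_kymograph()] result the dash was traced on.
#' @return One-row data.frame: `track_length_um`, `lifetime_s`,
#'   `growth_rate_um_per_s`, `dx_um`, `L_px`, `theta_rad`.
#' @export
dash_params <- function(d, kymo) {
  stopifnot(inherits(d, "dash"), inherits(kymo, "kymograph"))
  dy <- d$y1 - d$y0
  if (dy <= 0) stop("dash must span positive time (dy > 0)")
  dx_um <- (d$x1 - d$x0) * kymo$space_step_um
  track <- abs(dx_um)
  lifetime <- dy / kymo$n_rows * kymo$total_time_s
  data.frame(track_length_um = track, lifetime_s = lifetime,
             growth_rate_um_per_s = track / lifetime,
             dx_um = dx_um, L_px = d$L_px, theta_rad = d$theta_rad)
}

#' Detect comet dashes on a separated kymograph
#'
#' The kymograph is thresholded on its positive part, small gaps are
#' bridged by a morphological closing, and 8-connected components are
#' reduced to dashes: pixels at or above half the component's peak are
#' fit by their principal axis, and the extremal projections onto that
#' axis give the endpoints. The half-maximum refinement matters because
#' the temporal mobile blur smears dash ends - the half-amplitude point
#' of a Gaussian-blurred edge sits at the true edge.
#'
#' The default `"auto"` threshold is 2.5 times the kymograph's median
#' absolute deviation: after difference-of-Gaussians separation the
#' background is zero-centered with noise correlated over a few frames,
#' so a robust global scale is the natural reference. The closing
#' (default 5 px box, the scale of that noise correlation) re-joins dash
#' fragments split by noise dips; components smaller than `min_area_px`
#' (default 50 px, about half the footprint of the shortest expected
#' growth event) or shorter than `min_dash_len_px` along their axis, or
#' with no time extent, are discarded.
#'
#' @param kymo A [build_kymograph()] result (separated movie).
#' @param threshold Numeric threshold on the kymograph values, `"auto"`
#'   (2.5 x MAD) or `"otsu"`.
#' @param min_dash_len_px Minimum dash length in kymograph pixels;
#'   default 5.
#' @param min_area_px Minimum component area in pixels; default 50.
#' @param min_dy_px Minimum time extent in rows; default 4 (2 s at
#'   2 fps - a growth event shorter than that is not resolvable and a
#'   near-horizontal component would otherwise imply an unphysical
#'   growth rate).
#' @param close_px Box size of the gap-bridging closing; default 5
#'   (0 or 1 disables).
#' @param refine_frac Fraction of the component peak used for endpoint
#'   refinement; default 0.5.
#' @return List of [dash()] objects (possibly empty).
#' @export
detect_dashes <- function(kymo, threshold = "auto", min_dash_len_px = 5,
                          min_area_px = 50, min_dy_px = 4, close_px = 5,
                          refine_frac = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  v <- kymo$values
  pos <- pmax(v, 0)
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, c("auto", "otsu"))
    if (threshold == "auto") {
      # robust noise scale, floored at a tenth of the peak so noise-free
      # kymographs (MAD ~ 0) do not threshold at numerical zero
      thr <- max(2.5 * stats::mad(v), 0.1 * max(pos))
      if (thr == 0) return(list())
    } else {
      rng <- range(pos)
      if (diff(rng) == 0) return(list())
      thr <- EBImage::otsu(EBImage::Image(pos / rng[2]),
                           range = c(0, 1), levels = 256) * rng[2]
    }
  } else thr <- threshold
  mask <- pos > thr
  if (!any(mask)) return(list())
  if (close_px >= 2) {
    mask <- EBImage::closing(mask * 1,
                             EBImage::makeBrush(close_px, "box")) > 0
    dim(mask) <- dim(v)
  }
  lab <- label8(mask)
  dashes <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) < max(3L, min_area_px)) next
    rows <- ((idx - 1L) %% nrow(v)) + 1L
    cols <- ((idx - 1L) %/% nrow(v)) + 1L
    ints <- pos[idx]
    keep <- ints >= refine_frac * max(ints)
    X <- cbind(cols[keep], rows[keep])  # (x, y)
    if (nrow(X) < 2L) next
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc, nu = 0, nv = 1)
    ax <- sv$v[, 1]
    if (ax[2] < 0) ax <- -ax
    proj <- Xc %*% ax
    len <- max(proj) - min(proj)
    if (len < min_dash_len_px) next
    p0 <- ctr + min(proj) * ax
    p1 <- ctr + max(proj) * ax
    # extend endpoints along the fitted axis on the unthresholded values
    # out to the half-maximum crossing: the threshold trims faint dashes
    # (whose half-max lies below it) short, while the half-amplitude
    # point of a blurred edge marks the true end
    half <- refine_frac * max(pos[idx])
    extend <- function(p, dir) {
      best <- 0
      for (step in seq_len(20L)) {
        q <- p + step * dir * ax
        if (q[1] < 1 || q[1] > ncol(v) || q[2] < 1 || q[2] > nrow(v))
          break
        if (interp_bilinear(pos, q[1], q[2]) >= half) best <- step
        else if (step - best >= 2L) break
      }
      p + best * dir * ax
    }
    p0 <- extend(p0, -1)
    p1 <- extend(p1, +1)
    if (abs(p1[2] - p0[2]) < min_dy_px) next  # unresolvable time extent
    dashes[[length(dashes) + 1L]] <- dash(p0[1], p0[2], p1[1], p1[2])
  }
  dashes
}

#' Pool per-comet parameters into mean, SE and n
#'
#' @param params_df Data.frame of [dash_params()] rows (non-empty).
#' @return Data.frame with one row per metric (`track_length_um`,
#'   `lifetime_s`, `growth_rate_um_per_s`): `mean`, `se` (0 for n = 1),
#'   `n`.
#' @export
summarize_dynamics <- function(params_df) {
  stopifnot(is.data.frame(params_df), nrow(params_df) >= 1L)
  metrics <- c("track_length_um", "lifetime_s", "growth_rate_um_per_s")
  do.call(rbind, lapply(metrics, function(mname) {
    x <- params_df[[mname]]
    n <- length(x)
    data.frame(metric = mname, mean = mean(x),
               se = if (n > 1) stats::sd(x) / sqrt(n) else 0, n = n)
  }))
}
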