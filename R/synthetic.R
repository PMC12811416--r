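# Synthetic-microscopy generators. Each generator returns the rendered
# image/movie/mask together with a ground-truth record so every analysis
# stage can be tested without microscope data.

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv()))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

# ---- axon fields ---------------------------------------------------------

# Exact continuous-geometry crossing counts of the union of dilated ray
# segments (capsules) with semicircular arcs. Independent of the raster
# pipeline: works on the real-valued segment coordinates. Counts are
# evaluated at the nominal capsule half-width plus a thinner and a fatter
# variant spanning the +/- 1 px rasterization jitter of a dilated digital
# line; `count_lo`/`count_hi` bound the plausible discrete counts, and a
# radius is `uncertain` when the variants disagree or it lies within
# about one pixel of a segment's radial extent.
analytic_arc_counts <- function(segments, radii_um, halfwidth_um,
                                direction = c(1, 0),
                                halfwidth_margin_um = halfwidth_um * 2 / 3) {
  phi0 <- atan2(direction[2], direction[1])
  hs <- c(max(halfwidth_um - halfwidth_margin_um, 0.2 * halfwidth_um),
          halfwidth_um,
          halfwidth_um + halfwidth_margin_um)
  counts3 <- matrix(0L, length(radii_um), 3)
  for (k in seq_along(radii_um)) {
    r <- radii_um[k]
    # grid fine enough that a capsule interval (half-angle ~ h/r) spans
    # several samples even for the thin variant
    dtheta <- min(0.25 * hs[1] / r, 0.05)
    theta <- seq(phi0 - pi / 2, phi0 + pi / 2, by = dtheta)
    px <- r * cos(theta); py <- r * sin(theta)
    d2min <- rep(Inf, length(theta))
    for (i in seq_len(nrow(segments))) {
      ax <- segments$x0[i]; ay <- segments$y0[i]
      ux <- segments$x1[i] - ax; uy <- segments$y1[i] - ay
      L2 <- ux^2 + uy^2
      t <- pmin(pmax(((px - ax) * ux + (py - ay) * uy) / L2, 0), 1)
      d2min <- pmin(d2min, (px - (ax + t * ux))^2 +
                            (py - (ay + t * uy))^2)
    }
    for (j in 1:3) {
      rl <- rle(d2min <= hs[j]^2)
      counts3[k, j] <- sum(rl$values)
    }
  }
  r0 <- sqrt(segments$x0^2 + segments$y0^2)
  r1 <- sqrt(segments$x1^2 + segments$y1^2)
  near_end <- vapply(radii_um, function(r)
    any(abs(r - c(r0, r1)) <= 1.2 * halfwidth_um), TRUE)
  lo <- pmin(counts3[, 1], counts3[, 2], counts3[, 3])
  hi <- pmax(counts3[, 1], counts3[, 2], counts3[, 3])
  list(counts = counts3[, 2],
       count_lo = lo, count_hi = hi,
       uncertain = (lo != hi) | near_end)
}

#' Simulate a binarized axon field radiating from a microgroove edge
#'
#' Renders straight rays (optionally with outward branches) from a center
#' point on the left image edge into the half-plane of a direction vector,
#' emulating axons growing out of microfluidic microgrooves. Rays are
#' drawn as digital lines and dilated once (3x3), as the analysis would
#' see after thresholding real data. The truth record carries analytic
#' semicircle crossing counts: exact continuous-geometry counts of the
#' dilated-ray union (`expected_counts`, with an `uncertain` flag at radii
#' where one pixel of rasterization can flip the count) and the idealized
#' per-ray counts (`naive_counts` = number of segments whose radial span
#' contains the radius, valid wherever rays are separated on the arc).
#'
#' @param rays List of ray specs: `list(angle_rad=, length_um=, branches=)`,
#'   where `branches` (optional) is a list of
#'   `list(at_um=, angle_rad=, length_um=)` forking from the parent ray at
#'   `at_um` from the center. Angles are absolute (0 = +x, positive
#'   downward); each segment must point into the sampled half-plane and
#'   radially outward.
#' @param image_size_px `c(nx, ny)` image size in pixels.
#' @param calibration Isotropic [calibration()].
#' @param center `c(x, y)` in pixels; default midway up the left edge.
#' @param direction Half-plane direction vector; default `c(1, 0)`.
#' @param radii_um Radii at which truth counts are computed; default
#'   2, 4, ..., 1500 um (2-um semicircle spacing).
#' @return `list(mask = binary_mask, truth = list(...))`.
#' @export
make_axon_field <- function(rays, image_size_px, calibration,
                            center = NULL, direction = c(1, 0),
                            radii_um = seq(2, 1500, by = 2)) {
  px <- require_isotropic(calibration, "make_axon_field")
  nx <- image_size_px[1]; ny <- image_size_px[2]
  if (is.null(center)) center <- c(1, round(ny / 2))
  phi0 <- atan2(direction[2], direction[1])
  segs <- list()
  for (ray in rays) {
    ang <- ray$angle_rad; len <- ray$length_um
    dphi <- atan2(sin(ang - phi0), cos(ang - phi0))
    if (abs(dphi) > pi / 2 + 1e-9)
      stop("ray angle outside the sampled half-plane")
    tip <- c(len * cos(ang), len * sin(ang))
    segs[[length(segs) + 1L]] <-
      data.frame(x0 = 0, y0 = 0, x1 = tip[1], y1 = tip[2])
    for (br in ray$branches %||% list()) {
      fork <- c(br$at_um * cos(ang), br$at_um * sin(ang))
      u <- c(cos(br$angle_rad), sin(br$angle_rad))
      if (sum(fork * u) < -1e-9)
        stop("branch does not point radially outward")
      segs[[length(segs) + 1L]] <-
        data.frame(x0 = fork[1], y0 = fork[2],
                   x1 = fork[1] + br$length_um * u[1],
                   y1 = fork[2] + br$length_um * u[2])
    }
  }
  mask <- matrix(FALSE, ny, nx)
  if (length(segs) > 0) {
    segments <- do.call(rbind, segs)
    for (i in seq_len(nrow(segments))) {
      p0 <- center + c(segments$x0[i], segments$y0[i]) / px
      p1 <- center + c(segments$x1[i], segments$y1[i]) / px
      if (p1[1] < 0.5 || p1[1] > nx + 0.5 ||
          p1[2] < 0.5 || p1[2] > ny + 0.5)
        stop("ray exits image bounds")
      mask <- set_pixels(mask, line_pixels(p0[1], p0[2], p1[1], p1[2],
                                           nx, ny))
    }
    mask <- dilate3(mask)
    halfwidth_um <- 1.5 * px
    ana <- analytic_arc_counts(segments, radii_um, halfwidth_um, direction)
    r0 <- sqrt(segments$x0^2 + segments$y0^2)
    r1 <- sqrt(segments$x1^2 + segments$y1^2)
    naive <- vapply(radii_um, function(r)
      sum(r0 < r & r <= r1), integer(1))
    counts <- ana$counts; uncertain <- ana$uncertain
    count_lo <- ana$count_lo; count_hi <- ana$count_hi
  } else {
    segments <- data.frame(x0 = numeric(0), y0 = numeric(0),
                           x1 = numeric(0), y1 = numeric(0))
    counts <- integer(length(radii_um))
    naive <- integer(length(radii_um))
    count_lo <- count_hi <- counts
    uncertain <- rep(FALSE, length(radii_um))
  }
  list(mask = binary_mask(mask, calibration),
       truth = list(center = center, direction = direction, rays = rays,
                    segments = segments, radii_um = radii_um,
                    expected_counts = counts, naive_counts = naive,
                    count_lo = count_lo, count_hi = count_hi,
                    uncertain = uncertain))
}

#' Draw a random unbranched ray arbor specification
#'
#' Angles are spaced with a minimum separation so rays are resolvable on
#' the semicircular arcs; lengths are uniform in `length_range_um`.
#'
#' @param n_rays Number of rays.
#' @param length_range_um `c(min, max)` ray length in micrometers.
#' @param angle_range_rad Angular span (absolute angles) to draw from;
#'   default within +/- 80 degrees of +x.
#' @param min_sep_rad Minimum angular separation between rays.
#' @param seed Optional RNG seed.
#' @return A list of ray specs for [make_axon_field()].
#' @export
random_ray_spec <- function(n_rays, length_range_um = c(100, 1400),
                            angle_range_rad = c(-80, 80) * pi / 180,
                            min_sep_rad = 0.12, seed = NULL) {
  with_seed(seed, {
    span <- diff(angle_range_rad)
    if ((n_rays - 1) * min_sep_rad > span)
      stop("cannot fit ", n_rays, " rays with the requested separation")
    repeat {
      ang <- sort(stats::runif(n_rays, angle_range_rad[1],
                               angle_range_rad[2]))
      if (n_rays < 2 || min(diff(ang)) >= min_sep_rad) break
    }
    lens <- stats::runif(n_rays, length_range_um[1], length_range_um[2])
    lapply(seq_len(n_rays), function(i)
      list(angle_rad = ang[i], length_um = lens[i]))
  })
}

# ---- growth cones --------------------------------------------------------

#' Simulate a growth-cone actin mask: filled ellipse plus filopodia
#'
#' The body is a filled ellipse; filopodia are line segments of a given
#' pixel width leaving the ellipse boundary along the outward normal at a
#' parametric angle. The truth record keeps the requested geometry
#' verbatim (semi-axes, orientation, per-filopodium base point, direction
#' and length).
#'
#' @param a_um,b_um Semi-major and semi-minor axes in micrometers
#'   (`a_um >= b_um > 0`).
#' @param theta_rad Orientation of the major axis (0 = +x).
#' @param filopodia Data.frame with columns `t_rad` (parametric boundary
#'   angle), `length_um`, `width_px` (odd; default 3). `NULL` for none.
#' @param image_size_px `c(nx, ny)`.
#' @param calibration Isotropic [calibration()].
#' @param center `c(x, y)` pixels; default image center.
#' @return `list(mask = binary_mask, truth = list(...))`.
#' @export
make_growth_cone <- function(a_um, b_um, theta_rad = 0, filopodia = NULL,
                             image_size_px, calibration, center = NULL) {
  px <- require_isotropic(calibration, "make_growth_cone")
  if (!(a_um >= b_um && b_um > 0))
    stop("require a_um >= b_um > 0")
  nx <- image_size_px[1]; ny <- image_size_px[2]
  if (is.null(center)) center <- c(nx, ny) / 2
  a_px <- a_um / px; b_px <- b_um / px
  ct <- cos(theta_rad); st <- sin(theta_rad)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) - center[1]
  ys <- matrix(rep(seq_len(ny), nx), ny, nx) - center[2]
  u <- (xs * ct + ys * st) / a_px
  v <- (-xs * st + ys * ct) / b_px
  mask <- (u^2 + v^2) <= 1
  filo_truth <- NULL
  if (!is.null(filopodia) && nrow(filopodia) > 0) {
    if (is.null(filopodia$width_px)) filopodia$width_px <- 3
    rows <- list()
    for (i in seq_len(nrow(filopodia))) {
      t0 <- filopodia$t_rad[i]
      len_px <- filopodia$length_um[i] / px
      if (len_px <= 0) stop("filopodium length must be positive")
      # boundary point and outward normal of the rotated ellipse
      bx <- a_px * cos(t0); by <- b_px * sin(t0)
      base <- center + c(ct * bx - st * by, st * bx + ct * by)
      nrm <- c(b_px * cos(t0), a_px * sin(t0))
      nrm <- nrm / sqrt(sum(nrm^2))
      dir <- c(ct * nrm[1] - st * nrm[2], st * nrm[1] + ct * nrm[2])
      tip <- base + len_px * dir
      if (tip[1] < 1 || tip[1] > nx || tip[2] < 1 || tip[2] > ny)
        stop("filopodium exits image bounds")
      fm <- matrix(FALSE, ny, nx)
      fm <- set_pixels(fm, line_pixels(base[1], base[2], tip[1], tip[2],
                                       nx, ny))
      ndil <- max(0L, (filopodia$width_px[i] - 1L) %/% 2L)
      for (k in seq_len(ndil)) fm <- dilate3(fm)
      mask <- mask | fm
      rows[[i]] <- data.frame(t_rad = t0, length_um = filopodia$length_um[i],
                              width_px = filopodia$width_px[i],
                              base_x = base[1], base_y = base[2],
                              dir_x = dir[1], dir_y = dir[2])
    }
    filo_truth <- do.call(rbind, rows)
  }
  list(mask = binary_mask(mask, calibration),
       truth = list(center = center, a_um = a_um, b_um = b_um,
                    theta_rad = theta_rad, filopodia = filo_truth))
}

# ---- comet movies --------------------------------------------------------

# Minimum distance between two 2-D segments (each a 2x2 matrix of row
# points); used for comet collision checks in scaled kymograph space.
segment_min_dist <- function(p, q) {
  pts <- function(a, b) {
    t <- seq(0, 1, length.out = 21)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  A <- pts(p[1, ], p[2, ]); B <- pts(q[1, ], q[2, ])
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(min(d2))
}

#' Draw random comet kinematics that stay resolvable on a kymograph
#'
#' Velocities and lifetimes are uniform in the given ranges; start times
#' and positions are drawn so each comet's full trajectory fits the axis
#' and the acquisition, and so no two space-time tracks come closer than
#' a separation margin (manual tracing resolves overlapping dashes in
#' real kymographs; automated detection cannot, so the generator keeps
#' events disjoint).
#'
#' @param n Number of comets.
#' @param axis_length_um Usable axis length (um).
#' @param total_time_s Acquisition span (s).
#' @param v_range_um_s Velocity range, default `c(0.05, 0.15)` um/s.
#' @param lifetime_range_s Lifetime range, default `c(10, 30)` s.
#' @param amplitude,sigma_px Comet spot amplitude and PSF sigma.
#' @param sep_x_um,sep_t_s Space/time scales of the separation margin.
#' @param seed Optional RNG seed.
#' @return Data.frame with columns `t0_s, x0_um, v_um_s, lifetime_s,
#'   amplitude, sigma_px`.
#' @export
random_comet_spec <- function(n, axis_length_um, total_time_s,
                              v_range_um_s = c(0.05, 0.15),
                              lifetime_range_s = c(10, 30),
                              amplitude = 100, sigma_px = 1.5,
                              sep_x_um = 2, sep_t_s = 6, seed = NULL) {
  with_seed(seed, {
    acc <- list()
    tries <- 0L
    while (length(acc) < n) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place ", n, " non-overlapping comets")
      v <- stats::runif(1, v_range_um_s[1], v_range_um_s[2])
      life <- stats::runif(1, lifetime_range_s[1], lifetime_range_s[2])
      if (life >= total_time_s || v * life >= axis_length_um) next
      t0 <- stats::runif(1, 0, total_time_s - life)
      x0 <- stats::runif(1, 0, axis_length_um - v * life)
      seg <- rbind(c(x0 / sep_x_um, t0 / sep_t_s),
                   c((x0 + v * life) / sep_x_um, (t0 + life) / sep_t_s))
      ok <- all(vapply(acc, function(s)
        segment_min_dist(seg, s$seg) >= 1, TRUE))
      if (ok)
        acc[[length(acc) + 1L]] <-
          list(row = data.frame(t0_s = t0, x0_um = x0, v_um_s = v,
                                lifetime_s = life, amplitude = amplitude,
                                sigma_px = sigma_px),
               seg = seg)
    }
    do.call(rbind, lapply(acc, `[[`, "row"))
  })
}

#' Simulate an EB3-comet time-lapse movie with ground-truth kinematics
#'
#' Each frame is the sum of static Gaussian spots, the active comets
#' (Gaussian spots moving along the axis at constant velocity), a constant
#' background offset, and optional Gaussian noise. Defaults emulate a
#' 3-minute acquisition at 2 frames per second (360 frames).
#'
#' @param comets Data.frame as returned by [random_comet_spec()]; comet
#'   `i` is at axis position `x0_um + v_um_s * (t - t0_s)` for
#'   `t0_s <= t <= t0_s + lifetime_s` (frame `k` has time
#'   `(k - 1) * frame_interval_s`).
#' @param axis A [polyline_roi()] along which comets move; default a
#'   horizontal line through the image middle with a 5-px margin.
#' @param static_spots Data.frame with `x, y, amplitude, sigma_px`
#'   (pixel coordinates), or `NULL`.
#' @param image_size_px `c(nx, ny)`.
#' @param calibration Isotropic [calibration()] with a frame interval
#'   (default pixel-size dependent caller choice; frame interval 0.5 s
#'   reproduces 2 fps).
#' @param n_frames Number of frames; default 360.
#' @param background Constant offset added to every pixel.
#' @param noise_sd Additive Gaussian noise sd (0 = noise-free).
#' @param seed RNG seed for the noise.
#' @return `list(movie = movie, axis = polyline_roi, truth = list(...))`.
#' @export
make_comet_movie <- function(comets, axis = NULL, static_spots = NULL,
                             image_size_px, calibration, n_frames = 360,
                             background = 0, noise_sd = 0, seed = NULL) {
  px <- require_isotropic(calibration, "make_comet_movie")
  dt <- require_frame_interval(calibration)
  nx <- image_size_px[1]; ny <- image_size_px[2]
  if (is.null(axis))
    axis <- polyline_roi(rbind(c(6, round(ny / 2)),
                               c(nx - 5, round(ny / 2))), width_um = 1)
  axis_len_um <- roi_path_length_px(axis) * px
  total_t <- n_frames * dt
  if (nrow(comets) > 0) {
    bad <- comets$t0_s < 0 | comets$t0_s + comets$lifetime_s > total_t
    if (any(bad)) stop("comet active outside movie duration")
    bad <- comets$x0_um < 0 |
      comets$x0_um + comets$v_um_s * comets$lifetime_s > axis_len_um
    if (any(bad)) stop("comet trajectory leaves the axis")
  }
  # arc-length lookup along the axis (fine sampling, linear interp)
  samp <- sample_polyline(axis$vertices, step_px = 0.25)
  point_at_um <- function(s_um) {
    s_px <- s_um / px
    i <- pmin(pmax(findInterval(s_px, samp$s_px), 1L),
              length(samp$s_px) - 1L)
    f <- (s_px - samp$s_px[i]) / (samp$s_px[i + 1L] - samp$s_px[i])
    cbind(samp$x[i] + f * (samp$x[i + 1L] - samp$x[i]),
          samp$y[i] + f * (samp$y[i + 1L] - samp$y[i]))
  }
  base <- matrix(background, ny, nx)
  if (!is.null(static_spots) && nrow(static_spots) > 0)
    base <- render_spots(base, static_spots)
  frames <- array(0, dim = c(ny, nx, n_frames))
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      t <- (k - 1) * dt
      fr <- base
      if (nrow(comets) > 0) {
        act <- which(comets$t0_s <= t &
                     t <= comets$t0_s + comets$lifetime_s)
        if (length(act) > 0) {
          pos <- comets$x0_um[act] +
            comets$v_um_s[act] * (t - comets$t0_s[act])
          xy <- point_at_um(pos)
          fr <- render_spots(fr, data.frame(
            x = xy[, 1], y = xy[, 2],
            amplitude = comets$amplitude[act],
            sigma_px = comets$sigma_px[act]))
        }
      }
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(ny * nx, sd = noise_sd), ny, nx)
      frames[, , k] <- fr
    }
  })
  list(movie = movie(frames, calibration), axis = axis,
       truth = list(comets = comets, static_spots = static_spots,
                    axis = axis, background = background,
                    noise_sd = noise_sd, seed = seed))
}

# ---- two-channel colocalization pairs ------------------------------------

# Dart-throwing placement of n centers with pairwise min separation,
# avoiding a set of existing centers at the same separation.
place_centers <- function(n, nx, ny, min_sep, margin, avoid = NULL) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > 50000L)
      stop("cannot pack ", n, " spots with separation ", min_sep)
    p <- c(stats::runif(1, 1 + margin, nx - margin),
           stats::runif(1, 1 + margin, ny - margin))
    all_pts <- rbind(pts, avoid)
    if (nrow(all_pts) == 0 ||
        min((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2) >=
          min_sep^2)
      pts <- rbind(pts, p)
  }
  pts
}

#' Simulate a two-channel spot pair with controlled center overlap
#'
#' A fraction of channel-1 spots is re-used at identical centers in
#' channel 2; all other spots (within and across channels) are kept more
#' than `4 * sigma` apart, so the ground-truth Manders overlap is the
#' shared-spot fraction.
#'
#' @param n_ch1,n_ch2 Spot counts per channel.
#' @param overlap_fraction Fraction of channel-1 spots co-positioned in
#'   channel 2 (0..1); the shared count is `round(overlap_fraction * n_ch1)`
#'   and must be `<= n_ch2`.
#' @param image_size_px `c(nx, ny)`.
#' @param calibration A [calibration()].
#' @param amplitude,sigma_px Spot amplitude and sigma.
#' @param seed RNG seed.
#' @return `list(ch1 = image2d, ch2 = image2d, truth = list(...))`.
#' @export
make_coloc_pair <- function(n_ch1, n_ch2, overlap_fraction,
                            image_size_px, calibration,
                            amplitude = 100, sigma_px = 1.5, seed = NULL) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  nx <- image_size_px[1]; ny <- image_size_px[2]
  n_shared <- round(overlap_fraction * n_ch1)
  if (n_shared > n_ch2)
    stop("overlap_fraction implies more shared spots than n_ch2")
  min_sep <- 4 * sigma_px
  margin <- 5 * sigma_px
  with_seed(seed, {
    c1 <- place_centers(n_ch1, nx, ny, min_sep, margin)
    shared_idx <- if (n_shared > 0) sample(n_ch1, n_shared) else integer(0)
    shared <- c1[shared_idx, , drop = FALSE]
    extra2 <- place_centers(n_ch2 - n_shared, nx, ny, min_sep, margin,
                            avoid = c1)
    c2 <- rbind(shared, extra2)
    im <- function(centers) {
      v <- matrix(0, ny, nx)
      if (nrow(centers) > 0)
        v <- render_spots(v, data.frame(x = centers[, 1], y = centers[, 2],
                                        amplitude = amplitude,
                                        sigma_px = sigma_px))
      image2d(v, calibration)
    }
    list(ch1 = im(c1), ch2 = im(c2),
         truth = list(n_spots_ch1 = n_ch1, n_spots_ch2 = n_ch2,
                      overlap_fraction = overlap_fraction,
                      n_shared = n_shared,
                      centers_ch1 = c1, centers_ch2 = c2,
                      amplitude = amplitude, sigma_px = sigma_px,
                      seed = seed))
  })
}

# ---- puncta fields -------------------------------------------------------

#' Simulate a puncta field with known counts inside and outside a mask
#'
#' Gaussian puncta are placed at random pixel centers classified by the
#' mask value at the (rounded) center; all puncta respect a minimum
#' center separation. A constant background offset keeps the noisy image
#' nonnegative (residual negatives are clipped at zero).
#'
#' @param mask A [binary_mask()] defining inside/outside.
#' @param n_inside,n_outside Puncta counts for the two compartments.
#' @param amplitude,sigma_px Punctum amplitude and sigma.
#' @param noise_sd Additive Gaussian noise sd; `amplitude / noise_sd` is
#'   the SNR.
#' @param background Constant offset; default `5 * noise_sd`.
#' @param min_sep_px Minimum center separation; default `4 * sigma_px`.
#' @param edge_margin_px Minimum distance of a punctum center from the
#'   mask boundary (default 2), so the inside/outside ground truth is
#'   never decided by sub-pixel rounding of a boundary-straddling dot.
#' @param seed RNG seed.
#' @return `list(image = image2d, truth = list(...))`.
#' @export
make_puncta_field <- function(mask, n_inside, n_outside,
                              amplitude = 100, sigma_px = 1.5,
                              noise_sd = 0, background = 5 * noise_sd,
                              min_sep_px = 4 * sigma_px,
                              edge_margin_px = 2, seed = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  mv <- mask$values
  ny <- nrow(mv); nx <- ncol(mv)
  if (!any(mv)) stop("mask is empty")
  margin <- ceiling(3 * sigma_px)
  with_seed(seed, {
    place_in <- function(n, want_inside, existing) {
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(pts) < n) {
        tries <- tries + 1L
        if (tries > 50000L)
          stop("cannot pack ", n, " puncta with the given separation")
        p <- c(stats::runif(1, 1 + margin, nx - margin),
               stats::runif(1, 1 + margin, ny - margin))
        em <- ceiling(edge_margin_px)
        nb_r <- max(1L, round(p[2]) - em):min(ny, round(p[2]) + em)
        nb_c <- max(1L, round(p[1]) - em):min(nx, round(p[1]) + em)
        if (!all(mv[nb_r, nb_c] == want_inside)) next
        all_pts <- rbind(pts, existing)
        if (nrow(all_pts) == 0 ||
            min((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2) >=
              min_sep_px^2)
          pts <- rbind(pts, p)
      }
      pts
    }
    inside <- place_in(n_inside, TRUE, NULL)
    outside <- place_in(n_outside, FALSE, inside)
    centers <- rbind(inside, outside)
    v <- matrix(background, ny, nx)
    if (nrow(centers) > 0)
      v <- render_spots(v, data.frame(x = centers[, 1], y = centers[, 2],
                                      amplitude = amplitude,
                                      sigma_px = sigma_px))
    if (noise_sd > 0)
      v <- v + matrix(stats::rnorm(ny * nx, sd = noise_sd), ny, nx)
    v[v < 0] <- 0
    list(image = image2d(v, mask$calibration),
         truth = list(n_inside = n_inside, n_outside = n_outside,
                      centers_inside = inside, centers_outside = outside,
                      amplitude = amplitude, sigma_px = sigma_px,
                      noise_sd = noise_sd, background = background,
                      min_sep_px = min_sep_px, seed = seed))
  })
}

# ---- axial profile images ------------------------------------------------

#' Render a straight axon whose axial intensity follows a given function
#'
#' A horizontal stripe of `width_px` rows carries intensity
#' `f(d) + baseline` at distance `d` (um) from the tip (distance grows to
#' the right, i.e. proximally); the rest of the image sits at `baseline`.
#' The truth record samples `f` at pixel centers, which is what a profile
#' extraction along the stripe should reproduce.
#'
#' @param f Vectorized nonnegative function of distance (um).
#' @param length_um Axon length covered by the profile.
#' @param width_px Stripe width in pixels (odd recommended).
#' @param baseline Additive constant background.
#' @param calibration Isotropic [calibration()].
#' @param margin_px Image margin around the stripe; default 10.
#' @return `list(image = image2d, roi = polyline_roi (tip-first, 1 um
#'   wide), truth = list(distances_um, f_values, baseline))`.
#' @export
make_profile_image <- function(f, length_um = 50, width_px = 5,
                               baseline = 0, calibration,
                               margin_px = 10) {
  px <- require_isotropic(calibration, "make_profile_image")
  len_px <- ceiling(length_um / px)
  nx <- len_px + 2 * margin_px + 1
  ny <- width_px + 2 * margin_px
  tip_col <- margin_px + 1
  rows <- (ny - width_px) %/% 2 + seq_len(width_px)
  d_um <- (0:len_px) * px
  fv <- f(d_um)
  if (any(!is.finite(fv)) || any(fv < 0))
    stop("profile function must be finite and nonnegative")
  v <- matrix(baseline, ny, nx)
  v[rows, tip_col + 0:len_px] <-
    matrix(rep(fv + baseline, each = length(rows)), length(rows))
  yc <- rows[ceiling(length(rows) / 2)]
  roi <- polyline_roi(rbind(c(tip_col, yc), c(tip_col + len_px, yc)),
                      width_um = 1)
  list(image = image2d(v, calibration), roi = roi,
       truth = list(distances_um = d_um, f_values = fv,
                    baseline = baseline))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
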