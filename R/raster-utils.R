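# Internal raster helpers shared by the generators and the measurement
# modules. Pixel convention: x = column, y = row, centers at integers
# starting at 1.

# Pixels of an 8-connected digital line between two continuous points
# (DDA stepping at unit pitch; equivalent to Bresenham for our purposes).
# Returns an n x 2 integer matrix (x, y); pixels outside [1,nx]x[1,ny] are
# dropped when bounds are given.
line_pixels <- function(x0, y0, x1, y1, nx = NULL, ny = NULL) {
  n <- max(abs(x1 - x0), abs(y1 - y0))
  n <- max(1L, ceiling(n))
  t <- seq(0, 1, length.out = n + 1L)
  px <- round(x0 + t * (x1 - x0))
  py <- round(y0 + t * (y1 - y0))
  keep <- !duplicated(cbind(px, py))
  px <- px[keep]; py <- py[keep]
  if (!is.null(nx)) {
    inside <- px >= 1 & px <= nx & py >= 1 & py <= ny
    px <- px[inside]; py <- py[inside]
  }
  cbind(x = as.integer(px), y = as.integer(py))
}

# Set pixels (x, y) in a logical matrix.
set_pixels <- function(mask, xy) {
  if (nrow(xy) > 0)
    mask[cbind(xy[, 2], xy[, 1])] <- TRUE
  mask
}

# One-iteration 3x3 box dilation (EBImage).
dilate3 <- function(mask) {
  out <- EBImage::dilate(mask * 1, EBImage::makeBrush(3, "box")) > 0
  dim(out) <- dim(mask)
  out
}

# 8-connected labeling of a logical matrix via igraph components.
# Returns an integer matrix of labels (0 = background).
label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, ny, nx)
  if (length(idx) == 0L) return(lab)
  id <- matrix(0L, ny, nx)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% ny) + 1L
  c <- ((idx - 1L) %/% ny) + 1L
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    rr <- r + s[1]; cc <- c + s[2]
    ok <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx
    if (!any(ok)) next
    nb <- id[cbind(rr[ok], cc[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        rbind(id[cbind(r[ok], c[ok])][hit], nb[hit])
  }
  if (length(edges) > 0) {
    e <- do.call(cbind, edges)
    g <- igraph::graph_from_edgelist(t(e), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  lab[idx] <- as.integer(comp)
  lab
}

# Add isotropic Gaussian spots to an intensity matrix. spots: data.frame
# with columns x, y (continuous pixel coords), amplitude, sigma_px.
# Each spot is rendered on a +/- 5 sigma window.
render_spots <- function(values, spots) {
  if (is.null(spots) || nrow(spots) == 0L) return(values)
  ny <- nrow(values); nx <- ncol(values)
  for (i in seq_len(nrow(spots))) {
    x0 <- spots$x[i]; y0 <- spots$y[i]
    a <- spots$amplitude[i]; s <- spots$sigma_px[i]
    r <- ceiling(5 * s)
    cx <- max(1L, floor(x0 - r)):min(nx, ceiling(x0 + r))
    cy <- max(1L, floor(y0 - r)):min(ny, ceiling(y0 + r))
    if (length(cx) == 0L || length(cy) == 0L) next
    gx <- exp(-((cx - x0)^2) / (2 * s^2))
    gy <- exp(-((cy - y0)^2) / (2 * s^2))
    values[cy, cx] <- values[cy, cx] + a * (gy %o% gx)
  }
  values
}

# Bilinear interpolation of a matrix at continuous (x, y) pixel
# coordinates (centers at integers). Errors if any point falls outside
# the image.
interp_bilinear <- function(values, x, y) {
  ny <- nrow(values); nx <- ncol(values)
  if (any(x < 1 - 1e-9 | x > nx + 1e-9 | y < 1 - 1e-9 | y > ny + 1e-9))
    stop("sampling point outside image bounds")
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- values[cbind(y0, x0)]
  v01 <- values[cbind(y0, x0 + 1)]
  v10 <- values[cbind(y0 + 1, x0)]
  v11 <- values[cbind(y0 + 1, x0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# Sample points and tangents at unit-pixel arc-length steps along a
# polyline. Returns list(x, y, tx, ty, s_px) with s_px = 0, 1, 2, ...
sample_polyline <- function(vertices, step_px = 1, max_len_px = NULL) {
  d <- diff(vertices)
  seg_len <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (!is.null(max_len_px)) total <- min(total, max_len_px)
  s <- seq(0, total, by = step_px)
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
              length(seg_len))
  f <- (s - cum[seg]) / seg_len[seg]
  x <- vertices[seg, 1] + f * d[seg, 1]
  y <- vertices[seg, 2] + f * d[seg, 2]
  tx <- d[seg, 1] / seg_len[seg]
  ty <- d[seg, 2] / seg_len[seg]
  list(x = x, y = y, tx = tx, ty = ty, s_px = s)
}

# Zhang-Suen thinning of a logical matrix to a 1-px-wide skeleton.
thin_mask <- function(mask) {
  m <- mask
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  m <- pad
  nbrs <- function(m) {
    ny2 <- nrow(m); nx2 <- ncol(m)
    core <- 2:(ny2 - 1L); corx <- 2:(nx2 - 1L)
    list(p2 = m[core - 1L, corx],       # N
         p3 = m[core - 1L, corx + 1L],  # NE
         p4 = m[core, corx + 1L],       # E
         p5 = m[core + 1L, corx + 1L],  # SE
         p6 = m[core + 1L, corx],       # S
         p7 = m[core + 1L, corx - 1L],  # SW
         p8 = m[core, corx - 1L],       # W
         p9 = m[core - 1L, corx - 1L])  # NW
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      n <- nbrs(m)
      p <- m[2:(nrow(m) - 1L), 2:(ncol(m) - 1L)]
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, nrow(p), ncol(p))
      for (k in 1:8)
        A <- A + (!seqs[[k]] & seqs[[k + 1L]])
      if (sub == 1L) {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(n$p2 & n$p4 & n$p6) & !(n$p4 & n$p6 & n$p8)
      } else {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(n$p2 & n$p4 & n$p8) & !(n$p2 & n$p6 & n$p8)
      }
      if (any(cond)) {
        changed <- TRUE
        p[cond] <- FALSE
        m[2:(nrow(m) - 1L), 2:(ncol(m) - 1L)] <- p
      }
    }
    if (!changed) break
  }
  m[2:(ny + 1L), 2:(nx + 1L)]
}

# Separable Gaussian smoothing of a matrix (reflect boundary); used as a
# matched filter before puncta thresholding.
gaussian_smooth2d <- function(values, sigma_px) {
  if (sigma_px <= 0) return(values)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(mat) {  # along rows (first index)
    n <- nrow(mat)
    idx <- c(r:1, 1:n, n:(n - r + 1L))
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(values))))
}
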