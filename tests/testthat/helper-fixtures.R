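# Shared fixtures and independent oracles. Oracles are deliberately
# written from scratch (plain R, no package internals) so they check the
# production code through a different route.

cal1 <- function() calibration(1)

# --- independent line drawing for oracle skeletons ------------------------

# naive DDA line rasterization (independent of the package's drawing)
oracle_line <- function(mask, x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1)
  for (t in seq(0, 1, length.out = ceiling(n) + 1)) {
    x <- round(x0 + t * (x1 - x0)); y <- round(y0 + t * (y1 - y0))
    mask[y, x] <- TRUE
  }
  mask
}

# Random connected tree of 1-px line segments inside a square image.
random_tree_mask <- function(seed, size = 80, n_seg = 6,
                             seg_len = c(8, 22)) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  pts <- matrix(c(round(size / 2), round(size / 2)), 1, 2)  # (x, y)
  m[pts[1, 2], pts[1, 1]] <- TRUE
  for (i in seq_len(n_seg)) {
    repeat {
      fg <- which(m, arr.ind = TRUE)
      k <- sample(nrow(fg), 1)
      x0 <- fg[k, 2]; y0 <- fg[k, 1]
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, seg_len[1], seg_len[2])
      x1 <- round(x0 + len * cos(ang)); y1 <- round(y0 + len * sin(ang))
      if (x1 >= 3 && x1 <= size - 2 && y1 >= 3 && y1 <= size - 2) break
    }
    m <- oracle_line(m, x0, y0, x1, y1)
  }
  m
}

# --- brute-force geodesics (Floyd-Warshall over skeleton pixels) ----------

# All-pairs shortest path over the 8-connected pixel graph of a skeleton
# pixel set; returns the maximum finite distance between nodes (pixels of
# degree != 2). coords: n x 2 (x, y); px_um: isotropic pixel size.
oracle_lsp <- function(coords, px_um) {
  n <- nrow(coords)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  deg <- integer(n)
  for (i in seq_len(n - 1)) {
    dx <- abs(coords[(i + 1):n, 1] - coords[i, 1])
    dy <- abs(coords[(i + 1):n, 2] - coords[i, 2])
    nb <- which(dx <= 1 & dy <= 1)
    for (j in nb + i) {
      w <- sqrt((coords[j, 1] - coords[i, 1])^2 +
                (coords[j, 2] - coords[i, 2])^2) * px_um
      D[i, j] <- D[j, i] <- w
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  nodes <- which(deg != 2L)
  if (length(nodes) < 2) return(0)
  Dn <- D[nodes, nodes]
  max(Dn[is.finite(Dn)])
}

# --- misc ----------------------------------------------------------------

# centroid of the brightest neighborhood of a frame (comet tracking oracle)
frame_centroid <- function(frame, floor_frac = 0.5) {
  thr <- floor_frac * max(frame)
  idx <- which(frame >= thr)
  w <- frame[idx]
  y <- ((idx - 1) %% nrow(frame)) + 1
  x <- ((idx - 1) %/% nrow(frame)) + 1
  c(x = sum(w * x) / sum(w), y = sum(w * y) / sum(w))
}

expect_file_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a) + 10),
                   readBin(b, "raw", file.size(b) + 10))
}
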