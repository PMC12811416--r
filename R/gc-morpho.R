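# Growth-cone morphometry from an actin-outline mask: region metrics
# (area, perimeter, elongation ratio) and skeleton metrics (longest
# shortest path, filopodia count). The caller isolates the growth cone
# (axon shaft excluded) before analysis.

#' Parameters for skeleton-based growth-cone metrics
#'
#' @param min_filopodium_len_um Minimum terminal-branch length counted as
#'   a filopodium; default 1.0 um, the protocol's threshold.
#' @param prune_len_um Maximum length of noise spurs removed before
#'   counting; default 0.5 um (must be smaller than the filopodium
#'   threshold).
#' @return Object of class `gc_params`.
#' @export
gc_params <- function(min_filopodium_len_um = 1.0, prune_len_um = 0.5) {
  if (!(prune_len_um > 0 && min_filopodium_len_um > 0))
    stop("lengths must be positive")
  if (prune_len_um >= min_filopodium_len_um)
    stop("prune_len_um must be smaller than min_filopodium_len_um")
  structure(list(min_filopodium_len_um = min_filopodium_len_um,
                 prune_len_um = prune_len_um, connectivity = 8L),
            class = "gc_params")
}

#' Area, perimeter and elongation ratio of a single-object mask
#'
#' Area is the foreground pixel count times the pixel area. Perimeter is
#' the length of the outer boundary-pixel contour polygon. The elongation
#' (aspect) ratio is the major/minor axis ratio of the ellipse with the
#' same second central moments as the pixel set - the moment reading of a
#' "best-fit ellipse", which recovers the axes of analytic ellipses.
#'
#' @param mask A [binary_mask()] with exactly one connected component
#'   (8-connectivity).
#' @return `list(area_um2, perimeter_um, elongation_ratio)`.
#' @export
region_metrics <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mv <- mask$values
  if (!any(mv)) stop("mask is empty")
  lab <- label8(mv)
  if (max(lab) > 1L)
    stop("mask has ", max(lab), " connected components; expected one")
  cal <- mask$calibration
  pxx <- cal$pixel_size_x_um; pxy <- cal$pixel_size_y_um
  area <- sum(mv) * pxx * pxy
  # outer contour polygon through boundary pixel centers
  oc <- EBImage::ocontour(mv * 1L)[[1]]
  if (nrow(oc) >= 2) {
    # ocontour works in matrix index order: col 1 = row (y), col 2 = x
    d <- diff(rbind(oc, oc[1, , drop = FALSE]))
    perim <- sum(sqrt((d[, 1] * pxy)^2 + (d[, 2] * pxx)^2))
  } else {
    perim <- 4 * max(pxx, pxy)
  }
  idx <- which(mv)
  y_um <- (((idx - 1L) %% nrow(mv)) + 1L) * pxy
  x_um <- (((idx - 1L) %/% nrow(mv)) + 1L) * pxx
  cxx <- stats::var(x_um) * (length(idx) - 1) / length(idx)
  cyy <- stats::var(y_um) * (length(idx) - 1) / length(idx)
  cxy <- stats::cov(x_um, y_um) * (length(idx) - 1) / length(idx)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2),
              symmetric = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps)
  list(area_um2 = area, perimeter_um = perim,
       elongation_ratio = sqrt(ev[1] / ev[2]))
}

# Build the weighted 8-neighbor pixel graph of a skeleton mask.
# Returns list(coords = n x 2 (x, y), graph, degree, adj).
skeleton_graph <- function(skel, cal) {
  pxx <- cal$pixel_size_x_um; pxy <- cal$pixel_size_y_um
  ny <- nrow(skel); nx <- ncol(skel)
  idx <- which(skel)
  n <- length(idx)
  id <- matrix(0L, ny, nx); id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% ny) + 1L
  c <- ((idx - 1L) %/% ny) + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  shifts <- list(c(0L, 1L, pxx), c(1L, 0L, pxy),
                 c(1L, 1L, sqrt(pxx^2 + pxy^2)),
                 c(-1L, 1L, sqrt(pxx^2 + pxy^2)))
  for (s in shifts) {
    rr <- r + s[1]; cc <- c + s[2]
    ok <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx
    nb <- integer(length(idx)); nb[ok] <- id[cbind(rr[ok], cc[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      from <- c(from, seq_len(n)[hit]); to <- c(to, nb[hit])
      w <- c(w, rep(s[3], sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  deg <- igraph::degree(g)
  adj <- vector("list", n)
  if (length(from) > 0) {
    for (k in seq_along(from)) {
      adj[[from[k]]] <- c(adj[[from[k]]], to[k])
      adj[[to[k]]] <- c(adj[[to[k]]], from[k])
    }
  }
  list(coords = cbind(x = c, y = r), graph = g, degree = deg, adj = adj)
}

#' Skeletonize a mask into a 1-px-wide calibrated graph
#'
#' Topology-preserving thinning (Zhang-Suen) followed by construction of
#' the 8-connected pixel graph. Steps weigh 1 or sqrt(2) pixels times the
#' pixel size, so geodesic lengths are in micrometers. Pixels of degree 1
#' are endpoints, degree >= 3 junctions.
#'
#' @param mask A [binary_mask()] with a single connected component.
#' @return Object of class `skeleton`: list with `coords` (n x 2, x/y
#'   pixel coordinates), `graph` (igraph, edge weights in um), `degree`,
#'   `adj` (adjacency list), and `calibration`.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("mask is empty")
  lab <- label8(mask$values)
  if (max(lab) > 1L)
    stop("mask has multiple connected components")
  sk <- thin_mask(mask$values)
  gr <- skeleton_graph(sk, mask$calibration)
  structure(c(gr, list(calibration = mask$calibration)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d px, %d endpoints, %d junction px\n",
              nrow(x$coords), sum(x$degree == 1), sum(x$degree >= 3)))
  invisible(x)
}

# Terminal chains of a skeleton: walks from each endpoint along degree-2
# pixels until a junction (degree >= 3) or another endpoint. Returns a
# list of list(vertices, length_um, ends_at = "junction"|"endpoint").
terminal_chains <- function(skel) {
  deg <- skel$degree
  adj <- skel$adj
  wmat <- function(a, b) {
    d <- skel$coords[a, ] - skel$coords[b, ]
    sqrt((d[1] * skel$calibration$pixel_size_x_um)^2 +
         (d[2] * skel$calibration$pixel_size_y_um)^2)
  }
  chains <- list()
  for (v in which(deg == 1)) {
    path <- v; len <- 0; prev <- 0L; cur <- v
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0L) { ends <- "endpoint"; break }
      nxt <- nxt[1]
      len <- len + wmat(cur, nxt)
      path <- c(path, nxt)
      if (deg[nxt] >= 3L) { ends <- "junction"; break }
      if (deg[nxt] == 1L) { ends <- "endpoint"; break }
      prev <- cur; cur <- nxt
    }
    chains[[length(chains) + 1L]] <-
      list(vertices = path, length_um = len, ends_at = ends)
  }
  chains
}

# Rebuild a skeleton object from a subset of its pixels. Re-thinned:
# removing a spur can leave a redundant pixel hanging off the remaining
# chain via mixed cardinal/diagonal adjacency, which thinning clears.
skeleton_subset <- function(skel, keep) {
  ny <- max(skel$coords[, "y"]) + 1L
  nx <- max(skel$coords[, "x"]) + 1L
  m <- matrix(FALSE, ny, nx)
  m[cbind(skel$coords[keep, "y"], skel$coords[keep, "x"])] <- TRUE
  m <- thin_mask(m)
  gr <- skeleton_graph(m, skel$calibration)
  structure(c(gr, list(calibration = skel$calibration)),
            class = "skeleton")
}

#' Remove short noise spurs from a skeleton
#'
#' Terminal chains shorter than `prune_len_um` (measured endpoint to
#' supporting junction) are deleted, junction pixels retained; repeated
#' until no spur remains, so pruning is idempotent.
#'
#' @param skel A [skeletonize_mask()] result.
#' @param prune_len_um Spur length threshold in micrometers.
#' @return A pruned `skeleton`.
#' @export
prune_skeleton <- function(skel, prune_len_um) {
  repeat {
    chains <- terminal_chains(skel)
    drop <- integer(0)
    for (ch in chains) {
      if (ch$ends_at == "junction" && ch$length_um < prune_len_um)
        drop <- c(drop, ch$vertices[-length(ch$vertices)])
    }
    if (length(drop) == 0L) return(skel)
    keep <- setdiff(seq_len(nrow(skel$coords)), unique(drop))
    if (length(keep) == 0L) return(skel)
    skel <- skeleton_subset(skel, keep)
  }
}

#' Longest shortest path and filopodia count of a skeleton
#'
#' After pruning spurs shorter than `prune_len_um`, the longest shortest
#' path (LSP) is the maximum geodesic distance along the skeleton between
#' any two nodes (endpoints and junction pixels; degree-2 pixels carry
#' length but are not candidates). A filopodium is a terminal branch -
#' an endpoint-to-junction chain - longer than
#' `min_filopodium_len_um`; a junction-free skeleton has zero filopodia.
#'
#' @param skel A `skeleton`.
#' @param params A [gc_params()].
#' @return `list(lsp_um, n_filopodia)`.
#' @export
skeleton_metrics <- function(skel, params = gc_params()) {
  stopifnot(inherits(skel, "skeleton"), inherits(params, "gc_params"))
  if (nrow(skel$coords) == 0L) stop("empty skeleton")
  comp <- igraph::components(skel$graph)
  if (comp$no > 1L)
    stop("disconnected skeleton; upstream mask likely has several objects")
  skel <- prune_skeleton(skel, params$prune_len_um)
  nodes <- which(skel$degree != 2L)
  if (length(nodes) >= 2L) {
    D <- igraph::distances(skel$graph, v = nodes, to = nodes)
    lsp <- max(D[is.finite(D)])
  } else {
    lsp <- 0
  }
  chains <- terminal_chains(skel)
  n_filo <- sum(vapply(chains, function(ch)
    ch$ends_at == "junction" &&
      ch$length_um > params$min_filopodium_len_um, TRUE))
  list(lsp_um = lsp, n_filopodia = as.integer(n_filo))
}

#' All five growth-cone morphometrics for one mask
#'
#' @param mask A single-object [binary_mask()].
#' @param params A [gc_params()].
#' @return One-row data.frame: `area_um2`, `perimeter_um`,
#'   `elongation_ratio`, `lsp_um`, `n_filopodia`.
#' @export
gc_metrics <- function(mask, params = gc_params()) {
  rm <- region_metrics(mask)
  sm <- skeleton_metrics(skeletonize_mask(mask), params)
  data.frame(area_um2 = rm$area_um2, perimeter_um = rm$perimeter_um,
             elongation_ratio = rm$elongation_ratio,
             lsp_um = sm$lsp_um, n_filopodia = sm$n_filopodia)
}
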