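# Medial axis of the white space between contours.
#
# The skeleton detector follows the average-outward-flux characterization:
# on the smooth part of the distance function the normalized gradient field
# has (near-)zero flux through a small neighborhood, while skeleton points
# are sinks of that field (gradients from the two flanking contours converge
# there), giving strongly negative flux.

#' Exact Euclidean distance transform of a raster drawing
#'
#' Distances are exact Euclidean (not chamfer approximations), computed by a
#' two-pass lower-envelope algorithm in C++. Alongside the distance, one
#' nearest contour pixel is recorded for every pixel.
#'
#' @param raster a `raster_drawing` (or a logical mask matrix).
#' @return An object of class `distance_map`: list with `dist` (matrix, px),
#'   `nearest_x`, `nearest_y` (0-based coordinates of a nearest contour
#'   pixel), and `mask` (the input mask).
#' @export
distance_transform <- function(raster) {
  mask <- if (inherits(raster, "raster_drawing")) raster$mask else raster
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("distance_transform: raster has no contour pixels")
  r <- .edt_cpp(mask)
  structure(list(dist = r$dist,
                 nearest_x = r$nearest_col - 1L,
                 nearest_y = r$nearest_row - 1L,
                 mask = mask),
            class = "distance_map")
}

# shift matrix contents by (dy, dx): value at [y, x] becomes M[y+dy, x+dx],
# `fill` outside
shift_mat <- function(M, dy, dx, fill = NA_real_) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 - dy):min(H, H - dy)
  xs <- max(1, 1 - dx):min(W, W - dx)
  out[ys, xs] <- M[ys + dy, xs + dx]
  out
}

# average outward flux of the normalized distance gradient through the
# 8-neighborhood; out-of-canvas neighbors are skipped
average_outward_flux <- function(dist) {
  H <- nrow(dist); W <- ncol(dist)
  gx <- (shift_mat(dist, 0L, 1L) - shift_mat(dist, 0L, -1L)) / 2
  gy <- (shift_mat(dist, 1L, 0L) - shift_mat(dist, -1L, 0L)) / 2
  # one-sided at canvas borders
  gx[, 1] <- dist[, 2] - dist[, 1]; gx[, W] <- dist[, W] - dist[, W - 1]
  gy[1, ] <- dist[2, ] - dist[1, ]; gy[H, ] <- dist[H, ] - dist[H - 1, ]
  nrm <- sqrt(gx^2 + gy^2)
  nz <- nrm > 1e-12
  gx[nz] <- gx[nz] / nrm[nz]; gx[!nz] <- 0
  gy[nz] <- gy[nz] / nrm[nz]; gy[!nz] <- 0
  flux <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    u <- c(dx, dy) / sqrt(dx^2 + dy^2)
    fq <- shift_mat(gx, dy, dx) * u[1] + shift_mat(gy, dy, dx) * u[2]
    ok <- !is.na(fq)
    flux[ok] <- flux[ok] + fq[ok]
    cnt <- cnt + ok
  }
  flux / pmax(cnt, 1)
}

# One pass of Zhang-Suen thinning (step = 1 or 2); returns updated mask
zs_pass <- function(m, step) {
  f <- function(dy, dx) shift_mat(m * 1, dy, dx, fill = 0)
  P2 <- f(-1, 0); P3 <- f(-1, 1); P4 <- f(0, 1); P5 <- f(1, 1)
  P6 <- f(1, 0); P7 <- f(1, -1); P8 <- f(0, -1); P9 <- f(-1, -1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
  A <- matrix(0, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
  cond <- m & B >= 2 & B <= 6 & A == 1
  if (step == 1L) cond <- cond & (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  else            cond <- cond & (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  m[cond] <- FALSE
  m
}

thin_mask <- function(m) {
  repeat {
    m1 <- zs_pass(m, 1L)
    m2 <- zs_pass(m1, 2L)
    if (identical(m2, m)) return(m2)
    m <- m2
  }
}

#' Extract the medial axis from a distance map
#'
#' Axis pixels are the non-contour pixels whose average outward flux of the
#' normalized distance gradient through the 8-neighborhood falls below
#' `flux_threshold`. The raw flux ridge can be two pixels thick at odd
#' inter-contour separations, so the detected set is thinned to unit width
#' before tracing. Each axis point stores its radius (the distance-map
#' value) and its generating contour-pixel pair: the nearest contour pixel
#' on each of the two opposed sides, found by following the distance
#' gradient; if both sides resolve to the same contour pixel a single
#' generator is kept. The canvas border is not treated as a contour.
#'
#' @param dmap a `distance_map`.
#' @param flux_threshold scalar; axis pixels have flux below this
#'   (default -0.25).
#' @return An object of class `medial_axis`: list with `points` (data.frame
#'   x, y, radius, flux, g1x, g1y, g2x, g2y, branch, arc; coordinates
#'   0-based) and `dim` (canvas height, width).
#' @export
extract_medial_axis <- function(dmap, flux_threshold = -0.25) {
  stopifnot(inherits(dmap, "distance_map"))
  H <- nrow(dmap$dist); W <- ncol(dmap$dist)
  if (sum(dmap$mask) < 2L) {
    warning("extract_medial_axis: degenerate raster, empty axis")
    return(empty_axis(H, W))
  }
  flux <- average_outward_flux(dmap$dist)
  ax <- !dmap$mask & flux < flux_threshold & dmap$dist > 0
  if (!any(ax)) return(empty_axis(H, W))
  ax <- thin_mask(ax)
  iy <- row(ax)[ax] - 1L  # 0-based y
  ix <- col(ax)[ax] - 1L  # 0-based x
  n <- length(ix)
  lin <- function(x, y) x * H + y + 1L
  g1x <- dmap$nearest_x[lin(ix, iy)]
  g1y <- dmap$nearest_y[lin(ix, iy)]
  g2x <- rep(NA_integer_, n); g2y <- rep(NA_integer_, n)
  # opposite-side generator: among the 8 neighbors, take the one whose own
  # nearest contour pixel lies in the direction most opposed to g1
  offs <- cbind(dx = rep(-1:1, times = 3), dy = rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  v1x <- g1x - ix; v1y <- g1y - iy
  v1n <- sqrt(v1x^2 + v1y^2); v1n[v1n == 0] <- 1
  best_cos <- rep(Inf, n)
  for (k in seq_len(nrow(offs))) {
    qx <- ix + offs[k, 1]; qy <- iy + offs[k, 2]
    ok <- qx >= 0 & qx < W & qy >= 0 & qy < H
    sx <- rep(NA_integer_, n); sy <- rep(NA_integer_, n)
    sx[ok] <- dmap$nearest_x[lin(qx[ok], qy[ok])]
    sy[ok] <- dmap$nearest_y[lin(qx[ok], qy[ok])]
    wx <- sx - ix; wy <- sy - iy
    wn <- sqrt(wx^2 + wy^2); wn[!is.na(wn) & wn == 0] <- 1
    cosang <- (wx * v1x + wy * v1y) / (wn * v1n)
    upd <- ok & !is.na(cosang) & cosang < best_cos
    best_cos[upd] <- cosang[upd]
    g2x[upd] <- sx[upd]; g2y[upd] <- sy[upd]
  }
  # no genuinely opposed side found -> single generator
  single <- !is.finite(best_cos) | best_cos > -0.2 |
    (g2x == g1x & g2y == g1y)
  g2x[single] <- NA_integer_; g2y[single] <- NA_integer_
  pts <- data.frame(x = ix, y = iy,
                    radius = dmap$dist[lin(ix, iy)],
                    flux = flux[lin(ix, iy)],
                    g1x = g1x, g1y = g1y, g2x = g2x, g2y = g2y,
                    branch = NA_integer_, arc = NA_integer_)
  structure(list(points = pts, dim = c(H, W)), class = "medial_axis")
}

empty_axis <- function(H, W) {
  structure(list(points = data.frame(x = integer(), y = integer(),
                                     radius = double(), flux = double(),
                                     g1x = integer(), g1y = integer(),
                                     g2x = integer(), g2y = integer(),
                                     branch = integer(), arc = integer()),
                 dim = c(H, W)),
            class = "medial_axis")
}

#' @export
print.medial_axis <- function(x, ...) {
  nb <- length(unique(x$points$branch[!is.na(x$points$branch)]))
  cat(sprintf("<medial_axis> %d point(s), %d branch(es)\n",
              nrow(x$points), nb))
  invisible(x)
}

#' Group medial-axis pixels into simple branches
#'
#' 8-connected axis pixels are grouped into simple branches split at
#' junction pixels (pixels with three or more axis neighbors); the arc index
#' increases consecutively along each branch. Each junction pixel is
#' appended to one incident branch so that every axis pixel belongs to
#' exactly one branch; isolated pixels become length-1 branches.
#'
#' @param axis a `medial_axis` from [extract_medial_axis()].
#' @return The `medial_axis` with `branch` and `arc` columns filled.
#' @export
trace_branches <- function(axis) {
  stopifnot(inherits(axis, "medial_axis"))
  pts <- axis$points
  n <- nrow(pts)
  if (n == 0L) return(axis)
  H <- axis$dim[1]; W <- axis$dim[2]
  idx <- matrix(0L, H, W)
  idx[cbind(pts$y + 1L, pts$x + 1L)] <- seq_len(n)
  offs <- cbind(dx = rep(-1:1, times = 3), dy = rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    qx <- pts$x[i] + offs[, 1]; qy <- pts$y[i] + offs[, 2]
    ok <- qx >= 0 & qx < W & qy >= 0 & qy < H
    ids <- idx[cbind(qy[ok] + 1L, qx[ok] + 1L)]
    nbr[[i]] <- ids[ids > 0L]
  }
  deg <- lengths(nbr)
  junction <- deg >= 3L
  branch <- rep(NA_integer_, n); arc <- rep(NA_integer_, n)
  bid <- 0L
  visited <- junction  # junctions handled afterwards
  # walk simple paths through non-junction pixels
  simple_nbrs <- lapply(seq_len(n), function(i) nbr[[i]][!junction[nbr[[i]]]])
  sdeg <- lengths(simple_nbrs)
  order_candidates <- order(sdeg)  # endpoints (sdeg<=1) first so paths start at ends
  for (s in order_candidates) {
    if (visited[s] || junction[s]) next
    bid <- bid + 1L
    cur <- s; a <- 0L
    repeat {
      a <- a + 1L
      visited[cur] <- TRUE; branch[cur] <- bid; arc[cur] <- a
      nxt <- simple_nbrs[[cur]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      # prefer 4-connected continuation for cleaner arcs
      if (length(nxt) > 1L) {
        d4 <- abs(pts$x[nxt] - pts$x[cur]) + abs(pts$y[nxt] - pts$y[cur])
        nxt <- nxt[order(d4)]
      }
      cur <- nxt[1]
    }
  }
  # attach each junction pixel to an adjacent branch end, else group
  # junction clusters into their own branches
  jn <- which(junction)
  for (j in jn) {
    if (!is.na(branch[j])) next
    attached <- FALSE
    for (b in unique(branch[nbr[[j]]][!is.na(branch[nbr[[j]]])])) {
      members <- which(branch == b)
      last <- members[which.max(arc[members])]
      first <- members[which.min(arc[members])]
      if (last %in% nbr[[j]]) {
        branch[j] <- b; arc[j] <- arc[last] + 1L; attached <- TRUE; break
      }
      if (first %in% nbr[[j]]) {
        arc[members] <- arc[members] + 1L
        branch[j] <- b; arc[j] <- 1L; attached <- TRUE; break
      }
    }
    if (!attached) { bid <- bid + 1L; branch[j] <- bid; arc[j] <- 1L }
  }
  axis$points$branch <- branch
  axis$points$arc <- arc
  axis
}
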