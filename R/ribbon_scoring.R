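# Local ribbon-symmetry (parallelism) scoring.
#
# Parallel contours keep a constant separation, so the radius function along
# the medial axis between them is constant; every change of the radius above
# a small tolerance signals a departure from parallelism. The score of an
# axis point counts radius changes inside a local window along its branch
# and maps the count linearly to [0, 1].

#' Score the medial axis for local ribbon symmetry
#'
#' For each axis point a window of `W` points (arc-length, centered,
#' truncated at branch ends) is taken along its branch; `n` counts the
#' consecutive pairs whose radius differs by more than `epsilon`. The score
#' is `sigma = 1 - n / (W_eff - 1)` with `W_eff` the realized window length;
#' a length-1 window scores 1.
#'
#' @param axis a traced `medial_axis` (see [trace_branches()]).
#' @param W odd window length in axis points (default 11).
#' @param epsilon radius-change tolerance in px (default 0.5, which absorbs
#'   the rasterization quantization of the radius so exactly parallel
#'   digital lines score 1).
#' @return An object of class `axis_score`: the axis points data.frame with
#'   columns `n_changes`, `w_eff`, `score` added.
#' @export
score_axis <- function(axis, W = 11L, epsilon = 0.5) {
  stopifnot(inherits(axis, "medial_axis"))
  W <- as.integer(W)
  if (W < 3L || W %% 2L == 0L) stop("score_axis: W must be an odd integer >= 3")
  if (epsilon < 0) stop("score_axis: epsilon must be >= 0")
  pts <- axis$points
  if (nrow(pts) > 0L && anyNA(pts$branch))
    stop("score_axis: axis has untraced points; run trace_branches() first")
  pts$n_changes <- NA_integer_; pts$w_eff <- NA_integer_; pts$score <- NA_real_
  h <- (W - 1L) %/% 2L
  for (b in unique(pts$branch)) {
    sel <- which(pts$branch == b)
    sel <- sel[order(pts$arc[sel])]
    r <- pts$radius[sel]
    L <- length(r)
    chg <- if (L > 1L) as.integer(abs(diff(r)) > epsilon) else integer(0)
    cum <- c(0L, cumsum(chg))  # cum[i] = changes among pairs 1..i-1
    for (i in seq_len(L)) {
      lo <- max(1L, i - h); hi <- min(L, i + h)
      w_eff <- hi - lo + 1L
      n <- cum[hi] - cum[lo]
      s <- if (w_eff == 1L) 1 else 1 - n / (w_eff - 1L)
      j <- sel[i]
      pts$n_changes[j] <- n; pts$w_eff[j] <- w_eff; pts$score[j] <- s
    }
  }
  structure(list(points = pts, dim = axis$dim, W = W, epsilon = epsilon),
            class = c("axis_score", "medial_axis"))
}

#' Project axis scores onto contour pixels
#'
#' Each axis point passes its score to the contour pixels of its generating
#' pair. A contour pixel can be flanked by skeletons on both sides, so its
#' final score is the maximum over all scores it receives. Contour pixels
#' reached by no axis point are filled with the score of the nearest
#' assigned pixel of the same contour (ties take the maximum score); pixels
#' of contours with no assigned pixel at all are set to 0.
#'
#' @param axis_score an `axis_score` from [score_axis()].
#' @param raster the `raster_drawing` the axis was computed from.
#' @return An object of class `contour_score_map`: list with `score`
#'   (matrix, NA off-contour), `raster`, and `filled` (logical matrix,
#'   TRUE where the score came from the fill rule).
#' @export
project_to_contours <- function(axis_score, raster) {
  stopifnot(inherits(axis_score, "axis_score"),
            inherits(raster, "raster_drawing"))
  mask <- raster$mask
  H <- nrow(mask); W <- ncol(mask)
  smap <- matrix(NA_real_, H, W)
  pts <- axis_score$points
  if (nrow(pts) > 0L) {
    # Each axis point contributes its score to the contact set on each
    # side: the nearest contour pixel found by the distance gradient plus
    # its 8-neighboring contour pixels that lie within R + 0.5 of the axis
    # point (the gradient is multi-valued where several contour pixels are
    # equidistant; the EDT records only one of them). The per-pixel score
    # is the max over all contributions (a contour pixel is flanked by a
    # skeleton on either side).
    gx <- c(pts$g1x, pts$g2x); gy <- c(pts$g1y, pts$g2y)
    axx <- rep(pts$x, 2); axy <- rep(pts$y, 2)
    rad <- rep(pts$radius, 2); ssc <- rep(pts$score, 2)
    ok <- !is.na(gx)
    gx <- gx[ok]; gy <- gy[ok]; axx <- axx[ok]; axy <- axy[ok]
    rad <- rad[ok]; ssc <- ssc[ok]
    ii_all <- integer(0); ss_all <- numeric(0)
    for (dx in -1:1) for (dy in -1:1) {
      cx <- gx + dx; cy <- gy + dy
      keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
      keep[keep] <- mask[cbind(cy[keep] + 1L, cx[keep] + 1L)] &
        sqrt((cx[keep] - axx[keep])^2 + (cy[keep] - axy[keep])^2) <=
          rad[keep] + 0.5
      ii_all <- c(ii_all, cx[keep] * H + cy[keep] + 1L)
      ss_all <- c(ss_all, ssc[keep])
    }
    if (length(ii_all)) {
      agg <- tapply(ss_all, ii_all, max)
      smap[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  smap[!mask] <- NA_real_  # guard: generators are contour pixels by construction
  filled <- matrix(FALSE, H, W)
  miss <- mask & is.na(smap)
  if (any(miss)) {
    prov <- raster$provenance
    for (k in unique(prov[miss])) {
      sel_k <- !is.na(prov) & prov == k
      mk <- which(sel_k & miss)
      ak <- which(sel_k & !is.na(smap))
      if (length(ak) == 0L) { smap[mk] <- 0; filled[mk] <- TRUE; next }
      my <- (mk - 1L) %% H; mx <- (mk - 1L) %/% H
      ay <- (ak - 1L) %% H; ax <- (ak - 1L) %/% H
      d2 <- outer(mx, ax, function(a, b) (a - b)^2) +
            outer(my, ay, function(a, b) (a - b)^2)
      sc <- smap[ak]
      for (i in seq_along(mk)) {
        dmin <- min(d2[i, ])
        smap[mk[i]] <- max(sc[d2[i, ] == dmin])  # ties -> max
      }
      filled[mk] <- TRUE
    }
  }
  structure(list(score = smap, raster = raster, filled = filled),
            class = "contour_score_map")
}

#' @export
print.contour_score_map <- function(x, ...) {
  sc <- x$score[x$raster$mask]
  cat(sprintf("<contour_score_map> %d contour pixel(s), mean score %.3f\n",
              length(sc), mean(sc)))
  invisible(x)
}

#' Average local parallelism of a drawing
#'
#' The unweighted mean of the ribbon-symmetry score over all contour
#' pixels: the per-image parallelism rating used as the parametric
#' regressor in the event-related analysis.
#'
#' @param score_map a `contour_score_map`.
#' @return Scalar in `[0, 1]`.
#' @export
average_parallelism <- function(score_map) {
  stopifnot(inherits(score_map, "contour_score_map"))
  sc <- score_map$score[score_map$raster$mask]
  if (length(sc) == 0L) stop("average_parallelism: empty score map")
  mean(sc)
}

#' Score a drawing end to end
#'
#' Convenience wrapper: rasterize (if needed), distance transform, medial
#' axis extraction, branch tracing, axis scoring, projection to contours.
#'
#' @param drawing a `line_drawing` or `raster_drawing`.
#' @param W,epsilon see [score_axis()].
#' @param flux_threshold see [extract_medial_axis()].
#' @return A `contour_score_map`.
#' @export
score_drawing <- function(drawing, W = 11L, epsilon = 0.5,
                          flux_threshold = -0.25) {
  raster <- if (inherits(drawing, "line_drawing")) rasterize(drawing) else drawing
  stopifnot(inherits(raster, "raster_drawing"))
  dmap <- distance_transform(raster)
  axis <- extract_medial_axis(dmap, flux_threshold = flux_threshold)
  axis <- trace_branches(axis)
  sc <- score_axis(axis, W = W, epsilon = epsilon)
  project_to_contours(sc, raster)
}

#' Export a contour score map as CSV
#'
#' @param score_map a `contour_score_map`.
#' @param path output CSV path (columns x, y, contour_index, score).
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(score_map, path) {
  mask <- score_map$raster$mask
  H <- nrow(mask)
  ii <- which(mask)
  df <- data.frame(x = (ii - 1L) %/% H, y = (ii - 1L) %% H,
                   contour_index = score_map$raster$provenance[ii],
                   score = score_map$score[ii])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
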