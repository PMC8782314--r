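# Synthetic line drawings with known parallelism structure.
#
# Shapes are placed in disjoint grid cells so the parallelism ground truth
# of each shape is not contaminated by its neighbors:
#  - ribbon pairs: congruent polylines at a constant normal separation
#    (optionally perturbed by Gaussian jitter of the separation), the
#    locally parallel structure;
#  - wedges: two lines meeting at an opening angle, whose radius function
#    grows along the bisector (non-parallel by construction);
#  - random open curves: smooth random-walk polylines with no controlled
#    symmetry.

#' Specify a synthetic drawing
#'
#' @param n_ribbons number of parallel ribbon pairs.
#' @param jitter standard deviation (px) of the perpendicular jitter of the
#'   ribbon separation; 0 gives exactly parallel digital lines.
#' @param n_wedges number of wedge pairs.
#' @param wedge_angle wedge opening angle in degrees, in (0, 90].
#' @param n_curves number of random open curves.
#' @param canvas c(height, width) in px.
#' @return An object of class `drawing_spec`.
#' @export
drawing_spec <- function(n_ribbons = 2L, jitter = 0, n_wedges = 1L,
                         wedge_angle = 30, n_curves = 1L,
                         canvas = c(256L, 256L)) {
  stopifnot(n_ribbons >= 0, n_wedges >= 0, n_curves >= 0, jitter >= 0,
            wedge_angle > 0, wedge_angle <= 90)
  structure(list(n_ribbons = as.integer(n_ribbons), jitter = jitter,
                 n_wedges = as.integer(n_wedges), wedge_angle = wedge_angle,
                 n_curves = as.integer(n_curves),
                 canvas = as.integer(canvas)),
            class = "drawing_spec")
}

# a straight or jittered ribbon pair inside box (x0..x1, y0..y1);
# returns list of two contours
make_ribbon_pair <- function(x0, y0, x1, y1, jitter) {
  # axis-aligned only: a diagonal digital ribbon's end ridge continues
  # collinearly into the midline branch, leaving a few end pixels below 1,
  # so axis-aligned pairs are the exactly-parallel exemplars (see vignette)
  orient <- sample(c("h", "v"), 1L)
  sep <- sample(c(4L, 6L, 8L), 1L)
  jit <- function(n) if (jitter > 0) rnorm(n, 0, jitter) else numeric(n)
  if (orient == "h") {
    L <- (x1 - x0) - 2L
    yy <- round(runif(1, y0 + 1, y1 - sep - 1))
    xs <- seq(x0, x0 + L, by = 8); xs[length(xs)] <- x0 + L
    base <- cbind(xs, rep(yy, length(xs)))
    off <- cbind(numeric(length(xs)), sep + jit(length(xs)))
  } else {
    L <- (y1 - y0) - 2L
    xx <- round(runif(1, x0 + 1, x1 - sep - 1))
    ys <- seq(y0, y0 + L, by = 8); ys[length(ys)] <- y0 + L
    base <- cbind(rep(xx, length(ys)), ys)
    off <- cbind(sep + jit(length(ys)), numeric(length(ys)))
  }
  second <- base + off
  list(contour(base), contour(second))
}

make_wedge <- function(x0, y0, x1, y1, angle_deg) {
  th <- angle_deg * pi / 180
  L <- min(x1 - x0, (y1 - y0) / max(sin(th), 0.2)) - 2
  apex <- c(x0 + 1, y0 + 1)
  c1 <- rbind(apex, apex + c(L, 0))
  c2 <- rbind(apex, apex + L * c(cos(th), sin(th)))
  list(contour(c1), contour(c2))
}

make_curve <- function(x0, y0, x1, y1) {
  n <- sample(5:8, 1L)
  px <- numeric(n); py <- numeric(n)
  px[1] <- runif(1, x0 + 2, x1 - 2); py[1] <- runif(1, y0 + 2, y1 - 2)
  ang <- runif(1, 0, 2 * pi)
  step <- (x1 - x0) / (n + 1)
  for (i in 2:n) {
    ang <- ang + rnorm(1, 0, 0.6)
    px[i] <- min(max(px[i - 1] + step * cos(ang), x0 + 1), x1 - 1)
    py[i] <- min(max(py[i - 1] + step * sin(ang), y0 + 1), y1 - 1)
  }
  list(contour(cbind(px, py)))
}

#' Generate a synthetic line drawing
#'
#' Deterministic under `seed`. Shapes are laid out on a jittered grid; the
#' per-contour ground-truth label (`"parallel"` for ribbon contours,
#' `"nonparallel"` otherwise) is attached as attribute `contour_label`.
#'
#' @param spec a [drawing_spec()].
#' @param seed integer seed.
#' @param category optional category label carried by the drawing.
#' @return A `line_drawing` with attribute `contour_label`.
#' @export
generate_drawing <- function(spec, seed = 1L, category = NULL) {
  stopifnot(inherits(spec, "drawing_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_shapes <- spec$n_ribbons + spec$n_wedges + spec$n_curves
  if (n_shapes == 0L)
    return(line_drawing(list(), canvas = spec$canvas, category = category))
  g <- ceiling(sqrt(n_shapes))
  H <- spec$canvas[1]; W <- spec$canvas[2]
  ch <- floor(H / g); cw <- floor(W / g)
  if (min(ch, cw) < 26L)
    stop("generate_drawing: canvas too small for ", n_shapes, " shapes")
  cells <- expand.grid(cy = 0:(g - 1L), cx = 0:(g - 1L))
  cells <- cells[sample.int(nrow(cells), n_shapes), , drop = FALSE]
  kinds <- c(rep("ribbon", spec$n_ribbons), rep("wedge", spec$n_wedges),
             rep("curve", spec$n_curves))
  contours <- list(); labels <- character(0)
  margin <- 4L
  for (i in seq_len(n_shapes)) {
    x0 <- cells$cx[i] * cw + margin; x1 <- (cells$cx[i] + 1L) * cw - margin
    y0 <- cells$cy[i] * ch + margin; y1 <- (cells$cy[i] + 1L) * ch - margin
    new <- switch(kinds[i],
      ribbon = make_ribbon_pair(x0, y0, x1, y1, spec$jitter),
      wedge  = make_wedge(x0, y0, x1, y1, spec$wedge_angle),
      curve  = make_curve(x0, y0, x1, y1))
    # clamp to canvas (jitter can push a point over a cell edge)
    new <- lapply(new, function(cc) {
      p <- cc$points
      p[, 1] <- pmin(pmax(p[, 1], 0), W - 1L)
      p[, 2] <- pmin(pmax(p[, 2], 0), H - 1L)
      contour(p, cc$closed)
    })
    contours <- c(contours, new)
    labels <- c(labels, rep(if (kinds[i] == "ribbon") "parallel" else "nonparallel",
                            length(new)))
  }
  d <- line_drawing(contours, canvas = spec$canvas, category = category)
  attr(d, "contour_label") <- labels
  d
}

#' Generate a full stimulus set (intact / most / least per drawing)
#'
#' For each synthetic drawing the full pipeline is run (rasterize, score,
#' split), producing the three experimental versions: the intact drawing
#' and the most- and least-parallel half-images with equal contour-pixel
#' counts. Each drawing's shape counts are drawn from a small distribution
#' around `spec` so the set has the natural variability of a stimulus set;
#' one of the six scene-category labels is assigned cyclically.
#'
#' @param n_drawings number of drawings (the full set of the decoding
#'   experiment has 475).
#' @param spec base [drawing_spec()]; per-drawing shape counts are sampled
#'   around it.
#' @param seed master seed; per-drawing seeds are derived from it.
#' @param out_dir if non-NULL, PBM rasters (`<id>_<version>.pbm`) and the
#'   manifest CSV are written there.
#' @param vary logical; sample shape counts/jitter per drawing (default
#'   TRUE).
#' @return An object of class `stimulus_set`: list with `manifest`
#'   (data.frame drawing, category, version, n_pixels, mean_score; 3 rows
#'   per drawing) and `out_dir`.
#' @export
generate_stimulus_set <- function(n_drawings, spec = drawing_spec(),
                                  seed = 1L, out_dir = NULL, vary = TRUE) {
  stopifnot(n_drawings >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_drawings)
  rows <- vector("list", n_drawings)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n_drawings)) {
    set.seed(seeds[i])
    sp <- if (vary) {
      drawing_spec(n_ribbons = sample(1:3, 1L),
                   jitter = sample(c(0, 0.5, 1), 1L),
                   n_wedges = sample(1:2, 1L),  # always some non-parallel structure
                   wedge_angle = runif(1, 15, 60),
                   n_curves = sample(0:2, 1L),
                   canvas = spec$canvas)
    } else spec
    category <- .CATEGORIES[(i - 1L) %% 6L + 1L]
    d <- generate_drawing(sp, seed = seeds[i], category = category)
    sm <- score_drawing(d)
    sp2 <- split_half(sm, seed = seeds[i])
    id <- sprintf("d%04d", i)
    rows[[i]] <- data.frame(
      drawing = id, category = category,
      version = c("intact", "most", "least"),
      n_pixels = c(sum(sp2$intact$mask), sum(sp2$most$mask), sum(sp2$least$mask)),
      mean_score = c(average_parallelism(sm), sp2$mean_most, sp2$mean_least))
    if (!is.null(out_dir)) {
      write_pbm(sp2$intact, file.path(out_dir, paste0(id, "_intact.pbm")))
      write_pbm(sp2$most, file.path(out_dir, paste0(id, "_most.pbm")))
      write_pbm(sp2$least, file.path(out_dir, paste0(id, "_least.pbm")))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, out_dir = out_dir),
            class = "stimulus_set")
}
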