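#' @useDynLib ribbonsym, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median optim pf pt p.adjust rnorm runif sd t.test
#' @importFrom utils read.csv write.csv
NULL

# Coordinate convention: x grows rightwards (columns), y grows downwards
# (rows), both 0-based with pixel centers at integers. Pixel (x, y) maps to
# mask[y + 1, x + 1].

#' Create a contour
#'
#' A contour is an ordered polyline of (x, y) points in pixel units. Closed
#' contours connect the last point back to the first implicitly (the first
#' point is not duplicated).
#'
#' @param points numeric matrix with 2 columns (x, y) or a 2-column
#'   data.frame; at least 2 rows.
#' @param closed logical; if TRUE the last point connects back to the first.
#' @return An object of class `contour`.
#' @export
contour <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour: `points` must have exactly 2 columns (x, y)")
  if (nrow(points) < 2L)
    stop("contour: a contour needs at least 2 points")
  if (!all(is.finite(points)))
    stop("contour: all coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "contour")
}

#' Create a line drawing
#'
#' @param contours list of [contour()] objects (may be empty).
#' @param canvas integer vector `c(height, width)` in pixels.
#' @param category optional character label (e.g. a scene category).
#' @return An object of class `line_drawing`.
#' @export
line_drawing <- function(contours = list(), canvas = c(512L, 512L),
                         category = NULL) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas < 1L))
    stop("line_drawing: `canvas` must be c(height, width), both >= 1")
  for (k in seq_along(contours)) {
    cc <- contours[[k]]
    if (!inherits(cc, "contour"))
      stop("line_drawing: element ", k, " is not a contour")
    p <- cc$points
    if (any(p[, 1] < 0 | p[, 1] >= canvas[2] | p[, 2] < 0 | p[, 2] >= canvas[1]))
      stop("line_drawing: contour ", k, " has points outside the canvas")
  }
  structure(list(contours = contours, canvas = canvas, category = category),
            class = "line_drawing")
}

#' @export
print.line_drawing <- function(x, ...) {
  cat(sprintf("<line_drawing> %d contour(s) on %dx%d canvas%s\n",
              length(x$contours), x$canvas[1], x$canvas[2],
              if (is.null(x$category)) "" else paste0(" [", x$category, "]")))
  invisible(x)
}

# integer Bresenham line between pixel centers; returns matrix of (x, y)
bresenham <- function(x0, y0, x1, y1) {
  x0 <- as.integer(round(x0)); y0 <- as.integer(round(y0))
  x1 <- as.integer(round(x1)); y1 <- as.integer(round(y1))
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  n <- max(dx, dy) + 1L
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

#' Rasterize a line drawing
#'
#' Renders every polyline segment as an 8-connected 1-pixel-wide digital
#' line (integer Bresenham, no anti-aliasing). A provenance grid records
#' which contour produced each pixel; where several contours write the same
#' pixel the lowest contour index wins.
#'
#' @param drawing a [line_drawing()].
#' @return An object of class `raster_drawing` with elements `mask`
#'   (logical height x width matrix) and `provenance` (integer matrix,
#'   `NA` off-contour).
#' @export
rasterize <- function(drawing) {
  stopifnot(inherits(drawing, "line_drawing"))
  H <- drawing$canvas[1]; W <- drawing$canvas[2]
  mask <- matrix(FALSE, H, W)
  prov <- matrix(NA_integer_, H, W)
  if (length(drawing$contours) == 0L)
    warning("rasterize: empty drawing, returning empty mask")
  for (k in seq_along(drawing$contours)) {
    cc <- drawing$contours[[k]]
    p <- round(cc$points)
    if (any(p[, 1] < 0 | p[, 1] > W - 1 | p[, 2] < 0 | p[, 2] > H - 1))
      stop("rasterize: contour ", k, " leaves the canvas after rounding")
    segs <- seq_len(nrow(p) - 1L)
    pts <- do.call(rbind, lapply(segs, function(i)
      bresenham(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2])))
    if (cc$closed && nrow(p) > 2L)
      pts <- rbind(pts, bresenham(p[nrow(p), 1], p[nrow(p), 2], p[1, 1], p[1, 2]))
    # column-major linear index of pixel (x, y) -> mask[y + 1, x + 1]
    idx <- pts[, 1] * H + pts[, 2] + 1L
    mask[idx] <- TRUE
    new <- is.na(prov[idx])
    prov[idx[new]] <- k
  }
  structure(list(mask = mask, provenance = prov), class = "raster_drawing")
}

#' @export
print.raster_drawing <- function(x, ...) {
  cat(sprintf("<raster_drawing> %dx%d, %d contour pixel(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Write a line drawing to a JSON file
#'
#' One JSON document per drawing: contours as point arrays, canvas size,
#' optional category label. Numeric serialization is lossless (full double
#' precision), so write-then-read reproduces the points exactly.
#'
#' @param drawing a [line_drawing()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drawing <- function(drawing, path) {
  stopifnot(inherits(drawing, "line_drawing"))
  doc <- list(
    canvas = drawing$canvas,
    category = drawing$category,
    contours = lapply(drawing$contours, function(cc)
      list(closed = cc$closed,
           points = unname(cc$points)))
  )
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a line drawing from a JSON file
#'
#' @param path JSON file written by [write_drawing()].
#' @return A [line_drawing()].
#' @export
read_drawing <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e)
                    stop("read_drawing: cannot parse ", path, ": ",
                         conditionMessage(e)))
  if (is.null(doc$canvas) || length(doc$canvas) != 2L)
    stop("read_drawing: field `canvas` missing or malformed in ", path)
  if (is.null(doc$contours))
    stop("read_drawing: field `contours` missing in ", path)
  cs <- doc$contours
  # jsonlite may return a data.frame (points as list column) or a list
  mk <- function(points, closed, k) {
    points <- as.matrix(points)
    if (is.null(dim(points)) || nrow(points) < 2L)
      stop("read_drawing: contour ", k, ": needs >= 2 points (field `points`)")
    contour(points, closed = isTRUE(closed))
  }
  contours <-
    if (is.data.frame(cs)) {
      lapply(seq_len(nrow(cs)), function(k) mk(cs$points[[k]], cs$closed[[k]], k))
    } else {
      lapply(seq_along(cs), function(k) mk(cs[[k]]$points, cs[[k]]$closed, k))
    }
  line_drawing(contours, canvas = doc$canvas,
               category = if (is.null(doc$category)) NULL else doc$category)
}

#' Write a binary mask as a plain-text PBM (P1) image
#'
#' Lossless 1-bit raster interchange. PBM rows run top to bottom, matching
#' the y-down pixel convention; 1 = contour pixel (black).
#'
#' @param mask logical matrix (or a `raster_drawing`).
#' @param path output path (conventionally `.pbm`).
#' @return `path`, invisibly.
#' @export
write_pbm <- function(mask, path) {
  if (inherits(mask, "raster_drawing")) mask <- mask$mask
  stopifnot(is.matrix(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(mask), nrow(mask))), con)
  body <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read a plain-text PBM (P1) image as a logical mask
#'
#' @param path PBM file.
#' @return Logical matrix, TRUE = black (contour) pixel.
#' @export
read_pbm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (length(txt) < 2L || txt[1] != "P1")
    stop("read_pbm: ", path, " is not a plain PBM (P1) file (line 1)")
  dims <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  if (length(dims) != 2L || any(is.na(dims)))
    stop("read_pbm: malformed dimension line (line 2) in ", path)
  vals <- as.integer(unlist(strsplit(trimws(txt[-(1:2)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2])
    stop("read_pbm: pixel count mismatch in ", path)
  matrix(as.logical(vals), nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
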