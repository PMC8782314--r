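# Most-/least-parallel half-images.

#' Split a scored drawing into most- and least-parallel halves
#'
#' Contour pixels are rank ordered by their parallelism score; the top half
#' forms the most-parallel half-image and the bottom half the
#' least-parallel half-image, so both contain an equal number of contour
#' pixels (for odd totals the extra pixel goes to the most-parallel half).
#' Ties are broken by a seeded uniform shuffle so the split is deterministic
#' under a fixed seed.
#'
#' @param score_map a `contour_score_map` with every contour pixel scored.
#' @param seed integer seed for tie-breaking.
#' @return An object of class `split_pair`: list with `most`, `least`,
#'   `intact` (`raster_drawing`s), `threshold_rank` (number of pixels in
#'   the most half) and the mean scores of both halves.
#' @export
split_half <- function(score_map, seed = 1L) {
  stopifnot(inherits(score_map, "contour_score_map"))
  mask <- score_map$raster$mask
  ii <- which(mask)
  if (length(ii) == 0L) stop("split_half: empty score map")
  sc <- score_map$score[ii]
  if (anyNA(sc)) stop("split_half: unassigned contour-pixel scores")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tie <- sample.int(length(ii))
  ord <- order(-sc, tie)
  n_most <- ceiling(length(ii) / 2)
  most_idx <- ii[ord[seq_len(n_most)]]
  least_idx <- ii[ord[-seq_len(n_most)]]
  mk <- function(keep) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[keep] <- TRUE
    prov <- score_map$raster$provenance
    p <- matrix(NA_integer_, nrow(mask), ncol(mask))
    p[keep] <- prov[keep]
    structure(list(mask = m, provenance = p), class = "raster_drawing")
  }
  structure(list(most = mk(most_idx), least = mk(least_idx),
                 intact = score_map$raster,
                 threshold_rank = n_most,
                 mean_most = mean(score_map$score[most_idx]),
                 mean_least = mean(score_map$score[least_idx])),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf(
    "<split_pair> intact %d px = most %d px (mean %.3f) + least %d px (mean %.3f)\n",
    sum(x$intact$mask), sum(x$most$mask), x$mean_most,
    sum(x$least$mask), x$mean_least))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
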