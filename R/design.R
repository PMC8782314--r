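# Experimental designs: the block design of the decoding experiment, the
# slow event-related design of the model-based experiment, and the
# tent-basis (FIR) design matrix for amplitude-modulated deconvolution.

.CATEGORIES <- c("beach", "city", "forest", "highway", "mountain", "office")

#' The six scene-category labels
#' @return character vector of length 6.
#' @export
scene_categories <- function() .CATEGORIES
.CONDITIONS <- c("intact", "most", "least")
.TR <- 2                      # s, fMRI sampling interval
.TENT_LAGS <- seq(0, 12, 2)   # s, 7 tent apexes from onset to 12 s

#' Build the block design of the decoding experiment
#'
#' Each run holds 18 blocks, one per scene category x image condition. A
#' block shows 8 images, each for 800 ms with a 200 ms gap (1 s per trial,
#' 8 s per block). A 10 s fixation precedes the first block and follows
#' every block, so a run lasts 10 + 18 x (8 + 10) = 334 s = 167 volumes at
#' TR = 2 s; 9 runs give 1503 volumes.
#'
#' @param n_runs number of runs (default 9).
#' @param seed integer; block order within each run is a seeded shuffle.
#' @return An object of class `block_design`: list with `blocks`
#'   (data.frame run, block, category, condition, onset, offset in s),
#'   `trials` (data.frame with per-image onsets), `TR`, `volumes_per_run`,
#'   `n_volumes`, `run_duration`.
#' @export
build_block_design <- function(n_runs = 9L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  combos <- expand.grid(category = .CATEGORIES, condition = .CONDITIONS,
                        stringsAsFactors = FALSE)
  n_blocks <- nrow(combos)          # 18
  block_dur <- 8; fix_dur <- 10; trial_dur <- 1
  run_duration <- fix_dur + n_blocks * (block_dur + fix_dur)
  stopifnot(run_duration %% .TR == 0)
  blocks <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    ord <- sample.int(n_blocks)
    onset <- fix_dur + (seq_len(n_blocks) - 1L) * (block_dur + fix_dur)
    data.frame(run = r, block = seq_len(n_blocks),
               category = combos$category[ord],
               condition = combos$condition[ord],
               onset = onset, offset = onset + block_dur)
  }))
  trials <- blocks[rep(seq_len(nrow(blocks)), each = 8L), ]
  trials$trial <- rep(1:8, times = nrow(blocks))
  trials$onset <- trials$onset + (trials$trial - 1L) * trial_dur
  trials$duration <- 0.8
  trials$offset <- NULL
  rownames(blocks) <- rownames(trials) <- NULL
  structure(list(blocks = blocks, trials = trials, TR = .TR,
                 run_duration = run_duration,
                 volumes_per_run = run_duration / .TR,
                 n_runs = n_runs,
                 n_volumes = n_runs * run_duration / .TR),
            class = "block_design")
}

#' Build a slow event-related design
#'
#' One image per trial: 1 s presentation followed by 9 s fixation (10 s
#' onset spacing). The presentation order is a seeded shuffle of the image
#' table; per-image parametric values travel with the design.
#'
#' @param images data.frame with column `image_id` and one column per
#'   parametric value (e.g. `parallelism`, `luminance`, `contrast`).
#' @param seed integer shuffle seed.
#' @param lead_in s of fixation before the first onset (default 0).
#' @param tail s appended after the last trial so the final 12 s
#'   deconvolution window is covered (default 2, making the run a whole
#'   number of volumes).
#' @return An object of class `event_design`: list with `events`
#'   (data.frame image_id, onset, parametric columns), `TR`, `n_volumes`,
#'   `duration`.
#' @export
build_event_design <- function(images, seed = 1L, lead_in = 0, tail = 2) {
  stopifnot(is.data.frame(images), nrow(images) >= 1L,
            "image_id" %in% names(images))
  pcols <- setdiff(names(images), "image_id")
  for (p in pcols)
    if (!all(is.finite(images[[p]])))
      stop("build_event_design: non-finite parametric value in column ", p)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ev <- images[sample.int(nrow(images)), , drop = FALSE]
  rownames(ev) <- NULL
  ev$onset <- lead_in + (seq_len(nrow(ev)) - 1L) * 10
  duration <- lead_in + nrow(ev) * 10 + tail
  n_volumes <- ceiling(duration / .TR)
  structure(list(events = ev, TR = .TR, n_volumes = n_volumes,
                 duration = duration, parametric = pcols),
            class = "event_design")
}

# tent basis function k (apex at 2k s, half-width 2 s) evaluated at lag tau
tent_basis <- function(tau, k) pmax(0, 1 - abs(tau - .TENT_LAGS[k + 1L]) / .TR)

#' Build a tent-basis (FIR) design matrix for amplitude-modulated deconvolution
#'
#' For each parametric regressor and each of the 7 tents (apexes at 0, 2,
#' ..., 12 s), the column value at volume time `t` is the sum over events of
#' `amplitude x tent_k(t - onset)`. Parametric amplitudes are mean-centered
#' per regressor when `center` is on (default), and an unmodulated event
#' regressor (amplitude 1, not centered) plus per-run polynomial drift
#' columns are appended, so the parametric columns capture amplitude
#' modulation beyond mere stimulus occurrence.
#'
#' @param design an `event_design`.
#' @param regressors character; which parametric columns to model (default
#'   all of them).
#' @param center logical; mean-center parametric amplitudes (default TRUE).
#' @param drift_order polynomial drift order per run (default 2).
#' @return An object of class `design_matrix`: list with `X` (volumes x
#'   regressors), `groups` (named list of column indices: one entry per
#'   parametric regressor, `"event"`, `"drift"`), `lags` (the 7 tent apexes
#'   in s), `TR`.
#' @export
build_tent_design_matrix <- function(design, regressors = NULL,
                                     center = TRUE, drift_order = 2L) {
  stopifnot(inherits(design, "event_design"))
  if (is.null(regressors)) regressors <- design$parametric
  stopifnot(all(regressors %in% names(design$events)))
  ev <- design$events
  nv <- design$n_volumes
  tvol <- (seq_len(nv) - 1L) * design$TR
  n_tent <- length(.TENT_LAGS)
  tent_cols_for <- function(a) {
    if (!all(is.finite(a))) stop("build_tent_design_matrix: non-finite amplitude")
    M <- matrix(0, nv, n_tent)
    for (e in seq_len(nrow(ev))) {
      tau <- tvol - ev$onset[e]
      live <- tau >= 0 & tau <= 12   # causal: no response before onset
      if (!any(live)) next
      for (k in 0:(n_tent - 1L))
        M[live, k + 1L] <- M[live, k + 1L] + a[e] * tent_basis(tau[live], k)
    }
    M
  }
  cols <- list(); groups <- list(); nm <- character(0)
  for (r in regressors) {
    a <- ev[[r]]
    if (center) a <- a - mean(a)
    M <- tent_cols_for(a)
    groups[[r]] <- length(nm) + seq_len(n_tent)
    nm <- c(nm, paste0(r, "_lag", .TENT_LAGS))
    cols[[r]] <- M
  }
  Me <- tent_cols_for(rep(1, nrow(ev)))
  groups[["event"]] <- length(nm) + seq_len(n_tent)
  nm <- c(nm, paste0("event_lag", .TENT_LAGS))
  cols[["event"]] <- Me
  # drift: orthogonal polynomials of volume time, order 0..drift_order
  tt <- scale(tvol)[, 1]
  D <- matrix(1, nv, 1)
  if (drift_order >= 1L) D <- cbind(D, stats::poly(tt, drift_order))
  groups[["drift"]] <- length(nm) + seq_len(ncol(D))
  nm <- c(nm, paste0("drift", 0:(ncol(D) - 1L)))
  cols[["drift"]] <- D
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  structure(list(X = X, groups = groups, lags = .TENT_LAGS, TR = design$TR),
            class = "design_matrix")
}
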