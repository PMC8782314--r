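# Synthetic BOLD data with known ground truth.
#
# Voxels are abstract rows tagged with ROI labels; signals are expressed in
# percent of a common baseline (baseline 100 raw units, so 1 signal unit =
# 1% signal change). Noise is white Gaussian passed through an AR(1)
# filter, the minimal model of BOLD autocorrelation.

#' Ground truth for one simulated ROI
#'
#' @param hrf_shape gamma shape parameter k (> 1); the HRF mode (peak
#'   latency) is `(k - 1) * hrf_scale` seconds.
#' @param hrf_scale gamma scale parameter theta in seconds.
#' @param amp peak response amplitude (percent signal change per unit
#'   stimulus drive).
#' @param pattern_amp s.d. of the category pattern entries (block designs).
#' @param separability named multipliers of the category pattern per
#'   condition; 0 removes all category information from a condition.
#' @param cond_amp named per-condition univariate amplitudes added to every
#'   voxel.
#' @param beta_par,beta_sd mean and voxel scatter of the parallelism
#'   coupling (event designs).
#' @param beta_lum,beta_con luminance / contrast couplings (event designs).
#' @param unmod_amp amplitude of the unmodulated per-event response.
#' @return list of class `roi_truth`.
#' @export
roi_truth <- function(hrf_shape = 3, hrf_scale = 2.5, amp = 1,
                      pattern_amp = 1,
                      separability = c(intact = 1, most = 1, least = 1),
                      cond_amp = c(intact = 0.6, most = 0.8, least = 1),
                      beta_par = 1, beta_sd = 0.2,
                      beta_lum = 0.3, beta_con = 0.3, unmod_amp = 1) {
  stopifnot(hrf_shape > 1, hrf_scale > 0)
  structure(list(hrf_shape = hrf_shape, hrf_scale = hrf_scale, amp = amp,
                 pattern_amp = pattern_amp, separability = separability,
                 cond_amp = cond_amp, beta_par = beta_par, beta_sd = beta_sd,
                 beta_lum = beta_lum, beta_con = beta_con,
                 unmod_amp = unmod_amp),
            class = "roi_truth")
}

#' Ground truth for a simulated BOLD dataset
#'
#' @param rois named list of [roi_truth()] objects.
#' @param sigma marginal s.d. of the AR(1) noise, percent signal units
#'   (0 gives noise-free data for parameter-recovery checks).
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param baseline raw baseline level (percent conversion reference).
#' @param drift_amp s.d. of the random per-run quadratic drift.
#' @param motion_amp coupling of the 6 motion series into the data.
#' @return list of class `bold_truth`.
#' @export
bold_truth <- function(rois, sigma = 1, phi = 0.3, baseline = 100,
                       drift_amp = 0.5, motion_amp = 0.2) {
  stopifnot(is.list(rois), length(names(rois)) == length(rois),
            sigma >= 0, abs(phi) < 1)
  structure(list(rois = rois, sigma = sigma, phi = phi, baseline = baseline,
                 drift_amp = drift_amp, motion_amp = motion_amp),
            class = "bold_truth")
}

#' Gamma hemodynamic response function
#'
#' `h(t) = A * t^(k-1) * exp(-t / theta)` for `t > 0`, scaled so the peak
#' (at the mode `(k-1)*theta`) equals `amp`.
#'
#' @param t time in seconds (vector).
#' @param shape gamma shape k (> 1).
#' @param scale gamma scale theta (s).
#' @param amp peak amplitude.
#' @return numeric vector, 0 for `t <= 0`.
#' @export
hrf_gamma <- function(t, shape = 3, scale = 2.5, amp = 1) {
  mode <- (shape - 1) * scale
  peak <- mode^(shape - 1) * exp(-mode / scale)
  h <- ifelse(t > 0, t^(shape - 1) * exp(-t / scale), 0)
  amp * h / peak
}

# AR(1) noise with marginal s.d. sigma
ar1_noise <- function(n, sigma, phi) {
  e <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# smooth pseudo motion parameters: volumes x 6 random walks
make_motion <- function(n_volumes) {
  m <- sapply(1:6, function(j) cumsum(rnorm(n_volumes, 0, 0.02)))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate block-design BOLD data
#'
#' Voxel time series = baseline + condition-scaled category patterns
#' convolved with the ROI's gamma HRF + per-run quadratic drift + motion
#' coupling + AR(1) noise. Each block contributes the sum of the HRF
#' responses of its 8 one-second trials. Ground truth (category patterns,
#' HRFs) is returned alongside the data.
#'
#' @param design a `block_design`.
#' @param truth a [bold_truth()].
#' @param n_voxels named integer vector, voxels per ROI (names must match
#'   `truth$rois`).
#' @param seed integer seed; the dataset is bit-identical under a fixed
#'   seed.
#' @return An object of class `roi_dataset`: list with `data` (voxels x
#'   volumes), `roi` (per-voxel label), `run` (per-volume run id),
#'   `design`, `motion`, `truth`, `patterns` (the injected category
#'   patterns per ROI).
#' @export
simulate_block_bold <- function(design, truth, n_voxels, seed = 1L) {
  stopifnot(inherits(design, "block_design"), inherits(truth, "bold_truth"),
            all(names(n_voxels) %in% names(truth$rois)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  nv <- design$n_volumes; vpr <- design$volumes_per_run
  run <- rep(seq_len(design$n_runs), each = vpr)
  tvol <- rep((seq_len(vpr) - 1L) * design$TR, design$n_runs)
  V <- sum(n_voxels)
  roi <- rep(names(n_voxels), n_voxels)
  data <- matrix(0, V, nv)
  motion <- make_motion(nv)
  patterns <- list()
  # per-ROI block response regressors (volumes x blocks of one run reused
  # per run since block onsets repeat within runs)
  cat_idx <- match(design$blocks$category, .CATEGORIES)
  v0 <- 0L
  for (rn in names(n_voxels)) {
    rt <- truth$rois[[rn]]
    nvx <- n_voxels[[rn]]
    P <- matrix(rnorm(nvx * 6, 0, rt$pattern_amp), nvx, 6,
                dimnames = list(NULL, .CATEGORIES))
    patterns[[rn]] <- P
    sig <- matrix(0, nvx, nv)
    for (b in seq_len(nrow(design$blocks))) {
      rr <- design$blocks$run[b]
      vols <- which(run == rr)
      tt <- tvol[vols]
      resp <- rowSums(sapply(0:7, function(tr)
        hrf_gamma(tt - design$blocks$onset[b] - tr,
                  rt$hrf_shape, rt$hrf_scale, rt$amp))) / 8
      cond <- design$blocks$condition[b]
      drive <- rt$separability[[cond]] * P[, cat_idx[b]] + rt$cond_amp[[cond]]
      sig[, vols] <- sig[, vols] + drive %o% resp
    }
    data[v0 + seq_len(nvx), ] <- sig
    v0 <- v0 + nvx
  }
  # drift, motion coupling, noise (all in percent units), then baseline
  for (v in seq_len(V)) {
    dr <- numeric(nv)
    for (rr in seq_len(design$n_runs)) {
      vols <- which(run == rr)
      x <- seq(-1, 1, length.out = length(vols))
      cf <- rnorm(3, 0, truth$drift_amp)
      dr[vols] <- cf[1] + cf[2] * x + cf[3] * x^2
    }
    mw <- rnorm(6, 0, truth$motion_amp)
    data[v, ] <- truth$baseline +
      data[v, ] + dr + as.numeric(motion %*% mw) +
      ar1_noise(nv, truth$sigma, truth$phi)
  }
  structure(list(data = data, roi = roi, run = run, design = design,
                 motion = motion, truth = truth, patterns = patterns,
                 type = "block"),
            class = "roi_dataset")
}

#' Simulate event-related BOLD data with parametric parallelism modulation
#'
#' Voxel response = sum over events of (centered parallelism x voxel beta +
#' luminance/contrast couplings + unmodulated amplitude) x the ROI's HRF
#' lag profile, plus drift and AR(1) noise. The HRF enters as the
#' piecewise-linear (tent) interpolation of the gamma HRF sampled at lags
#' 0, 2, ..., 12 s and zero outside, so the tent deconvolution model is
#' exactly identified and noise-free recovery is exact; parametric values
#' are mean-centered in the generator exactly as in the analysis design
#' matrix.
#'
#' @param design an `event_design` with `parallelism`, `luminance`,
#'   `contrast` columns.
#' @param truth a [bold_truth()].
#' @param n_voxels named integer vector, voxels per ROI.
#' @param seed integer seed.
#' @return An object of class `roi_dataset` with per-voxel injected betas
#'   in `voxel_beta` and the per-ROI HRF lag profiles in `hrf_lags`.
#' @export
simulate_event_bold <- function(design, truth, n_voxels, seed = 1L) {
  stopifnot(inherits(design, "event_design"), inherits(truth, "bold_truth"),
            all(names(n_voxels) %in% names(truth$rois)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ev <- design$events
  nv <- design$n_volumes
  tvol <- (seq_len(nv) - 1L) * design$TR
  V <- sum(n_voxels)
  roi <- rep(names(n_voxels), n_voxels)
  data <- matrix(0, V, nv)
  cpar <- ev$parallelism - mean(ev$parallelism)
  clum <- ev$luminance - mean(ev$luminance)
  ccon <- ev$contrast - mean(ev$contrast)
  hrf_lags <- list()
  voxel_beta <- numeric(V)
  v0 <- 0L
  for (rn in names(n_voxels)) {
    rt <- truth$rois[[rn]]
    nvx <- n_voxels[[rn]]
    h <- hrf_gamma(.TENT_LAGS, rt$hrf_shape, rt$hrf_scale, rt$amp)
    hrf_lags[[rn]] <- h
    # tent-interpolated HRF profile of each event, volumes x events drive
    L <- matrix(0, nv, nrow(ev))
    for (e in seq_len(nrow(ev))) {
      tau <- tvol - ev$onset[e]
      live <- tau >= 0 & tau <= 12
      if (!any(live)) next
      L[live, e] <- stats::approx(.TENT_LAGS, h, xout = tau[live])$y
    }
    bet <- rt$beta_par + rnorm(nvx, 0, rt$beta_sd)
    voxel_beta[v0 + seq_len(nvx)] <- bet
    drive_common <- rt$beta_lum * clum + rt$beta_con * ccon + rt$unmod_amp
    base_resp <- as.numeric(L %*% drive_common)
    par_resp <- as.numeric(L %*% cpar)
    data[v0 + seq_len(nvx), ] <-
      rep(1, nvx) %o% base_resp + bet %o% par_resp
    v0 <- v0 + nvx
  }
  motion <- make_motion(nv)
  for (v in seq_len(V)) {
    x <- seq(-1, 1, length.out = nv)
    cf <- rnorm(3, 0, truth$drift_amp)
    data[v, ] <- truth$baseline + data[v, ] +
      cf[1] + cf[2] * x + cf[3] * x^2 +
      ar1_noise(nv, truth$sigma, truth$phi)
  }
  structure(list(data = data, roi = roi, run = rep(1L, nv), design = design,
                 motion = motion, truth = truth, voxel_beta = voxel_beta,
                 hrf_lags = hrf_lags, type = "event"),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %s design: %d voxel(s) x %d volume(s), ROIs: %s\n",
              x$type, nrow(x$data), ncol(x$data),
              paste(unique(x$roi), collapse = ", ")))
  invisible(x)
}
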