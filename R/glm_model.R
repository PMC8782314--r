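# Model-based analysis of event-related data: tent-basis deconvolution of
# the parallelism-modulated BOLD response, ROI beta time courses with
# polynomial/AUC summaries, gamma-mode peak-latency estimation, and the two
# voxel-subsampling ("bootstrap") latency-comparison schemes.

#' Tent-basis deconvolution (OLS per voxel)
#'
#' Ordinary least squares of every voxel time course on the tent design
#' matrix; the seven lag betas of each parametric regressor are extracted
#' together with their standard errors.
#'
#' @param dataset a `roi_dataset` (event design) or a voxels x volumes
#'   matrix.
#' @param dm a `design_matrix` from [build_tent_design_matrix()].
#' @return An object of class `beta_timecourse`: list with `betas`
#'   (regressors x voxels, all columns), `se` (same shape), `groups`,
#'   `lags`, `sigma2` (per-voxel residual variance), `dof`, `xtx_inv`,
#'   `roi` (per-voxel labels if the input carried them).
#' @export
deconvolve_tent <- function(dataset, dm) {
  stopifnot(inherits(dm, "design_matrix"))
  Y <- if (inherits(dataset, "roi_dataset")) dataset$data else dataset
  roi <- if (inherits(dataset, "roi_dataset")) dataset$roi else NULL
  stopifnot(is.matrix(Y), ncol(Y) == nrow(dm$X))
  X <- dm$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("deconvolve_tent: design matrix is rank deficient; collinear ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, t(Y))                       # p x V
  res <- t(Y) - X %*% B
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  rownames(B) <- rownames(se) <- colnames(X)
  structure(list(betas = B, se = se, groups = dm$groups, lags = dm$lags,
                 sigma2 = sigma2, dof = dof, xtx_inv = xtx_inv, roi = roi),
            class = "beta_timecourse")
}

#' Extract the lag-beta course of one regressor
#'
#' @param bt a `beta_timecourse`.
#' @param regressor regressor name (default `"parallelism"`).
#' @return lags x voxels matrix of betas.
#' @export
beta_course <- function(bt, regressor = "parallelism") {
  stopifnot(inherits(bt, "beta_timecourse"),
            regressor %in% names(bt$groups))
  bt$betas[bt$groups[[regressor]], , drop = FALSE]
}

#' ROI beta time course: mean, 4th-degree polynomial, AUC 2-10 s
#'
#' The unweighted voxel mean of the lag betas, a least-squares 4th-degree
#' polynomial fit over the lags, and the area under that polynomial
#' integrated analytically on [2, 10] s.
#'
#' @param bt a `beta_timecourse`.
#' @param voxels logical/integer voxel selector (e.g. `bt$roi == "V4"`).
#' @param regressor regressor name.
#' @param auc_window integration window in s (default `c(2, 10)`).
#' @return list with `course` (mean betas per lag), `poly_coef`
#'   (coefficients, constant first), `auc`.
#' @export
roi_timecourse_summary <- function(bt, voxels, regressor = "parallelism",
                                   auc_window = c(2, 10)) {
  cb <- beta_course(bt, regressor)[, voxels, drop = FALSE]
  if (ncol(cb) == 0L) stop("roi_timecourse_summary: empty ROI")
  course <- rowMeans(cb)
  lags <- bt$lags
  cf <- coef(lm(course ~ stats::poly(lags, 4, raw = TRUE)))
  cf <- unname(cf)
  a <- auc_window[1]; b <- auc_window[2]
  auc <- sum(cf * (b^(1:5) - a^(1:5)) / (1:5))
  list(course = course, poly_coef = cf, auc = auc)
}

# gamma model evaluated at t for parameters k (shape), theta (scale);
# amplitude is profiled out analytically (the model is linear in A)
.gamma_shape_fn <- function(t, k, theta) ifelse(t > 0, t^(k - 1) * exp(-t / theta), 0)

#' Fit a gamma function to a beta time course and return its mode
#'
#' Nonlinear least squares of `A * t^(k-1) * exp(-t/theta)` to the (lag,
#' beta) pairs; the amplitude `A` is profiled out analytically and (k,
#' theta) are optimized from multiple starts with box constraints `k` in
#' (1, 20], `theta` in (0.1, 10]. The peak latency is the gamma mode
#' `(k - 1) * theta`. Fits are flagged invalid when the course is all zero,
#' when no start converges, or when the mode leaves [0, 12] s.
#'
#' @param course numeric vector of betas (>= 4 finite values).
#' @param lags lag times in s (default 0, 2, ..., 12).
#' @param starts optional matrix of (k, theta) starting points; default a
#'   fixed 4 x 4 grid.
#' @return An object of class `gamma_fit`: list with `shape`, `scale`,
#'   `amplitude`, `mode`, `ss`, `valid`.
#' @export
fit_gamma_mode <- function(course, lags = seq(0, 12, 2), starts = NULL) {
  stopifnot(length(course) == length(lags))
  if (sum(is.finite(course)) < 4L)
    stop("fit_gamma_mode: need >= 4 finite points")
  invalid <- list(shape = NA_real_, scale = NA_real_, amplitude = NA_real_,
                  mode = NA_real_, ss = NA_real_, valid = FALSE)
  if (all(abs(course) < 1e-14))
    return(structure(invalid, class = "gamma_fit"))
  if (is.null(starts))
    starts <- as.matrix(expand.grid(k = c(1.5, 2, 4, 8),
                                    theta = c(0.5, 1, 2, 4)))
  obj <- function(p) {
    g <- .gamma_shape_fn(lags, p[1], p[2])
    gg <- sum(g * g)
    if (gg < 1e-300 || !is.finite(gg)) return(sum(course^2))
    A <- sum(course * g) / gg
    sum((course - A * g)^2)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = c(1 + 1e-6, 0.1 + 1e-9), upper = c(20, 10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(structure(invalid, class = "gamma_fit"))
  k <- best$par[1]; theta <- best$par[2]
  g <- .gamma_shape_fn(lags, k, theta)
  A <- sum(course * g) / sum(g * g)
  mode <- (k - 1) * theta
  structure(list(shape = unname(k), scale = unname(theta),
                 amplitude = unname(A), mode = unname(mode),
                 ss = best$value,
                 valid = is.finite(mode) && mode >= 0 && mode <= 12),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<gamma_fit> k=%.3f theta=%.3f A=%.3g mode=%.2f s (SS %.3g)\n",
                x$shape, x$scale, x$amplitude, x$mode, x$ss))
  else cat("<gamma_fit> invalid\n")
  invisible(x)
}

#' Voxel-subsampling latency comparison between ROIs
#'
#' Repeated subsampling (without replacement) of voxels within each ROI:
#' per replicate the sampled voxels' beta courses are averaged, a gamma is
#' fitted, and for each ROI pair the ordering of the fitted modes is
#' recorded. Two schemes: `"proportion"` samples a fixed fraction of each
#' ROI (default 50%); `"fixed"` samples the same absolute voxel count from
#' every ROI (half the size of the smallest ROI unless given). Replicates
#' with an invalid fit in a participating ROI are skipped and counted.
#'
#' @param voxel_betas lags x voxels matrix (e.g. `beta_course(bt)`).
#' @param roi per-voxel ROI labels.
#' @param pairs list of 2-vectors `c(roi_a, roi_b)`; the reported
#'   proportion is of replicates where `roi_a` peaks earlier than `roi_b`.
#' @param scheme `"proportion"` or `"fixed"`.
#' @param n_samples number of replicates.
#' @param seed integer seed.
#' @param frac sampled fraction in the proportion scheme (default 0.5).
#' @param fixed_n voxel count in the fixed scheme (default
#'   `fixed_count_sample_size()` of the participating ROI sizes).
#' @param lags lag times.
#' @param starts optional gamma starting points (warm starts from the
#'   full-ROI fits are always added).
#' @return An object of class `bootstrap_result`: data.frame with pair,
#'   proportion_earlier, n_valid, n_samples, scheme; attributes carry the
#'   per-ROI full-data modes.
#' @export
bootstrap_latency <- function(voxel_betas, roi, pairs,
                              scheme = c("proportion", "fixed"),
                              n_samples = 1000L, seed = 1L, frac = 0.5,
                              fixed_n = NULL, lags = seq(0, 12, 2),
                              starts = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(voxel_betas), ncol(voxel_betas) == length(roi))
  rois <- unique(unlist(pairs))
  sizes <- vapply(rois, function(r) sum(roi == r), integer(1))
  if (any(sizes == 0L)) stop("bootstrap_latency: empty ROI among pairs")
  n_take <- if (scheme == "proportion") {
    pmax(1L, round(frac * sizes))
  } else {
    if (is.null(fixed_n)) fixed_n <- fixed_count_sample_size(sizes)
    if (any(fixed_n > sizes))
      stop("bootstrap_latency: sample size ", fixed_n,
           " exceeds ROI size ", min(sizes))
    stats::setNames(rep(as.integer(fixed_n), length(rois)), rois)
  }
  names(n_take) <- rois
  # warm starts from the full-ROI fits
  full_modes <- numeric(0)
  warm <- matrix(numeric(0), ncol = 2)
  for (r in rois) {
    f <- fit_gamma_mode(rowMeans(voxel_betas[, roi == r, drop = FALSE]),
                        lags = lags)
    full_modes[r] <- f$mode
    if (f$valid) warm <- rbind(warm, c(f$shape, f$scale))
  }
  if (is.null(starts))
    starts <- as.matrix(expand.grid(k = c(2, 4), theta = c(1, 2.5)))
  starts <- rbind(starts, warm)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx_by_roi <- lapply(rois, function(r) which(roi == r))
  names(idx_by_roi) <- rois
  modes <- matrix(NA_real_, n_samples, length(rois),
                  dimnames = list(NULL, rois))
  for (s in seq_len(n_samples)) {
    for (r in rois) {
      take <- sample(idx_by_roi[[r]], n_take[[r]])
      f <- fit_gamma_mode(rowMeans(voxel_betas[, take, drop = FALSE]),
                          lags = lags, starts = starts)
      if (f$valid) modes[s, r] <- f$mode
    }
  }
  out <- do.call(rbind, lapply(pairs, function(p) {
    ok <- is.finite(modes[, p[1]]) & is.finite(modes[, p[2]])
    data.frame(pair = paste(p[1], "before", p[2]),
               proportion_earlier = mean(modes[ok, p[1]] < modes[ok, p[2]]),
               n_valid = sum(ok), n_samples = n_samples, scheme = scheme)
  }))
  attr(out, "full_modes") <- full_modes
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

#' Fixed-count subsample size from an ROI size table
#'
#' Half the size of the smallest ROI, rounded down: the rule that gives 828
#' voxels for the published ROI size table (smallest ROI V4, 1656 voxels).
#'
#' @param roi_sizes named integer vector of ROI sizes.
#' @return integer sample size.
#' @export
fixed_count_sample_size <- function(roi_sizes) {
  stopifnot(length(roi_sizes) >= 1L, all(roi_sizes >= 1))
  as.integer(floor(min(roi_sizes) / 2))
}

#' Published average ROI sizes of the event-related dataset
#'
#' Average voxel counts per ROI as printed for the public four-participant
#' event-related dataset used in the model-based analysis. `Other` (all
#' remaining voxels, the baseline "ROI") is excluded unless requested.
#'
#' @param include_other include the baseline `Other` region.
#' @return named integer vector.
#' @export
bold5000_roi_sizes <- function(include_other = FALSE) {
  s <- c(V1 = 3968L, V2 = 4889L, V3 = 4534L, V4 = 1656L, LO = 16031L,
         pFs = 8659L, PPA = 6652L, OPA = 5492L, RSC = 5291L, FFA = 5319L)
  if (include_other) s <- c(s, Other = 134220L)
  s
}

#' Per-voxel parallelism significance map
#'
#' Joint F-test of the seven parallelism-lag betas against zero for every
#' voxel, with a signed effect (the sum of the lag betas) and a
#' significance flag at the configured uncorrected alpha.
#'
#' @param bt a `beta_timecourse`.
#' @param regressor regressor name.
#' @param alpha significance level (default 0.001, uncorrected).
#' @return data.frame voxel, F, p, effect (sum of betas), significant.
#' @export
parallelism_voxel_map <- function(bt, regressor = "parallelism",
                                  alpha = 0.001) {
  stopifnot(inherits(bt, "beta_timecourse"))
  ii <- bt$groups[[regressor]]
  q <- length(ii)
  B <- bt$betas[ii, , drop = FALSE]
  Vsub <- bt$xtx_inv[ii, ii]
  Vinv <- solve(Vsub)
  quad <- colSums((Vinv %*% B) * B)
  Fv <- quad / (q * bt$sigma2)
  p <- pf(Fv, q, bt$dof, lower.tail = FALSE)
  data.frame(voxel = seq_len(ncol(B)), F = Fv, p = p,
             effect = colSums(B), significant = p < alpha)
}
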