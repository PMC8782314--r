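event_fixture <- function(n_img = 80, sigma = 0, seed = 3, n_vox = c(A = 6L),
                          rois = list(A = roi_truth(hrf_shape = 3,
                                                    hrf_scale = 2))) {
  imgs <- make_images(n_img, seed = seed)
  ed <- build_event_design(imgs, seed = seed)
  truth <- bold_truth(rois, sigma = sigma, phi = if (sigma > 0) 0.3 else 0,
                      drift_amp = 0.3)
  ds <- simulate_event_bold(ed, truth, n_vox, seed = seed)
  list(ds = ds, dm = build_tent_design_matrix(ed), ed = ed)
}

test_that("tent deconvolution recovers injected lag profiles to 1e-8", {
  fx <- event_fixture()
  bt <- deconvolve_tent(fx$ds, fx$dm)
  bc <- beta_course(bt)
  for (v in seq_len(ncol(bc)))
    expect_lt(max(abs(bc[, v] - fx$ds$voxel_beta[v] * fx$ds$hrf_lags$A)), 1e-8)
  # pure-drift voxel: parallelism betas vanish
  Y <- fx$ds$data
  tt <- seq(-1, 1, length.out = ncol(Y))
  Y[1, ] <- 5 + 3 * tt - 2 * tt^2
  ds2 <- fx$ds; ds2$data <- Y
  bt2 <- deconvolve_tent(ds2, fx$dm)
  expect_lt(max(abs(beta_course(bt2)[, 1])), 1e-8)
  # consistent permutation of volumes leaves betas unchanged
  perm <- sample(ncol(Y))
  dmp <- fx$dm; dmp$X <- fx$dm$X[perm, ]
  btp <- deconvolve_tent(fx$ds$data[, perm, drop = FALSE], dmp)
  expect_equal(btp$betas, deconvolve_tent(fx$ds$data, fx$dm)$betas,
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  fx <- event_fixture(n_img = 30)
  dm <- fx$dm
  dm$X <- cbind(dm$X, dup = dm$X[, 1])
  expect_error(deconvolve_tent(fx$ds, dm), "rank deficient")
})

test_that("ROI summary: polynomial exactness and analytic AUC", {
  fx <- event_fixture()
  bt <- deconvolve_tent(fx$ds, fx$dm)
  # overwrite with an exactly quadratic course via a synthetic bt object
  lags <- bt$lags
  quad <- 2 + 0.5 * lags - 0.1 * lags^2
  bt$betas[bt$groups$parallelism, ] <- matrix(quad, 7, ncol(bt$betas))
  rs <- roi_timecourse_summary(bt, rep(TRUE, ncol(bt$betas)))
  expect_equal(rs$course, quad, ignore_attr = TRUE)
  expect_equal(rs$poly_coef[1:3], c(2, 0.5, -0.1), tolerance = 1e-8)
  closed <- function(t) 2 * t + 0.25 * t^2 - 0.1 * t^3 / 3
  expect_equal(rs$auc, closed(10) - closed(2), tolerance = 1e-8)
  # constant course c -> AUC = 8c
  bt$betas[bt$groups$parallelism, ] <- 0.7
  expect_equal(roi_timecourse_summary(bt, rep(TRUE, ncol(bt$betas)))$auc,
               8 * 0.7, tolerance = 1e-8)
  # random course: analytic AUC equals numeric quadrature of the fit
  set.seed(9)
  rnd <- rnorm(7)
  bt$betas[bt$groups$parallelism, ] <- matrix(rnd, 7, ncol(bt$betas))
  rs3 <- roi_timecourse_summary(bt, rep(TRUE, ncol(bt$betas)))
  poly_fn <- function(t) sapply(t, function(ti) sum(rs3$poly_coef * ti^(0:4)))
  expect_equal(rs3$auc, integrate(poly_fn, 2, 10, abs.tol = 1e-12)$value,
               tolerance = 1e-10)
})

test_that("gamma fits recover modes, ignore scale, order correctly", {
  lags <- seq(0, 12, 2)
  course4 <- hrf_gamma(lags, shape = 3, scale = 2)    # mode 4 s
  f <- fit_gamma_mode(course4)
  expect_true(f$valid)
  expect_equal(f$mode, 4, tolerance = 0.05)
  f10 <- fit_gamma_mode(10 * course4)
  expect_equal(f10$mode, f$mode, tolerance = 1e-4)
  course6 <- hrf_gamma(lags, shape = 4, scale = 2)    # mode 6 s
  expect_lt(f$mode, fit_gamma_mode(course6)$mode)
  # all-zero course -> invalid, not an error
  fz <- fit_gamma_mode(rep(0, 7))
  expect_false(fz$valid)
  expect_error(fit_gamma_mode(c(1, 2, NA, NA, NA, NA, NA)), "finite")
})

test_that("bootstrap latency orders ROIs by injected HRF mode", {
  fx <- event_fixture(sigma = 1, n_vox = c(A = 40L, B = 40L),
                      rois = list(A = roi_truth(hrf_shape = 3, hrf_scale = 2),
                                  B = roi_truth(hrf_shape = 4, hrf_scale = 2)))
  bt <- deconvolve_tent(fx$ds, fx$dm)
  bc <- beta_course(bt)
  br <- bootstrap_latency(bc, fx$ds$roi, pairs = list(c("A", "B")),
                          scheme = "proportion", n_samples = 200, seed = 4)
  expect_gt(br$proportion_earlier, 0.95)
  # determinism
  br2 <- bootstrap_latency(bc, fx$ds$roi, pairs = list(c("A", "B")),
                           scheme = "proportion", n_samples = 200, seed = 4)
  expect_identical(br$proportion_earlier, br2$proportion_earlier)
  # voxel relabeling within ROI leaves proportions unchanged
  perm <- seq_along(fx$ds$roi)
  ia <- which(fx$ds$roi == "A"); perm[ia] <- ia[sample(length(ia))]
  br3 <- bootstrap_latency(bc[, perm], fx$ds$roi[perm],
                           pairs = list(c("A", "B")),
                           scheme = "proportion", n_samples = 200, seed = 4)
  expect_equal(br$proportion_earlier, br3$proportion_earlier, tolerance = 0.05)
  # fixed scheme: error when the requested count exceeds the ROI
  expect_error(bootstrap_latency(bc, fx$ds$roi, pairs = list(c("A", "B")),
                                 scheme = "fixed", fixed_n = 400,
                                 n_samples = 10, seed = 1),
               "exceeds ROI size")
})

test_that("exchangeable ROIs show no systematic ordering", {
  # Within one dataset the subsample modes concentrate around that
  # dataset's chance asymmetry, so the 0.5 expectation only holds across
  # datasets: check (a) the two orderings are complementary, and (b) no
  # systematic direction across independent datasets.
  same <- list(A = roi_truth(hrf_shape = 3, hrf_scale = 2),
               B = roi_truth(hrf_shape = 3, hrf_scale = 2))
  fx <- event_fixture(sigma = 1.5, n_vox = c(A = 30L, B = 30L), rois = same)
  bt <- deconvolve_tent(fx$ds, fx$dm)
  br <- bootstrap_latency(beta_course(bt), fx$ds$roi,
                          pairs = list(c("A", "B"), c("B", "A")),
                          scheme = "proportion", n_samples = 100, seed = 6)
  expect_lte(br$proportion_earlier[1] + br$proportion_earlier[2], 1)
  expect_gte(br$proportion_earlier[1] + br$proportion_earlier[2], 0.98)
  wins <- vapply(1:10, function(i) {
    fxi <- event_fixture(sigma = 1.5, n_vox = c(A = 12L, B = 12L),
                         rois = same, seed = 100 + i, n_img = 40)
    bti <- deconvolve_tent(fxi$ds, fxi$dm)
    bri <- bootstrap_latency(beta_course(bti), fxi$ds$roi,
                             pairs = list(c("A", "B")),
                             scheme = "proportion", n_samples = 30,
                             seed = i)
    bri$proportion_earlier > 0.5
  }, logical(1))
  expect_gte(sum(wins), 1)   # binomial(10, 0.5) central 99% band
  expect_lte(sum(wins), 9)
})

test_that("fixed-count sample size follows the half-smallest-ROI rule", {
  expect_equal(fixed_count_sample_size(c(A = 10, B = 7)), 3L)
  expect_equal(fixed_count_sample_size(bold5000_roi_sizes()), 828L)
  expect_equal(min(bold5000_roi_sizes()), 1656L)  # V4 the smallest
})

test_that("parallelism voxel map controls false positives and finds signal", {
  fx <- event_fixture(sigma = 1, n_vox = c(A = 50L, B = 50L),
                      rois = list(A = roi_truth(beta_par = 1.5, beta_sd = 0),
                                  B = roi_truth(beta_par = 0, beta_sd = 0)))
  bt <- deconvolve_tent(fx$ds, fx$dm)
  pm <- parallelism_voxel_map(bt, alpha = 0.05)
  null_rate <- mean(pm$significant[fx$ds$roi == "B"])
  expect_lt(null_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
  expect_true(all(pm$significant[fx$ds$roi == "A"]))
  expect_true(all(pm$effect[fx$ds$roi == "A"] > 0))
})
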