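make_block_data <- function(n_runs = 9L, V = 24L, sigma = 1, seed = 1,
                            sep_least = 1) {
  bd <- build_block_design(n_runs = n_runs, seed = seed)
  truth <- bold_truth(list(A = roi_truth(separability = c(intact = 1, most = 1,
                                                          least = sep_least))),
                      sigma = sigma, phi = 0.3)
  ds <- simulate_block_bold(bd, truth, c(A = V), seed = seed)
  block_average(preprocess_dataset(ds))
}

test_that("preprocessing removes nuisance structure exactly", {
  set.seed(10)
  motion <- matrix(rnorm(50 * 6), 50, 6)
  # voxel = affine function of motion column 1 -> residuals identically 0
  run <- rbind(100 + 2 * motion[, 1],
               matrix(100 + rnorm(3 * 50), 3, 50))
  res <- preprocess_run(run, motion)
  expect_lt(max(abs(res[1, ])), 1e-8)
  # residuals orthogonal to all nuisance columns
  X <- cbind(1, motion)
  expect_lt(max(abs(crossprod(X, t(res)))), 1e-6)
  # constant voxel -> zero residuals
  resc <- preprocess_run(matrix(7, 1, 50), motion)
  expect_lt(max(abs(resc)), 1e-10)
  expect_error(preprocess_run(matrix(0, 1, 50), motion), "dead voxel")
  expect_error(preprocess_run(matrix(1, 1, 10), motion[1:10, ]), "20 volumes")
})

test_that("block averaging picks the delay-shifted window", {
  bd <- build_block_design(n_runs = 3L, seed = 1)
  # deterministic data: value = global volume index
  nv <- bd$n_volumes
  ds <- structure(list(data = matrix(seq_len(nv), 1, nv, byrow = TRUE),
                       roi = "A", run = rep(1:3, each = 167),
                       design = bd,
                       motion = matrix(0, nv, 6), type = "block"),
                  class = "roi_dataset")
  bp <- block_average(ds, delay = 4)
  b <- bd$blocks
  # block onset o: volumes (o+4)/2 .. (o+12)/2 - 1 (0-based), 4 volumes
  expected <- tapply(seq_len(nrow(b)), seq_len(nrow(b)), function(i)
    mean((b$run[i] - 1) * 167 + (b$onset[i] + 4) / 2 + 0:3 + 1))
  expect_equal(unname(bp$patterns[, 1]), as.numeric(expected))
  expect_equal(nrow(bp$patterns), 54L)   # 18 x 3 runs
  expect_equal(sum(bp$info$condition == "most"), 18L)
  expect_error(block_average(ds, delay = 3), "divisible")
})

test_that("anova_f matches the textbook oracle", {
  set.seed(5)
  X <- matrix(rnorm(54 * 8), 54, 8)
  g <- rep(letters[1:6], 9)
  f <- anova_f(X, g)
  for (v in 1:8) expect_equal(f[v], anova_f_oracle(X[, v], g), tolerance = 1e-10)
})

test_that("nested voxel selection finds the informative voxel", {
  set.seed(8)
  n <- 54; runs <- rep(1:9, each = 6); labels <- rep(scene_categories(), 9)
  V <- 10
  X <- matrix(rnorm(n * V, 0, 3), n, V)
  X[, 4] <- as.integer(factor(labels)) * 2 + rnorm(n, 0, 0.05)
  sel <- select_voxels_nested(X, labels, runs, grid = c(1 / V, 1))
  expect_equal(sel$proportion, 1 / V)
  expect_true(sel$mask[4])
  expect_equal(sum(sel$mask), 1L)
  # all voxels identical -> every proportion ties -> largest returned
  Xc <- matrix(rep(rnorm(n), V), n, V)
  selc <- select_voxels_nested(Xc, labels, runs, grid = seq(0.5, 1, 0.25))
  expect_equal(selc$proportion, 1)
  expect_error(select_voxels_nested(X[labels == "beach", ],
                                    labels[labels == "beach"],
                                    runs[labels == "beach"]),
               "single category")
})

test_that("perfectly separable patterns decode at 1.0", {
  set.seed(3)
  labels <- rep(scene_categories(), 9)
  runs <- rep(1:9, each = 6)
  proto <- diag(6) * 5
  X <- proto[as.integer(factor(labels)), ] + matrix(rnorm(54 * 6, 0, 0.1), 54, 6)
  r <- decode_loro(X, labels, runs)
  expect_equal(r$accuracy, 1.0)
})

test_that("shuffled labels decode at chance (binomial 99% band)", {
  set.seed(14)
  bp <- make_block_data(sigma = 1, seed = 14)
  sel <- bp$info$condition == "intact"
  labs <- sample(bp$info$category[sel])   # break label-pattern pairing
  r <- decode_loro(bp$patterns[sel, ], labs, bp$info$run[sel])
  n <- sum(sel)
  band <- qbinom(c(0.005, 0.995), n, 1 / 6) / n
  expect_gte(r$accuracy, band[1])
  expect_lte(r$accuracy, band[2])
})

test_that("no information leaks from the left-out run", {
  # canary: permuting the left-out run's labels must not change the
  # predictions for that run (selection + training never see them)
  set.seed(21)
  bp <- make_block_data(n_runs = 5L, V = 12L, sigma = 1, seed = 21)
  sel <- bp$info$condition == "most"
  X <- bp$patterns[sel, ]; labs <- bp$info$category[sel]
  runs <- bp$info$run[sel]
  r1 <- decode_loro(X, labs, runs, grid = c(0.5, 1))
  labs2 <- labs
  labs2[runs == 3] <- sample(labs[runs == 3])
  r2 <- decode_loro(X, labs2, runs, grid = c(0.5, 1))
  expect_identical(r1$folds$prediction[r1$folds$run == 3],
                   r2$folds$prediction[r2$folds$run == 3])
})

test_that("accuracy is invariant to voxel order and affine rescaling", {
  set.seed(31)
  bp <- make_block_data(n_runs = 5L, V = 12L, sigma = 0.8, seed = 31)
  sel <- bp$info$condition == "intact"
  X <- bp$patterns[sel, ]; labs <- bp$info$category[sel]
  runs <- bp$info$run[sel]
  a1 <- decode_loro(X, labs, runs, grid = 1)$accuracy
  perm <- sample(ncol(X))
  a2 <- decode_loro(X[, perm], labs, runs, grid = 1)$accuracy
  a3 <- decode_loro(X * 3.7, labs, runs, grid = 1)$accuracy
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("group stats: paired t and BH-FDR match hand computation", {
  # BH on {0.001, 0.02, 0.03, 0.5} -> {0.004, 0.04, 0.04, 0.5}
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_equal(bh_oracle(p), c(0.004, 0.04, 0.04, 0.5))
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))

  df <- expand.grid(subject = 1:6, roi = c("r1", "r2"),
                    condition = c("most", "least"),
                    stringsAsFactors = FALSE)
  set.seed(2)
  df$accuracy <- 0.5
  df$accuracy[df$roi == "r1" & df$condition == "most"] <-
    0.7 + rnorm(6, 0, 0.01)
  gs <- group_stats(df)
  r1 <- gs[gs$roi == "r1", ]; r2 <- gs[gs$roi == "r2", ]
  # identical accuracies in both conditions -> t = 0, p = 1
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  expect_match(r2$note, "zero-variance")
  tt <- t.test(df$accuracy[df$roi == "r1" & df$condition == "most"],
               rep(0.5, 6), paired = TRUE)
  expect_equal(r1$t, unname(tt$statistic))
  expect_equal(gs$q, p.adjust(gs$p, "BH"))
})

test_that("univariate means reflect injected condition amplitudes", {
  bp <- make_block_data(n_runs = 4L, V = 16L, sigma = 0.3, seed = 41)
  um <- univariate_means(bp)
  m <- setNames(um$mean, um$condition)
  # default cond_amp: intact 0.6 < most 0.8 < least 1 (times HRF gain)
  expect_lt(m["intact"], m["most"])
  expect_lt(m["most"], m["least"])
})
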