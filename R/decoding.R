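# Scene-category decoding from block-design data: percent signal change,
# motion-nuisance regression, block averaging at a fixed hemodynamic delay,
# nested ANOVA-F voxel selection, leave-one-run-out linear SVM, and group
# statistics with Benjamini-Hochberg FDR control.

#' Percent signal change and motion-nuisance regression for one run
#'
#' Each voxel is converted to percent signal change about its run mean,
#' then replaced by the OLS residuals of a regression on an intercept plus
#' the six motion parameters.
#'
#' @param run_data voxels x volumes matrix (one run).
#' @param motion volumes x 6 motion-parameter matrix for the run.
#' @return Residual matrix of the same shape.
#' @export
preprocess_run <- function(run_data, motion) {
  stopifnot(is.matrix(run_data), nrow(motion) == ncol(run_data))
  if (ncol(run_data) <= 20L)
    stop("preprocess_run: run must have more than 20 volumes")
  mu <- rowMeans(run_data)
  if (any(abs(mu) < 1e-12))
    stop("preprocess_run: dead voxel (zero run mean) at index ",
         which(abs(mu) < 1e-12)[1])
  psc <- 100 * sweep(sweep(run_data, 1, mu), 1, mu, "/")
  X <- cbind(1, motion)
  # residual maker applied to all voxels at once
  Q <- qr.Q(qr(X))
  t(t(psc) - Q %*% crossprod(Q, t(psc)))
}

#' Preprocess a whole block dataset run by run
#'
#' @param dataset a `roi_dataset` from [simulate_block_bold()] (or with the
#'   same fields).
#' @return The dataset with `data` replaced by nuisance residuals.
#' @export
preprocess_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "roi_dataset"))
  out <- dataset$data
  for (r in unique(dataset$run)) {
    vols <- which(dataset$run == r)
    out[, vols] <- preprocess_run(dataset$data[, vols, drop = FALSE],
                                  dataset$motion[vols, , drop = FALSE])
  }
  dataset$data <- out
  dataset
}

#' Average residuals over blocks at a hemodynamic delay
#'
#' For each block the volumes whose run-relative time falls in
#' `[onset + delay, offset + delay)` are averaged; a window shifted past
#' the run end is truncated with a warning.
#'
#' @param dataset a preprocessed `roi_dataset` (block design).
#' @param delay hemodynamic delay in s; must be divisible by TR (default 4).
#' @return An object of class `block_patterns`: list with `patterns`
#'   (blocks x voxels matrix) and `info` (data.frame run, category,
#'   condition per block).
#' @export
block_average <- function(dataset, delay = 4) {
  stopifnot(inherits(dataset, "roi_dataset"))
  design <- dataset$design
  TR <- design$TR
  if (delay %% TR != 0) stop("block_average: delay must be divisible by TR")
  vpr <- design$volumes_per_run
  blocks <- design$blocks
  P <- matrix(NA_real_, nrow(blocks), nrow(dataset$data))
  for (b in seq_len(nrow(blocks))) {
    v_lo <- (blocks$onset[b] + delay) / TR          # 0-based within run
    v_hi <- (blocks$offset[b] + delay) / TR         # exclusive
    if (v_hi > vpr) {
      warning("block_average: window truncated at run end (block ", b, ")")
      v_hi <- vpr
    }
    vols <- (blocks$run[b] - 1L) * vpr + seq.int(v_lo + 1L, v_hi)
    P[b, ] <- rowMeans(dataset$data[, vols, drop = FALSE])
  }
  structure(list(patterns = P,
                 info = blocks[, c("run", "category", "condition")],
                 roi = dataset$roi),
            class = "block_patterns")
}

#' One-way ANOVA F statistic per voxel
#'
#' @param patterns n x V matrix of patterns.
#' @param labels length-n grouping factor (category labels).
#' @return Length-V vector of F statistics.
#' @export
anova_f <- function(patterns, labels) {
  labels <- factor(labels)
  k <- nlevels(labels); n <- nrow(patterns)
  stopifnot(k >= 2L, n > k)
  gm <- colMeans(patterns)
  ssb <- 0; ssw <- 0
  for (g in levels(labels)) {
    sel <- labels == g
    m <- colMeans(patterns[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + colSums(sweep(patterns[sel, , drop = FALSE], 2, m)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# linear one-vs-one SVM wrapper (dual coordinate descent in C++)
svm_predict <- function(Xtrain, ytrain, Xtest, C = 1) {
  yt <- as.integer(factor(ytrain, levels = .CATEGORIES))
  pred <- .ovo_svm_cpp(Xtrain, yt, Xtest, C, 100L, 1e-4)
  .CATEGORIES[pred]
}

#' Nested cross-validated voxel selection by ANOVA-F rank
#'
#' For each candidate proportion, voxels are ranked by the category ANOVA F
#' computed on the inner-training folds only and the inner
#' leave-one-run-out accuracy is measured; the proportion with the highest
#' inner accuracy wins (ties go to the larger proportion). The returned
#' mask ranks voxels on the full training set at that proportion.
#'
#' @param patterns training patterns (n x V).
#' @param labels category labels (length n).
#' @param runs run id per pattern; needs >= 2 distinct runs.
#' @param grid candidate proportions (default 0.1 ... 1.0).
#' @param C SVM cost parameter.
#' @return list with `proportion`, `mask` (logical length V), and
#'   `inner_accuracy` (named by proportion).
#' @export
select_voxels_nested <- function(patterns, labels, runs,
                                 grid = seq(0.1, 1, by = 0.1), C = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("select_voxels_nested: training set has a single category")
  ur <- unique(runs)
  if (length(ur) < 2L)
    stop("select_voxels_nested: need >= 2 runs in the training set")
  V <- ncol(patterns)
  n_keep <- pmax(1L, round(grid * V))
  yi <- as.integer(factor(labels, levels = .CATEGORIES))
  cv <- .inner_cv_cpp(patterns, yi, as.integer(runs), as.integer(n_keep),
                      C, 100L, 1e-4)
  acc <- cv$hits / cv$total
  best <- max(which(acc == max(acc)))   # ties -> larger proportion
  f_full <- anova_f(patterns, labels)
  mask <- logical(V)
  mask[order(-f_full)[seq_len(n_keep[best])]] <- TRUE
  list(proportion = grid[best], mask = mask,
       inner_accuracy = stats::setNames(acc, grid))
}

#' Leave-one-run-out category decoding
#'
#' For each left-out run: nested voxel selection on the remaining runs,
#' a linear one-vs-one SVM trained on the remaining runs' patterns, and
#' prediction of the left-out run. Accuracy is pooled over folds. Voxel
#' selection and training never see the left-out run.
#'
#' @param patterns n x V pattern matrix (one condition).
#' @param labels category labels.
#' @param runs run ids; needs >= 3 distinct runs.
#' @param grid,C see [select_voxels_nested()].
#' @param select logical; set FALSE to skip voxel selection (all voxels).
#' @return An object of class `decoding_result`: list with `accuracy`,
#'   `folds` (data.frame run, truth, prediction), `proportions` (chosen
#'   proportion per fold).
#' @export
decode_loro <- function(patterns, labels, runs, grid = seq(0.1, 1, by = 0.1),
                        C = 1, select = TRUE) {
  labels <- as.character(labels)
  ur <- sort(unique(runs))
  if (length(ur) < 3L) stop("decode_loro: need >= 3 runs")
  folds <- list(); props <- numeric(0)
  for (r in ur) {
    tr <- runs != r; te <- !tr
    if (sum(tr) < length(unique(labels[tr])))
      stop("decode_loro: fewer training patterns than classes")
    if (select) {
      sel <- select_voxels_nested(patterns[tr, , drop = FALSE], labels[tr],
                                  runs[tr], grid = grid, C = C)
      keep <- sel$mask; props <- c(props, sel$proportion)
    } else {
      keep <- rep(TRUE, ncol(patterns)); props <- c(props, 1)
    }
    pred <- svm_predict(patterns[tr, keep, drop = FALSE], labels[tr],
                        patterns[te, keep, drop = FALSE], C)
    folds[[length(folds) + 1L]] <-
      data.frame(run = r, truth = labels[te], prediction = pred)
  }
  folds <- do.call(rbind, folds)
  structure(list(accuracy = mean(folds$prediction == folds$truth),
                 folds = folds, proportions = props),
            class = "decoding_result")
}

#' Decode one condition of a block dataset within one ROI
#'
#' Convenience wrapper: subset the block patterns to a condition and ROI,
#' then run [decode_loro()].
#'
#' @param bp `block_patterns` from [block_average()].
#' @param condition one of `"intact"`, `"most"`, `"least"`.
#' @param roi ROI label (default: all voxels).
#' @param ... passed to [decode_loro()].
#' @return A `decoding_result`.
#' @export
decode_condition <- function(bp, condition, roi = NULL, ...) {
  stopifnot(inherits(bp, "block_patterns"))
  sel <- bp$info$condition == condition
  vox <- if (is.null(roi)) rep(TRUE, ncol(bp$patterns)) else bp$roi == roi
  decode_loro(bp$patterns[sel, vox, drop = FALSE],
              bp$info$category[sel], bp$info$run[sel], ...)
}

#' Group statistics: paired t-tests per ROI with BH-FDR adjustment
#'
#' Two-sided paired t-test of `condition_a` vs `condition_b` per ROI across
#' subjects, with Benjamini-Hochberg adjustment across ROIs. Zero-variance
#' differences yield a degenerate test, reported with a note.
#'
#' @param df data.frame with columns `subject`, `roi`, `condition`, and a
#'   value column.
#' @param value name of the value column (default `"accuracy"`).
#' @param condition_a,condition_b the two conditions to compare (default
#'   most vs least).
#' @return data.frame: roi, mean_a, mean_b, t, df, p, q (BH-adjusted),
#'   note.
#' @export
group_stats <- function(df, value = "accuracy",
                        condition_a = "most", condition_b = "least") {
  stopifnot(all(c("subject", "roi", "condition", value) %in% names(df)))
  rois <- unique(df$roi)
  out <- lapply(rois, function(r) {
    a <- df[df$roi == r & df$condition == condition_a, ]
    b <- df[df$roi == r & df$condition == condition_b, ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    stopifnot(nrow(a) == nrow(b), nrow(a) >= 2L)
    d <- a[[value]] - b[[value]]
    if (sd(d) < 1e-12) {
      data.frame(roi = r, mean_a = mean(a[[value]]), mean_b = mean(b[[value]]),
                 t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                 df = length(d) - 1L, p = if (mean(d) == 0) 1 else 0,
                 note = "zero-variance differences")
    } else {
      tt <- t.test(a[[value]], b[[value]], paired = TRUE)
      data.frame(roi = r, mean_a = mean(a[[value]]), mean_b = mean(b[[value]]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, note = "")
    }
  })
  out <- do.call(rbind, out)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("roi", "mean_a", "mean_b", "t", "df", "p", "q", "note")]
}

#' Univariate condition means per ROI
#'
#' Mean block-averaged percent-signal-change response per ROI and
#' condition (the univariate companion to the decoding analysis; reported
#' as block-averaged signal, not separate GLM betas).
#'
#' @param bp `block_patterns`.
#' @return data.frame roi, condition, mean.
#' @export
univariate_means <- function(bp) {
  stopifnot(inherits(bp, "block_patterns"))
  rois <- unique(bp$roi)
  out <- expand.grid(roi = rois, condition = .CONDITIONS,
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(r, cond) {
    mean(bp$patterns[bp$info$condition == cond, bp$roi == r, drop = FALSE])
  }, out$roi, out$condition)
  out
}
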