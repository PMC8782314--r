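# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / direct formula) and independent of the package internals.

# two parallel horizontal lines `sep` px apart, centered on the canvas
parallel_pair <- function(sep = 10, len = 47, canvas = c(64, 64)) {
  y0 <- (canvas[1] - sep) %/% 2
  x0 <- (canvas[2] - len) %/% 2
  line_drawing(list(
    contour(rbind(c(x0, y0), c(x0 + len, y0))),
    contour(rbind(c(x0, y0 + sep), c(x0 + len, y0 + sep)))
  ), canvas = canvas)
}

# wedge: two lines from a common apex with the given opening angle
wedge_pair <- function(angle_deg = 30, len = 50, canvas = c(64, 64)) {
  th <- angle_deg * pi / 180
  apex <- c(5, 5)
  line_drawing(list(
    contour(rbind(apex, apex + c(len, 0))),
    contour(rbind(apex, apex + len * c(cos(th), sin(th))))
  ), canvas = canvas)
}

# brute-force exact EDT oracle: O(N * M) scan over all contour pixels
edt_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  cy <- row(mask)[mask]; cx <- col(mask)[mask]
  out <- matrix(NA_real_, H, W)
  for (y in seq_len(H)) for (x in seq_len(W))
    out[y, x] <- sqrt(min((y - cy)^2 + (x - cx)^2))
  out
}

# direct evaluation of one tent basis function
tent_oracle <- function(tau, k, TR = 2) pmax(0, 1 - abs(tau - TR * k) / TR)

# textbook one-way ANOVA F for a single voxel
anova_f_oracle <- function(x, g) {
  g <- factor(g)
  n <- length(x); k <- nlevels(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  n <- length(p); o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n); out[o] <- pmin(q, 1)
  out
}

# small event-image table with parametric values
make_images <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(image_id = sprintf("im%04d", seq_len(n)),
             parallelism = runif(n), luminance = runif(n),
             contrast = runif(n))
}

# 90-degree clockwise rotation of a matrix: m[y, x] -> out[x, H + 1 - y]
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
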