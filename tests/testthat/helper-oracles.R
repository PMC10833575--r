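# Independent brute-force oracles and small geometry builders used across
# the suite. These deliberately avoid the package's own code paths.

# Squared Euclidean distance from every pixel center to the nearest TRUE
# pixel center of `mask`, by exhaustive enumeration.
bf_sqdist_to_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  best <- rep(Inf, nr * nc)
  for (m in seq_len(nrow(idx)))
    best <- pmin(best, (rows - idx[m, 1L])^2 + (cols - idx[m, 2L])^2)
  matrix(best, nr, nc)
}

# Exhaustive dilation: pixels whose centers lie within r_px of the mask.
bf_dilate <- function(mask, r_px) {
  bf_sqdist_to_mask(mask) <= r_px^2
}

# Disk mask: pixel centers strictly inside radius r of (cx, cy), 0-based.
disk_mask <- function(nr, nc, cx, cy, r) {
  cols <- rep(0:(nc - 1), each = nr)
  rows <- rep(0:(nr - 1), times = nc)
  matrix((cols - cx)^2 + (rows - cy)^2 < r^2, nr, nc)
}

rect_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

random_mask <- function(nr, nc, density = 0.03) {
  m <- matrix(runif(nr * nc) < density, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

# ICC(A,k) point estimate from an aov()-based two-way ANOVA decomposition;
# an independent route to the mean squares.
icc_aov_oracle <- function(x) {
  df <- data.frame(y = as.vector(x),
                   subj = factor(as.vector(row(x))),
                   rater = factor(as.vector(col(x))))
  tab <- anova(stats::aov(y ~ subj + rater, data = df))
  MSR <- tab["subj", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (MSC - MSE) / nrow(x))
}

# Rater matrix simulated from known variance components.
simulate_rater_matrix <- function(n, k, sd_subject, sd_rater, sd_resid) {
  outer(rnorm(n, 0, sd_subject), rep(1, k)) +
    outer(rep(1, n), rnorm(k, 0, sd_rater)) +
    matrix(rnorm(n * k, 0, sd_resid), n, k)
}

# Small phantom spec used throughout the suite: full pipeline geometry at a
# reduced field of view (same 0.085 mm pixels).
small_phantom_spec <- function(pattern = "rim", seed = 1L, ...) {
  phantom_spec(width = 360, height = 280,
               loaf = list(cx = 179.5, cy = 139.5, rx = 150, ry = 115),
               tumor = list(cx = 179.5, cy = 139.5, r = 35),
               pattern = pattern, seed = seed, ...)
}

# Circle polygon (many vertices) for rasterization tests.
circle_polygon <- function(cx, cy, r, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}
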