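# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package's fast paths.

# Plain quadruple-loop 2D cross-correlation with zero padding.
naive_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  d <- dim(x); k <- dim(w)
  OW <- (d[1] + 2 * pad - k[1]) %/% stride + 1
  OH <- (d[2] + 2 * pad - k[2]) %/% stride + 1
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  y <- array(0, c(OW, OH, k[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(k[4]))
    for (ox in seq_len(OW)) for (oy in seq_len(OH)) {
      acc <- b[co]
      for (ci in seq_len(d[3]))
        acc <- acc + sum(xp[(ox - 1) * stride + seq_len(k[1]),
                            (oy - 1) * stride + seq_len(k[2]), ci, n] *
                           w[, , ci, co])
      y[ox, oy, co, n] <- acc
    }
  y
}

# Bilinear interpolation of a single map at one 0-based pixel point, with
# out-of-image neighbours contributing zero.
naive_bilinear_point <- function(img, sx, sy) {
  W <- nrow(img); H <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  ax <- sx - x0; ay <- sy - y0
  g <- function(xx, yy)
    if (xx >= 0 && xx < W && yy >= 0 && yy < H) img[xx + 1, yy + 1] else 0
  (1 - ax) * (1 - ay) * g(x0, y0) + ax * (1 - ay) * g(x0 + 1, y0) +
    (1 - ax) * ay * g(x0, y0 + 1) + ax * ay * g(x0 + 1, y0 + 1)
}

# Dense inverse-mapped affine warp (content moved by p -> A p + t) computed
# point by point with naive interpolation.
naive_warp_affine <- function(img, A, t = c(0, 0)) {
  W <- nrow(img); H <- ncol(img)
  Ai <- solve(A)
  out <- matrix(0, W, H)
  for (ix in seq_len(W)) for (iy in seq_len(H)) {
    p <- c(ix - 1, iy - 1) - t
    s <- Ai %*% p
    out[ix, iy] <- naive_bilinear_point(img, s[1], s[2])
  }
  out
}

# Rank-then-Pearson Spearman with average ranks for ties.
naive_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Exact Gaussian heatmap evaluated pixel by pixel.
naive_gaussian_map <- function(center, confidence, W, H, sigma) {
  out <- matrix(0, W, H)
  for (ix in seq_len(W)) for (iy in seq_len(H))
    out[ix, iy] <- confidence *
      exp(-((ix - 1 - center[1])^2 + (iy - 1 - center[2])^2) / (2 * sigma^2))
  out
}

# Central finite difference of f at x[i].
num_grad <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# A small smooth test image: a couple of Gaussian blobs on a dark background.
smooth_test_map <- function(W = 56, seed = 1) {
  set.seed(seed)
  m <- matrix(0, W, W)
  for (i in 1:3) {
    c0 <- runif(2, W * 0.3, W * 0.7)
    m <- m + runif(1, 0.5, 1) * naive_gaussian_map(c0, 1, W, W, runif(1, 3, 6))
  }
  m
}

# Tiny balanced walk dataset shared by training-oriented tests.
make_walk_dataset <- function(n_subjects = 4, n_views = 1, score_max = 2,
                              duration = 48, seed = 1) {
  generate_dataset(n_subjects = n_subjects,
                   views = default_camera_views(n_views),
                   action = "walk", score_max = score_max,
                   videos_per_score = 1, duration = duration, seed = seed)
}
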