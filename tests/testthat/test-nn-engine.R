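# Network-engine primitives against brute-force oracles and finite
# differences. The fast convolution has several internal paths (shifted GEMM,
# single-channel gather, single-filter gradients, strided im2col), so shapes
# are fuzzed across all of them.

conv_shapes <- list(
  list(W = 9, H = 9, C = 1, Cout = 10, k = 5, stride = 1, pad = 2),   # gather path
  list(W = 12, H = 10, C = 16, Cout = 1, k = 3, stride = 1, pad = 1), # single-filter
  list(W = 11, H = 13, C = 7, Cout = 5, k = 3, stride = 1, pad = 1),  # shifted GEMM
  list(W = 8, H = 8, C = 3, Cout = 4, k = 5, stride = 1, pad = 2),
  list(W = 14, H = 14, C = 3, Cout = 6, k = 3, stride = 2, pad = 1),  # im2col
  list(W = 15, H = 15, C = 2, Cout = 4, k = 7, stride = 2, pad = 3),
  list(W = 9, H = 9, C = 4, Cout = 3, k = 1, stride = 1, pad = 0))

test_that("convolution forward matches the naive oracle on all paths", {
  set.seed(11)
  for (s in conv_shapes) for (rep in 1:3) {
    x <- array(rnorm(s$W * s$H * s$C * 2), c(s$W, s$H, s$C, 2))
    w <- array(rnorm(s$k^2 * s$C * s$Cout), c(s$k, s$k, s$C, s$Cout))
    b <- rnorm(s$Cout)
    got <- trajscore:::conv2d_fwd_cpp(x, w, b, s$stride, s$pad)
    want <- naive_conv2d(x, w, b, s$stride, s$pad)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("convolution backward matches finite differences on all paths", {
  set.seed(12)
  for (s in conv_shapes) {
    x <- array(rnorm(s$W * s$H * s$C), c(s$W, s$H, s$C, 1))
    w <- array(rnorm(s$k^2 * s$C * s$Cout), c(s$k, s$k, s$C, s$Cout))
    b <- rnorm(s$Cout)
    y <- trajscore:::conv2d_fwd_cpp(x, w, b, s$stride, s$pad)
    dy <- array(rnorm(length(y)), dim(y))
    g <- trajscore:::conv2d_bwd_cpp(x, w, dy, s$stride, s$pad, TRUE)
    loss_w <- function(wv) {
      sum(trajscore:::conv2d_fwd_cpp(x, array(wv, dim(w)), b,
                                     s$stride, s$pad) * dy)
    }
    loss_x <- function(xv) {
      sum(trajscore:::conv2d_fwd_cpp(array(xv, dim(x)), w, b,
                                     s$stride, s$pad) * dy)
    }
    for (i in sample(length(w), 4))
      expect_equal(num_grad(loss_w, as.vector(w), i), g$dw[i], tolerance = 1e-5)
    for (i in sample(length(x), 4))
      expect_equal(num_grad(loss_x, as.vector(x), i), g$dx[i], tolerance = 1e-5)
    expect_equal(g$db, apply(dy, 3, sum), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("grouped convolution equals dense convolution with block weights", {
  set.seed(13)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  wg <- array(rnorm(9 * 3 * 4), c(3, 3, 3, 4))   # 2 groups of 3 -> 2 each
  b <- rnorm(4)
  layer <- trajscore:::nn_layer("groupconv", w = "w", b = "b", stride = 1L,
                                pad = 1L, groups = 2L)
  got <- trajscore:::layer_forward(layer, list(w = wg, b = b), x, FALSE)$y
  wd <- array(0, c(3, 3, 6, 4))
  wd[, , 1:3, 1:2] <- wg[, , , 1:2]
  wd[, , 4:6, 3:4] <- wg[, , , 3:4]
  want <- naive_conv2d(x, wd, b, 1, 1)
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("maxpool forward/backward agree with direct enumeration", {
  set.seed(14)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  r <- trajscore:::maxpool_fwd_cpp(x, 3L, 2L, 1L)
  # naive pooling with padding treated as -Inf
  xp <- array(-Inf, c(9, 9, 2, 2)); xp[2:8, 2:8, , ] <- x
  for (n in 1:2) for (c in 1:2) for (ox in 1:4) for (oy in 1:4)
    expect_equal(r$y[ox, oy, c, n],
                 max(xp[(ox - 1) * 2 + 1:3, (oy - 1) * 2 + 1:3, c, n]))
  dy <- array(rnorm(length(r$y)), dim(r$y))
  dx <- trajscore:::maxpool_bwd_cpp(r$idx, dy, dim(x))
  loss <- function(xv) {
    sum(trajscore:::maxpool_fwd_cpp(array(xv, dim(x)), 3L, 2L, 1L)$y * dy)
  }
  for (i in sample(length(x), 6))
    expect_equal(num_grad(loss, as.vector(x), i), dx[i], tolerance = 1e-5)
})

test_that("batch norm matches hand computation and its gradient checks out", {
  set.seed(15)
  x <- array(rnorm(5 * 5 * 3 * 4, mean = 2, sd = 3), c(5, 5, 3, 4))
  params <- list(g = c(1.5, 0.7, 1), b = c(0.1, -0.2, 0),
                 rm = rep(0, 3), rv = rep(1, 3))
  layer <- trajscore:::nn_layer("bn", gamma = "g", beta = "b",
                                rmean = "rm", rvar = "rv")
  out <- trajscore:::layer_forward(layer, params, x, training = TRUE)
  for (c in 1:3) {
    z <- (x[, , c, ] - mean(x[, , c, ])) /
      sqrt(mean((x[, , c, ] - mean(x[, , c, ]))^2) + 1e-5)
    expect_equal(out$y[, , c, ], params$g[c] * z + params$b[c],
                 tolerance = 1e-10)
  }
  # running stats move toward the batch stats
  expect_equal(out$update$rm, 0.1 * apply(x, 3, mean), tolerance = 1e-10)

  dy <- array(rnorm(length(x)), dim(x))
  bk <- trajscore:::layer_backward(layer, params, out$cache, dy)
  loss <- function(xv) {
    sum(trajscore:::layer_forward(layer, params,
                                  array(xv, dim(x)), TRUE)$y * dy)
  }
  for (i in sample(length(x), 5))
    expect_equal(num_grad(loss, as.vector(x), i), bk$dx[i], tolerance = 1e-4)
})

test_that("bilinear sampling matches the per-point oracle and differentiates", {
  set.seed(16)
  img <- matrix(rnorm(25), 5, 5)
  gx <- matrix(runif(20, -0.8, 4.8), 20, 1)
  gy <- matrix(runif(20, -0.8, 4.8), 20, 1)
  got <- trajscore:::bilinear_fwd_cpp(array(img, c(5, 5, 1)), gx, gy)
  for (p in 1:20)
    expect_equal(got[p, 1], naive_bilinear_point(img, gx[p, 1], gy[p, 1]),
                 tolerance = 1e-12)

  dy <- matrix(rnorm(20), 20, 1)
  g <- trajscore:::bilinear_bwd_cpp(array(img, c(5, 5, 1)), gx, gy, dy)
  loss_img <- function(v) {
    sum(trajscore:::bilinear_fwd_cpp(array(v, c(5, 5, 1)), gx, gy) * dy)
  }
  for (i in sample(25, 5))
    expect_equal(num_grad(loss_img, as.vector(img), i), g$dx[i],
                 tolerance = 1e-6)
  loss_gx <- function(v) {
    sum(trajscore:::bilinear_fwd_cpp(array(img, c(5, 5, 1)),
                                     matrix(v, 20, 1), gy) * dy)
  }
  for (p in sample(20, 5))
    expect_equal(num_grad(loss_gx, as.vector(gx), p), g$dgx[p, 1],
                 tolerance = 1e-6)
})

test_that("fully-connected and residual blocks backpropagate correctly", {
  set.seed(17)
  params <- list(w = matrix(rnorm(12), 3, 4), b = rnorm(3))
  layer <- trajscore:::nn_layer("fc", w = "w", b = "b")
  x <- matrix(rnorm(8), 4, 2)
  fw <- trajscore:::layer_forward(layer, params, x, FALSE)
  expect_equal(fw$y, params$w %*% x + params$b)
  dy <- matrix(rnorm(6), 3, 2)
  bk <- trajscore:::layer_backward(layer, params, fw$cache, dy)
  expect_equal(bk$grads$w, dy %*% t(x))
  expect_equal(bk$dx, t(params$w) %*% dy)

  # residual block: main conv + identity shortcut, checked by composition
  p <- list(w = array(rnorm(9 * 4), c(3, 3, 2, 2)), b = rnorm(2))
  block <- trajscore:::nn_layer(
    "resblock",
    main = list(trajscore:::nn_layer("conv", w = "w", b = "b",
                                     stride = 1L, pad = 1L)),
    shortcut = list())
  xr <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  fr <- trajscore:::layer_forward(block, p, xr, FALSE)
  pre <- naive_conv2d(xr, p$w, p$b, 1, 1) + xr
  expect_equal(fr$y, pre * (pre > 0), tolerance = 1e-10, ignore_attr = TRUE)
  dyr <- array(rnorm(length(xr)), dim(xr))
  br <- trajscore:::layer_backward(block, p, fr$cache, dyr)
  lossr <- function(v) {
    sum(trajscore:::layer_forward(block, list(w = array(v, dim(p$w)), b = p$b),
                                  xr, FALSE)$y * dyr)
  }
  for (i in sample(length(p$w), 4))
    expect_equal(num_grad(lossr, as.vector(p$w), i), br$grads$w[i],
                 tolerance = 1e-5)
})
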