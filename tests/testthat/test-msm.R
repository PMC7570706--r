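# Score-classification backbones: channel adaptation, first-layer weight
# reuse, forward behaviour, trainability.

test_that("adapted backbones emit S+1 logits for the movement score ranges", {
  # S = 4 (5 classes) and S = 12 (13 classes) are the extreme score ranges
  bb5 <- adapt_backbone("tiny", J = 15, S = 4, seed = 1)
  desc <- array(runif(56 * 56 * 15, 0, 255), c(56, 56, 15))
  expect_length(forward_score(bb5, desc), 5)

  bb13 <- adapt_backbone("tiny", J = 15, S = 12, seed = 1)
  expect_length(forward_score(bb13, desc), 13)

  expect_error(forward_score(bb5, desc * NaN), class = "trajscore_invalid_data")
})

test_that("tiny backbone forward fits interactive latency", {
  bb <- adapt_backbone("tiny", J = 15, S = 4, seed = 2)
  desc <- array(runif(56 * 56 * 15, 0, 255), c(56, 56, 15))
  forward_score(bb, desc)  # warm up
  t0 <- Sys.time()
  for (i in 1:10) forward_score(bb, desc)
  per_call <- as.numeric(Sys.time() - t0, units = "secs") / 10
  expect_lt(per_call, 0.05)
})

test_that("first-layer tiling preserves constant-input responses", {
  set.seed(3)
  pre <- array(rnorm(3 * 3 * 3 * 8), c(3, 3, 3, 8))

  # J = 3: degenerate tiling returns the pretrained kernel unchanged
  expect_equal(init_first_layer(pre, 3), pre)

  # J = 6: each channel slice appears twice at half weight
  w6 <- init_first_layer(pre, 6)
  expect_equal(w6[, , 1, ], pre[, , 1, ] / 2)
  expect_equal(w6[, , 4, ], pre[, , 1, ] / 2)
  expect_equal(w6[, , 5, ], pre[, , 2, ] / 2)

  # response to an all-ones input matches the 3-channel response
  w15 <- init_first_layer(pre, 15)
  ones3 <- array(1, c(8, 8, 3, 1))
  ones15 <- array(1, c(8, 8, 15, 1))
  y3 <- naive_conv2d(ones3, pre, numeric(8), 1, 1)
  y15 <- trajscore:::conv2d_fwd_cpp(ones15, w15, numeric(8), 1L, 1L)
  expect_equal(y15, y3, tolerance = 1e-5, ignore_attr = TRUE)

  expect_error(init_first_layer(pre, 0), class = "trajscore_invalid_argument")
  expect_error(init_first_layer(pre[, , 1:2, , drop = FALSE], 6),
               class = "trajscore_shape_error")
})

test_that("evaluation-mode scoring is deterministic and matches a manual head", {
  bb <- adapt_backbone("tiny", J = 15, S = 3, seed = 4)
  desc <- array(runif(56 * 56 * 15, 0, 255), c(56, 56, 15))
  expect_identical(forward_score(bb, desc), forward_score(bb, desc))

  # hand-set FC head: logits must equal the manually computed affine chain
  # applied to the global-average-pooled features
  gap_i <- which(vapply(bb$layers, function(l) l$op == "gap", logical(1)))
  feats_layers <- bb$layers[seq_len(gap_i)]
  feats <- trajscore:::nn_forward(feats_layers, bb$params,
                                  trajscore:::as_dim4(desc), FALSE)$y
  set.seed(5)
  bb$params[["bb.f1.w"]] <- diag(32)
  bb$params[["bb.f1.b"]] <- rep(0.5, 32)
  bb$params[["bb.f2.w"]] <- matrix(rnorm(4 * 32), 4, 32)
  bb$params[["bb.f2.b"]] <- c(1, 2, 3, 4)
  h <- pmax(feats + 0.5, 0)
  want <- as.numeric(bb$params[["bb.f2.w"]] %*% h + bb$params[["bb.f2.b"]])
  expect_equal(forward_score(bb, desc), want, tolerance = 1e-10)
})

test_that("standard-architecture families differ only at the re-channeled ends", {
  # parameter-count oracle computed from the layer arithmetic of the standard
  # architectures (convolutions and FC layers with biases)
  vgg_cfg <- c(64, 64, 128, 128, 256, 256, 256, 256, 512, 512, 512, 512,
               512, 512, 512, 512)
  conv_params <- function(k, cin, cout) k * k * cin * cout + cout
  vgg_middle <- 0
  cin <- 64
  for (cout in vgg_cfg[-1]) {
    vgg_middle <- vgg_middle + conv_params(3, cin, cout)
    cin <- cout
  }
  vgg_fc_middle <- (25088 * 4096 + 4096) + (4096 * 4096 + 4096)

  bb <- adapt_backbone("vgg19_adapted", J = 15, S = 4, seed = 6)
  n_first <- length(bb$params[["bb.c1.w"]]) + length(bb$params[["bb.c1.b"]]) +
    4 * 64                                  # adapted first layer + its BN
  n_last <- length(bb$params[["bb.f3.w"]]) + length(bb$params[["bb.f3.b"]])
  n_total <- sum(vapply(bb$params, length, 1L))
  expect_equal(n_total - n_first - n_last, vgg_middle + vgg_fc_middle)
  expect_equal(dim(bb$params[["bb.c1.w"]]), c(3L, 3L, 15L, 64L))
  expect_equal(nrow(bb$params[["bb.f3.w"]]), 5L)

  # forward at 224x224 via internal bilinear resize produces 5 finite logits
  desc <- array(runif(56 * 56 * 15, 0, 255), c(56, 56, 15))
  lg <- forward_score(bb, desc)
  expect_length(lg, 5)
  expect_true(all(is.finite(lg)))
  rm(bb); gc(verbose = FALSE)
})

test_that("the grouped-convolution residual family forwards and counts right", {
  bb <- adapt_backbone("resnext50_adapted", J = 15, S = 5, seed = 7)
  # ResNeXt-50 32x4d: conv/bn/fc parameter count from the block arithmetic
  conv_p <- function(k, cin, cout, groups = 1) k * k * (cin / groups) * cout + cout
  bn_p <- function(ch) 4 * ch
  total <- conv_p(7, 15, 64) + bn_p(64)           # adapted stem
  cin <- 64
  blocks <- c(3, 4, 6, 3); widths <- c(128, 256, 512, 1024)
  couts <- c(256, 512, 1024, 2048)
  for (st in 1:4) for (b in seq_len(blocks[st])) {
    w <- widths[st]; co <- couts[st]
    total <- total + conv_p(1, cin, w) + bn_p(w) +
      conv_p(3, w, w, 32) + bn_p(w) + conv_p(1, w, co) + bn_p(co)
    if (cin != co || (b == 1 && st > 1))
      total <- total + conv_p(1, cin, co) + bn_p(co)
    cin <- co
  }
  total <- total + 2048 * 6 + 6                    # adapted final FC, S = 5
  expect_equal(sum(vapply(bb$params, length, 1L)), total)
  expect_equal(dim(bb$params[["bb.stem.w"]]), c(7L, 7L, 15L, 64L))

  desc <- array(runif(56 * 56 * 15, 0, 255), c(56, 56, 15))
  lg <- forward_score(bb, desc)
  expect_length(lg, 6)
  expect_true(all(is.finite(lg)))
  rm(bb); gc(verbose = FALSE)
})

test_that("the tiny backbone learns a separable descriptor task quickly", {
  # three classes encoded by which block of joint channels carries energy —
  # linearly separable in channel-pooled features
  set.seed(8)
  make_desc <- function(cls) {
    m <- naive_gaussian_map(c(28, 28), 1, 56, 56, 8) * 255
    x <- array(runif(56 * 56 * 15, 0, 20), c(56, 56, 15))
    for (ch in (cls - 1) * 5 + 1:5) x[, , ch] <- x[, , ch] + m
    x
  }
  bb <- adapt_backbone("tiny", J = 15, S = 2, seed = 9)
  params <- bb$params
  velocity <- list()
  acc <- 0
  for (step in 1:200) {
    cls <- sample(1:3, 4, replace = TRUE)
    x <- array(0, c(56, 56, 15, 4))
    for (i in 1:4) x[, , , i] <- make_desc(cls[i])
    fw <- trajscore:::nn_forward(bb$layers, params, x, training = TRUE)
    params <- fw$params                      # keep batch-norm running stats
    g <- trajscore:::cross_entropy_grad(fw$y, cls - 1)
    bk <- trajscore:::nn_backward(bb$layers, params, fw$caches, g)
    upd <- trajscore:::sgd_step(
      params, bk$grads, velocity, lr = 0.01, momentum = 0.9,
      trainable = grep("\\.(rmean|rvar)$", names(params), value = TRUE,
                       invert = TRUE))
    params <- upd$params
    velocity <- upd$velocity
  }
  test_cls <- rep(1:3, 20)
  correct <- vapply(test_cls, function(cl) {
    lg <- trajscore:::nn_forward(bb$layers, params,
                                 trajscore:::as_dim4(make_desc(cl)), FALSE)$y
    which.max(lg) == cl
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})
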