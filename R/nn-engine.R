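#' @useDynLib trajscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- Minimal dense-network engine -------------------------------------------
#
# Layers are plain lists with an `op` field; trainable tensors live in a single
# named list of arrays (`params`) and layers reference them by name, so weight
# sharing (e.g. one temporal-aggregation filter applied to every joint) falls
# out naturally. Activation tensors are column-major arrays dim c(W, H, C, N);
# after `flatten`/`gap` they become (features x N) matrices.

nn_layer <- function(op, ...) c(list(op = op), list(...))

# He-scaled gaussian init for a conv kernel (kw, kh, cin, cout).
init_conv <- function(kw, kh, cin, cout, gain = 2) {
  array(stats::rnorm(kw * kh * cin * cout, sd = sqrt(gain / (kw * kh * cin))),
        dim = c(kw, kh, cin, cout))
}

init_fc <- function(nout, nin, gain = 2) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(gain / nin)), nout, nin)
}

as_dim4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x  # higher-rank arrays pass through; C++ kernels fold trailing dims
}

layer_forward <- function(layer, params, x, training) {
  op <- layer$op
  if (op == "conv") {
    x <- as_dim4(x)
    y <- conv2d_fwd_cpp(x, params[[layer$w]], params[[layer$b]],
                        layer$stride, layer$pad)
    list(y = y, cache = list(x = x))
  } else if (op == "groupconv") {
    x <- as_dim4(x)
    g <- layer$groups
    d <- dim(x)
    cin_g <- d[3] %/% g
    w <- params[[layer$w]]; b <- params[[layer$b]]
    cout_g <- dim(w)[4] %/% g
    ys <- vector("list", g)
    for (i in seq_len(g)) {
      xi <- x[, , ((i - 1) * cin_g + 1):(i * cin_g), , drop = FALSE]
      wi <- w[, , , ((i - 1) * cout_g + 1):(i * cout_g), drop = FALSE]
      ys[[i]] <- conv2d_fwd_cpp(xi, wi, b[((i - 1) * cout_g + 1):(i * cout_g)],
                                layer$stride, layer$pad)
    }
    dy1 <- dim(ys[[1]])
    y <- array(0, c(dy1[1], dy1[2], dy1[3] * g, dy1[4]))
    for (i in seq_len(g)) y[, , ((i - 1) * cout_g + 1):(i * cout_g), ] <- ys[[i]]
    list(y = y, cache = list(x = x))
  } else if (op == "relu") {
    y <- relu_fwd_cpp(x)
    list(y = y, cache = list(y = y))
  } else if (op == "maxpool") {
    x <- as_dim4(x)
    r <- maxpool_fwd_cpp(x, layer$k, layer$stride, layer$pad)
    list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
  } else if (op == "bn") {
    x <- as_dim4(x)
    d <- dim(x)
    eps <- layer$eps %||% 1e-5
    if (training && !isTRUE(layer$bypass)) {
      if (d[3] == 1) {
        m <- mean(x); v <- mean(x^2) - m^2
      } else {
        xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
        m <- colMeans(xm)
        v <- colMeans(xm^2) - m^2
      }
    } else if (isTRUE(layer$bypass)) {
      m <- rep(0, d[3]); v <- rep(1 - eps, d[3])
    } else {
      m <- params[[layer$rmean]]; v <- params[[layer$rvar]]
    }
    mb <- array(rep(m, each = d[1] * d[2]), d)
    vb <- array(rep(v, each = d[1] * d[2]), d)
    xhat <- (x - mb) / sqrt(vb + eps)
    gb <- array(rep(params[[layer$gamma]], each = d[1] * d[2]), d)
    bb <- array(rep(params[[layer$beta]], each = d[1] * d[2]), d)
    y <- gb * xhat + bb
    upd <- NULL
    if (training && !isTRUE(layer$bypass)) {
      mom <- layer$momentum %||% 0.1
      upd <- list()
      upd[[layer$rmean]] <- (1 - mom) * params[[layer$rmean]] + mom * m
      upd[[layer$rvar]] <- (1 - mom) * params[[layer$rvar]] + mom * v
    }
    list(y = y, cache = list(xhat = xhat, var = v, eps = eps, dims = d,
                             training = training && !isTRUE(layer$bypass)),
         update = upd)
  } else if (op == "flatten") {
    d <- dim(as_dim4(x))
    y <- matrix(x, prod(d[1:3]), d[4])
    list(y = y, cache = list(xdim = d))
  } else if (op == "gap") {
    x <- as_dim4(x)
    d <- dim(x)
    y <- apply(x, c(3, 4), mean)
    if (is.null(dim(y))) y <- matrix(y, d[3], d[4])
    list(y = y, cache = list(xdim = d))
  } else if (op == "fc") {
    y <- params[[layer$w]] %*% x + params[[layer$b]]
    list(y = y, cache = list(x = x))
  } else if (op == "scale") {
    list(y = x * layer$mul + layer$add, cache = NULL)
  } else if (op == "resize") {
    x <- as_dim4(x)
    d <- dim(x)
    ow <- layer$size[1]; oh <- layer$size[2]
    gx <- rep(seq(0, d[1] - 1, length.out = ow), times = oh)
    gy <- rep(seq(0, d[2] - 1, length.out = oh), each = ow)
    nimg <- d[3] * d[4]
    gxm <- matrix(gx, length(gx), nimg)
    gym <- matrix(gy, length(gy), nimg)
    xi <- x; dim(xi) <- c(d[1], d[2], nimg)
    y <- bilinear_fwd_cpp(xi, gxm, gym)
    dim(y) <- c(ow, oh, d[3], d[4])
    list(y = y, cache = list(x = x, gx = gxm, gy = gym))
  } else if (op == "resblock") {
    rm_ <- nn_forward(layer$main, params, x, training)
    rs_ <- if (length(layer$shortcut))
      nn_forward(layer$shortcut, params, x, training)
    else list(y = x, caches = NULL, params = params)
    s <- rm_$y + rs_$y
    y <- s * (s > 0)
    # merge running-stat updates from both branches
    upd <- list()
    for (nm in names(params)) {
      if (!identical(rm_$params[[nm]], params[[nm]])) upd[[nm]] <- rm_$params[[nm]]
      if (!is.null(rs_$caches) && !identical(rs_$params[[nm]], params[[nm]]))
        upd[[nm]] <- rs_$params[[nm]]
    }
    list(y = y, cache = list(main = rm_$caches, shortcut = rs_$caches,
                             mask = s > 0),
         update = if (length(upd)) upd else NULL)
  } else {
    stop("unknown layer op: ", op)
  }
}

layer_backward <- function(layer, params, cache, dy) {
  op <- layer$op
  grads <- list()
  if (op == "conv") {
    r <- conv2d_bwd_cpp(cache$x, params[[layer$w]], as_dim4(dy),
                        layer$stride, layer$pad,
                        need_dx = !isTRUE(layer$no_input_grad))
    grads[[layer$w]] <- r$dw
    grads[[layer$b]] <- r$db
    dx <- r$dx
  } else if (op == "groupconv") {
    g <- layer$groups
    x <- cache$x
    d <- dim(x)
    cin_g <- d[3] %/% g
    w <- params[[layer$w]]
    cout_g <- dim(w)[4] %/% g
    dy <- as_dim4(dy)
    dx <- array(0, d)
    dw <- array(0, dim(w))
    db <- numeric(dim(w)[4])
    for (i in seq_len(g)) {
      ci <- ((i - 1) * cin_g + 1):(i * cin_g)
      co <- ((i - 1) * cout_g + 1):(i * cout_g)
      r <- conv2d_bwd_cpp(x[, , ci, , drop = FALSE], w[, , , co, drop = FALSE],
                          dy[, , co, , drop = FALSE], layer$stride, layer$pad)
      dx[, , ci, ] <- r$dx
      dw[, , , co] <- r$dw
      db[co] <- r$db
    }
    grads[[layer$w]] <- dw
    grads[[layer$b]] <- db
  } else if (op == "relu") {
    dx <- relu_bwd_cpp(cache$y, dy)
  } else if (op == "maxpool") {
    dx <- maxpool_bwd_cpp(cache$idx, as_dim4(dy), as.integer(cache$xdim))
  } else if (op == "bn") {
    d <- cache$dims
    dy <- as_dim4(dy)
    npix <- prod(d[c(1, 2, 4)])
    ch_sum <- function(z) {
      if (d[3] == 1) sum(z)
      else colSums(matrix(aperm(z, c(1, 2, 4, 3)), ncol = d[3]))
    }
    xhat <- cache$xhat
    gamma <- params[[layer$gamma]]
    dgamma <- ch_sum(dy * xhat)
    dbeta <- ch_sum(dy)
    grads[[layer$gamma]] <- dgamma
    grads[[layer$beta]] <- dbeta
    gb <- array(rep(gamma, each = d[1] * d[2]), d)
    dxhat <- dy * gb
    inv_sd <- 1 / sqrt(cache$var + cache$eps)
    isb <- array(rep(inv_sd, each = d[1] * d[2]), d)
    if (cache$training) {
      s1 <- ch_sum(dxhat)
      s2 <- ch_sum(dxhat * xhat)
      s1b <- array(rep(s1, each = d[1] * d[2]), d)
      s2b <- array(rep(s2, each = d[1] * d[2]), d)
      dx <- isb / npix * (npix * dxhat - s1b - xhat * s2b)
    } else {
      dx <- dxhat * isb
    }
  } else if (op == "flatten") {
    dx <- array(dy, cache$xdim)
  } else if (op == "gap") {
    d <- cache$xdim
    dx <- array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
  } else if (op == "fc") {
    grads[[layer$w]] <- dy %*% t(cache$x)
    grads[[layer$b]] <- rowSums(dy)
    dx <- t(params[[layer$w]]) %*% dy
  } else if (op == "scale") {
    dx <- dy * layer$mul
  } else if (op == "resize") {
    d <- dim(cache$x)
    dy4 <- as_dim4(dy)
    dyi <- dy4; dim(dyi) <- c(dim(dy4)[1] * dim(dy4)[2], d[3] * d[4])
    xi <- cache$x; dim(xi) <- c(d[1], d[2], d[3] * d[4])
    r <- bilinear_bwd_cpp(xi, cache$gx, cache$gy, dyi)
    dx <- r$dx
    dim(dx) <- d
  } else if (op == "resblock") {
    ds <- dy * cache$mask
    rm_ <- nn_backward(layer$main, params, cache$main, ds)
    grads <- rm_$grads
    if (length(layer$shortcut)) {
      rs_ <- nn_backward(layer$shortcut, params, cache$shortcut, ds)
      grads <- add_grads(grads, rs_$grads)
      dx <- rm_$dx + rs_$dx
    } else {
      dx <- rm_$dx + ds
    }
  } else {
    stop("unknown layer op: ", op)
  }
  list(dx = dx, grads = grads)
}

nn_forward <- function(layers, params, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], params, x, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$update)) for (nm in names(r$update)) params[[nm]] <- r$update[[nm]]
  }
  list(y = x, caches = caches, params = params)
}

nn_backward <- function(layers, params, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], params, caches[[i]], dy)
    dy <- r$dx
    for (nm in names(r$grads)) {
      grads[[nm]] <- if (is.null(grads[[nm]])) r$grads[[nm]] else grads[[nm]] + r$grads[[nm]]
    }
  }
  list(dx = dy, grads = grads)
}

# Accumulate `b` into `a` elementwise by name.
add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

sgd_step <- function(params, grads, velocity, lr, momentum = 0.9,
                     trainable = names(params)) {
  for (nm in intersect(trainable, names(grads))) {
    v <- velocity[[nm]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * grads[[nm]]
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, velocity = velocity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
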