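# Trajectory-descriptor module: a learned temporal-aggregation convolution
# collapses a W x H x T stack of one joint's heatmaps into a single trajectory
# map; a spatial transformer (4-parameter affine: rotation/scale/shear, no
# translation) regresses per-joint transform parameters and resamples the map
# on the induced grid to normalize it across camera views.

#' Initialise trajectory-descriptor weights
#'
#' The temporal-aggregation layer is a single 3x3 2D convolution over the T
#' temporal channels with batch norm and ReLU. The localisation network is
#' conv 5x5 (1->10), maxpool 2, ReLU, conv 5x5 (10->10), maxpool 2, ReLU,
#' FC 32, ReLU, FC 4. The final FC is initialised to the identity transform
#' (zero weights, bias `(1, 0, 0, 1)`), the standard stable initialisation: at
#' initialisation the spatial transformer is an exact no-op.
#'
#' The temporal-aggregation filter defaults to an all-positive near-uniform
#' kernel (temporal mean plus noise) so trajectory traces are visible from the
#' first step; batch-norm keeps the scale in check while training adapts it.
#'
#' @param T_len clip length (temporal channels), default 16.
#' @param input_size descriptor side length W (= H); >= 16 so both poolings
#'   are valid.
#' @return a named list of parameter arrays prefixed `phi.`, `phi_bn.`,
#'   `loc.`.
#' @keywords internal
init_vtdm_params <- function(T_len = 16L, input_size = 56L) {
  if (input_size < 16)
    abort("input_size must be >= 16 for the two 2x2 poolings",
          class = "trajscore_invalid_argument")
  flat <- (input_size %/% 4)^2 * 10
  p <- list()
  p[["phi.w"]] <- array(1 / (9 * T_len), c(3, 3, T_len, 1)) +
    init_conv(3, 3, T_len, 1) * 0.05
  p[["phi.b"]] <- 0
  p[["phi_bn.gamma"]] <- 1
  p[["phi_bn.beta"]] <- 0
  p[["phi_bn.rmean"]] <- 0
  p[["phi_bn.rvar"]] <- 1
  p[["loc.c1.w"]] <- init_conv(5, 5, 1, 10)
  p[["loc.c1.b"]] <- numeric(10)
  p[["loc.c2.w"]] <- init_conv(5, 5, 10, 10)
  p[["loc.c2.b"]] <- numeric(10)
  p[["loc.f1.w"]] <- init_fc(32, flat)
  p[["loc.f1.b"]] <- numeric(32)
  p[["loc.f2.w"]] <- matrix(0, 4, 32)
  p[["loc.f2.b"]] <- c(1, 0, 0, 1)
  p
}

loc_layers <- function() {
  list(nn_layer("conv", w = "loc.c1.w", b = "loc.c1.b", stride = 1L, pad = 2L),
       nn_layer("maxpool", k = 2L, stride = 2L, pad = 0L),
       nn_layer("relu"),
       nn_layer("conv", w = "loc.c2.w", b = "loc.c2.b", stride = 1L, pad = 2L),
       nn_layer("maxpool", k = 2L, stride = 2L, pad = 0L),
       nn_layer("relu"),
       nn_layer("flatten"),
       nn_layer("fc", w = "loc.f1.w", b = "loc.f1.b"),
       nn_layer("relu"),
       nn_layer("fc", w = "loc.f2.w", b = "loc.f2.b"))
}

#' Temporal aggregation of a joint heatmap clip into a trajectory descriptor
#'
#' Applies the shared 3x3 convolution filter over the T temporal channels
#' (stride 1, zero padding 1), then batch norm and ReLU, producing the
#' `W x H x 1` trajectory descriptor of the clip.
#'
#' @param clip `W x H x T` array from [stack_clip()].
#' @param weights parameter list from [init_vtdm_params()] (or a fitted
#'   model's `$params`).
#' @param bn_mode `"eval"` (running statistics), `"train"` (batch statistics)
#'   or `"bypass"` (identity batch norm, used by numerical oracles).
#' @param relu apply the final ReLU (default `TRUE`).
#' @param pre_activation if `TRUE`, return the raw convolution output before
#'   batch norm and ReLU.
#' @return a `W x H` matrix.
#' @export
trajectory_descriptor <- function(clip, weights, bn_mode = "eval",
                                  relu = TRUE, pre_activation = FALSE) {
  d <- dim(clip)
  kT <- dim(weights[["phi.w"]])[3]
  if (length(d) != 3 || d[3] != kT)
    abort(sprintf("clip has %d temporal channels, filter expects %d",
                  if (length(d) == 3) d[3] else -1L, kT),
          class = "trajscore_shape_error")
  x <- array(clip, c(d[1], d[2], d[3], 1))
  y <- conv2d_fwd_cpp(x, weights[["phi.w"]], weights[["phi.b"]], 1L, 1L)
  if (pre_activation) return(matrix(y, d[1], d[2]))
  bn <- nn_layer("bn", gamma = "phi_bn.gamma", beta = "phi_bn.beta",
                 rmean = "phi_bn.rmean", rvar = "phi_bn.rvar",
                 bypass = identical(bn_mode, "bypass"))
  y <- layer_forward(bn, weights, y, training = identical(bn_mode, "train"))$y
  if (relu) y <- y * (y > 0)
  matrix(y, d[1], d[2])
}

#' Regress affine transform parameters from a trajectory descriptor
#'
#' Runs the localisation network and reshapes its 4 outputs into the 2x2
#' matrix `theta` of the affine sampling transform (row-major:
#' `theta[1,1], theta[1,2], theta[2,1], theta[2,2]`).
#'
#' @param desc `W x H` trajectory descriptor (W = H >= 16).
#' @param weights parameter list containing the `loc.*` tensors sized for
#'   this input resolution.
#' @return a 2x2 numeric matrix.
#' @export
localise <- function(desc, weights) {
  d <- dim(desc)
  if (d[1] < 16 || d[2] < 16)
    abort("descriptor must be at least 16x16", class = "trajscore_shape_error")
  x <- array(desc, c(d[1], d[2], 1, 1))
  v <- nn_forward(loc_layers(), weights, x, training = FALSE)$y
  matrix(as.numeric(v), 2, 2, byrow = TRUE)
}

#' Build an affine sampling grid
#'
#' The general grid G holds the normalized pixel-center coordinates of the
#' output map in `[-1, 1]^2` (origin at the map center, x rightward, y
#' downward); each source point is `theta %*% c(x, y)` — a pure 4-parameter
#' linear map with no translation term, so rotation/scale/shear act about the
#' map center.
#'
#' @param theta 2x2 affine matrix (e.g. from [localise()]).
#' @param out_size output `(W', H')`.
#' @return a `sampling_grid`: list with `xs`, `ys` (`W' x H'` matrices of
#'   normalized source coordinates) and `out_size`.
#' @export
make_sampling_grid <- function(theta, out_size = c(56, 56)) {
  if (any(out_size < 1))
    abort("out_size must be positive", class = "trajscore_invalid_argument")
  if (!all(dim(theta) == c(2, 2)) || any(!is.finite(theta)))
    abort("theta must be a finite 2x2 matrix", class = "trajscore_shape_error")
  W <- out_size[1]; H <- out_size[2]
  gx <- if (W > 1) seq(-1, 1, length.out = W) else 0
  gy <- if (H > 1) seq(-1, 1, length.out = H) else 0
  GX <- matrix(gx, W, H)
  GY <- matrix(gy, W, H, byrow = TRUE)
  structure(list(xs = theta[1, 1] * GX + theta[1, 2] * GY,
                 ys = theta[2, 1] * GX + theta[2, 2] * GY,
                 out_size = as.integer(out_size)),
            class = "sampling_grid")
}

#' Sample a descriptor on an affine grid by bilinear interpolation
#'
#' Each output pixel is the bilinear interpolation of the input at its source
#' point; source points outside the input (outside `[-1, 1]^2` in normalized
#' coordinates) contribute zero, matching the zero background of trajectory
#' maps. The operation is differentiable in both the descriptor and the grid.
#'
#' @param desc `W x H` numeric matrix.
#' @param grid a [make_sampling_grid()] result.
#' @return a `W' x H'` matrix.
#' @export
bilinear_sample <- function(desc, grid) {
  if (any(!is.finite(grid$xs)) || any(!is.finite(grid$ys)))
    abort("grid contains non-finite coordinates", class = "trajscore_invalid_grid")
  W <- nrow(desc); H <- ncol(desc)
  px <- (grid$xs + 1) / 2 * (W - 1)
  py <- (grid$ys + 1) / 2 * (H - 1)
  x <- array(desc, c(W, H, 1))
  y <- bilinear_fwd_cpp(x, matrix(px, ncol = 1), matrix(py, ncol = 1))
  matrix(y, grid$out_size[1], grid$out_size[2])
}

#' Warp an image by a pixel-space affine map
#'
#' Computes the dense warp `I'(p) = I(A^{-1} (p - t))`, i.e. the image whose
#' content has been moved by `p -> A p + t`, using bilinear interpolation with
#' zero padding. Used to check the affine-trajectory hypothesis against
#' rendered trajectory maps of transformed sequences.
#'
#' @param img `W x H` matrix.
#' @param A 2x2 matrix, `t` length-2 translation (pixels).
#' @export
warp_affine <- function(img, A, t = c(0, 0)) {
  W <- nrow(img); H <- ncol(img)
  Ai <- solve(A)
  px <- matrix(rep(seq_len(W) - 1, H), W, H)
  py <- matrix(rep(seq_len(H) - 1, each = W), W, H)
  sx <- Ai[1, 1] * (px - t[1]) + Ai[1, 2] * (py - t[2])
  sy <- Ai[2, 1] * (px - t[1]) + Ai[2, 2] * (py - t[2])
  y <- bilinear_fwd_cpp(array(img, c(W, H, 1)),
                        matrix(sx, ncol = 1), matrix(sy, ncol = 1))
  matrix(y, W, H)
}

#' Normalized cross-correlation between two maps
#'
#' @param a,b numeric arrays of identical shape.
#' @return a scalar in `[-1, 1]` (0 if either map is constant).
#' @export
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# ---- batched internal path ---------------------------------------------------

# x: (W, H, T, M) stacked joint clips (possibly several samples' joints folded
# into M). Returns the per-joint descriptors after optional STN and 0-255
# normalization, plus caches for backprop.
vtdm_batch_forward <- function(x, params, stn = TRUE, training = FALSE,
                               normalize = TRUE) {
  d <- dim(x)
  if (length(d) == 5) d <- c(d[1], d[2], d[3], d[4] * d[5])
  W <- d[1]; H <- d[2]; M <- d[4]
  phi_layers <- list(
    nn_layer("conv", w = "phi.w", b = "phi.b", stride = 1L, pad = 1L,
             no_input_grad = TRUE),
    nn_layer("bn", gamma = "phi_bn.gamma", beta = "phi_bn.beta",
             rmean = "phi_bn.rmean", rvar = "phi_bn.rvar"),
    nn_layer("relu"))
  fw <- nn_forward(phi_layers, params, x, training)
  lam <- fw$y                              # (W, H, 1, M)
  params <- fw$params
  cache <- list(phi_layers = phi_layers, phi_caches = fw$caches, stn = stn,
                dims = d, normalize = normalize)

  if (stn) {
    lw <- nn_forward(loc_layers(), params, lam, training)
    theta <- lw$y                          # (4, M), rows th11, th12, th21, th22
    gx <- if (W > 1) seq(-1, 1, length.out = W) else 0
    gy <- if (H > 1) seq(-1, 1, length.out = H) else 0
    GM <- cbind(as.vector(matrix(gx, W, H)),
                as.vector(matrix(gy, W, H, byrow = TRUE)))  # (P, 2)
    px <- (GM %*% theta[1:2, , drop = FALSE] + 1) * ((W - 1) / 2)
    py <- (GM %*% theta[3:4, , drop = FALSE] + 1) * ((H - 1) / 2)
    lam3 <- lam; dim(lam3) <- c(W, H, M)
    out <- bilinear_fwd_cpp(lam3, px, py)  # (P, M)
    cache$loc_caches <- lw$caches
    cache$GM <- GM
    cache$px <- px; cache$py <- py
    cache$lam3 <- lam3
    cache$theta <- theta
    desc <- out
  } else {
    desc <- lam
    dim(desc) <- c(W * H, M)
  }

  if (normalize) {
    mm <- col_minmax_cpp(desc)
    scale <- ifelse(mm$max > mm$min, 255 / (mm$max - mm$min), 0)
    desc <- sweep(sweep(desc, 2, mm$min), 2, scale, `*`)
    cache$norm_scale <- scale
    cache$norm_jmin <- mm$jmin
    cache$norm_jmax <- mm$jmax
    cache$norm_y <- desc
  }
  dim(desc) <- c(W, H, 1, M)
  list(desc = desc, cache = cache, params = params)
}

vtdm_batch_backward <- function(params, cache, ddesc) {
  d <- cache$dims
  W <- d[1]; H <- d[2]; M <- d[4]
  dd <- ddesc
  dim(dd) <- c(W * H, M)
  if (cache$normalize) {
    # exact subgradient of y = 255 (x - min) / (max - min): the bulk term
    # plus the argmin/argmax contributions through min and max
    s <- cache$norm_scale
    sum_dy <- colSums(dd)
    sum_dyy <- colSums(dd * cache$norm_y)
    dmax <- -(s / 255) * sum_dyy
    dmin <- -s * sum_dy - dmax
    dd <- sweep(dd, 2, s, `*`)
    mi <- cbind(cache$norm_jmin, seq_len(M))
    ma <- cbind(cache$norm_jmax, seq_len(M))
    dd[mi] <- dd[mi] + dmin
    dd[ma] <- dd[ma] + dmax
  }
  grads <- list()
  if (cache$stn) {
    r <- bilinear_bwd_cpp(cache$lam3, cache$px, cache$py, dd)
    dlam <- r$dx
    dim(dlam) <- c(W, H, 1, M)
    # chain pixel-coordinate grads back to normalized coords, then to theta
    dtheta <- rbind(crossprod(cache$GM, r$dgx) * ((W - 1) / 2),
                    crossprod(cache$GM, r$dgy) * ((H - 1) / 2))
    lb <- nn_backward(loc_layers(), params, cache$loc_caches, dtheta)
    grads <- add_grads(grads, lb$grads)
    dlam <- dlam + lb$dx
  } else {
    dlam <- dd
    dim(dlam) <- c(W, H, 1, M)
  }
  pb <- nn_backward(cache$phi_layers, params, cache$phi_caches, dlam)
  grads <- add_grads(grads, pb$grads)
  list(dx = pb$dx, grads = grads)
}

#' Forward pass of the view-invariant descriptor stage for all joints
#'
#' Per joint: temporal-aggregation convolution, then (unless `stn = FALSE`)
#' localisation -> affine grid -> bilinear sampling, then 0-255 range
#' normalization; the J single-channel descriptors are stacked in joint order
#' into the `W x H x J` global descriptor. The convolution filter and the
#' localisation weights are shared across joints; `theta` is regressed per
#' joint. With the spatial transformer disabled each channel is simply the
#' normalized trajectory descriptor.
#'
#' @param clips `W x H x T x J` array (or list of J `W x H x T` clips).
#' @param weights parameter list (see [init_vtdm_params()]).
#' @param stn enable the spatial transformer stage.
#' @param normalize apply 0-255 normalization per channel.
#' @return `W x H x J` array.
#' @export
vtdm_forward <- function(clips, weights, stn = TRUE, normalize = TRUE) {
  if (is.list(clips)) {
    if (length(clips) != N_JOINTS)
      abort(sprintf("need %d joint clips, got %d", N_JOINTS, length(clips)),
            class = "trajscore_shape_error")
    clips <- array(unlist(clips), c(dim(clips[[1]]), length(clips)))
  }
  d <- dim(clips)
  if (length(d) != 4 || d[4] != N_JOINTS)
    abort("clips must be a W x H x T x 15 array", class = "trajscore_shape_error")
  r <- vtdm_batch_forward(clips, weights, stn = stn, training = FALSE,
                          normalize = normalize)
  out <- r$desc
  dim(out) <- c(d[1], d[2], N_JOINTS)
  out
}
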