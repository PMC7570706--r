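# Movement score module: an image classifier over the J-channel stack of
# view-normalized trajectory descriptors. The first convolution is
# re-channeled from 3 (RGB) to J joint channels and the final FC layer emits
# S+1 score classes. Three families: "tiny" (3 conv blocks + global pool +
# 2 FC, sized for CPU-scale experiments), and faithful adaptations of the
# standard VGG-19 and ResNeXt-50 (32x4d) architectures.

bn_params <- function(p, prefix, ch) {
  p[[paste0(prefix, ".gamma")]] <- rep(1, ch)
  p[[paste0(prefix, ".beta")]] <- rep(0, ch)
  p[[paste0(prefix, ".rmean")]] <- rep(0, ch)
  p[[paste0(prefix, ".rvar")]] <- rep(1, ch)
  p
}

bn_layer <- function(prefix) {
  nn_layer("bn", gamma = paste0(prefix, ".gamma"), beta = paste0(prefix, ".beta"),
           rmean = paste0(prefix, ".rmean"), rvar = paste0(prefix, ".rvar"))
}

# Three conv blocks (conv + batch norm + ReLU), global average pooling and a
# two-layer FC head. Batch norm in each block keeps the sparse bright-trace
# descriptors well conditioned: without it the constant zero background
# dominates the pooled features.
tiny_backbone <- function(J, S) {
  p <- list()
  p[["bb.c1.w"]] <- init_conv(3, 3, J, 16); p[["bb.c1.b"]] <- numeric(16)
  p[["bb.c2.w"]] <- init_conv(3, 3, 16, 32); p[["bb.c2.b"]] <- numeric(32)
  p[["bb.c3.w"]] <- init_conv(3, 3, 32, 32); p[["bb.c3.b"]] <- numeric(32)
  p <- bn_params(p, "bb.bn1", 16)
  p <- bn_params(p, "bb.bn2", 32)
  p <- bn_params(p, "bb.bn3", 32)
  p[["bb.f1.w"]] <- init_fc(32, 32); p[["bb.f1.b"]] <- numeric(32)
  p[["bb.f2.w"]] <- init_fc(S + 1, 32, gain = 1); p[["bb.f2.b"]] <- numeric(S + 1)
  layers <- list(
    nn_layer("scale", mul = 1 / 255, add = -0.5),
    nn_layer("conv", w = "bb.c1.w", b = "bb.c1.b", stride = 1L, pad = 1L),
    bn_layer("bb.bn1"),
    nn_layer("relu"),
    nn_layer("maxpool", k = 2L, stride = 2L, pad = 0L),
    nn_layer("conv", w = "bb.c2.w", b = "bb.c2.b", stride = 1L, pad = 1L),
    bn_layer("bb.bn2"),
    nn_layer("relu"),
    nn_layer("maxpool", k = 2L, stride = 2L, pad = 0L),
    nn_layer("conv", w = "bb.c3.w", b = "bb.c3.b", stride = 1L, pad = 1L),
    bn_layer("bb.bn3"),
    nn_layer("relu"),
    nn_layer("gap"),
    nn_layer("fc", w = "bb.f1.w", b = "bb.f1.b"),
    nn_layer("relu"),
    nn_layer("fc", w = "bb.f2.w", b = "bb.f2.b"))
  list(params = p, layers = layers)
}

# Standard VGG-19 convolutional configuration; "M" is a 2x2 maxpool.
VGG19_CFG <- list(64, 64, "M", 128, 128, "M", 256, 256, 256, 256, "M",
                  512, 512, 512, 512, "M", 512, 512, 512, 512, "M")

vgg19_backbone <- function(J, S) {
  p <- list()
  layers <- list(nn_layer("resize", size = c(224L, 224L)),
                 nn_layer("scale", mul = 1 / 255, add = -0.5))
  cin <- J
  ci <- 0
  for (v in VGG19_CFG) {
    if (identical(v, "M")) {
      layers <- c(layers, list(nn_layer("maxpool", k = 2L, stride = 2L, pad = 0L)))
    } else {
      ci <- ci + 1
      nm <- sprintf("bb.c%d", ci)
      p[[paste0(nm, ".w")]] <- init_conv(3, 3, cin, v)
      p[[paste0(nm, ".b")]] <- numeric(v)
      layers <- c(layers, list(
        nn_layer("conv", w = paste0(nm, ".w"), b = paste0(nm, ".b"),
                 stride = 1L, pad = 1L)))
      if (ci == 1) { # adapted first layer carries batch norm
        p <- bn_params(p, "bb.bn1", v)
        layers <- c(layers, list(bn_layer("bb.bn1")))
      }
      layers <- c(layers, list(nn_layer("relu")))
      cin <- v
    }
  }
  p[["bb.f1.w"]] <- init_fc(4096, 7 * 7 * 512); p[["bb.f1.b"]] <- numeric(4096)
  p[["bb.f2.w"]] <- init_fc(4096, 4096); p[["bb.f2.b"]] <- numeric(4096)
  p[["bb.f3.w"]] <- init_fc(S + 1, 4096, gain = 1); p[["bb.f3.b"]] <- numeric(S + 1)
  layers <- c(layers, list(
    nn_layer("flatten"),
    nn_layer("fc", w = "bb.f1.w", b = "bb.f1.b"), nn_layer("relu"),
    nn_layer("fc", w = "bb.f2.w", b = "bb.f2.b"), nn_layer("relu"),
    nn_layer("fc", w = "bb.f3.w", b = "bb.f3.b")))
  list(params = p, layers = layers)
}

resnext_block <- function(p, prefix, cin, width, cout, stride, groups = 32L) {
  conv <- function(nm, kw, ci, co, s, pad, grouped = FALSE) {
    ci_eff <- if (grouped) ci %/% groups else ci
    p[[paste0(nm, ".w")]] <<- init_conv(kw, kw, ci_eff, co)
    p[[paste0(nm, ".b")]] <<- numeric(co)
    if (grouped)
      nn_layer("groupconv", w = paste0(nm, ".w"), b = paste0(nm, ".b"),
               stride = s, pad = pad, groups = groups)
    else
      nn_layer("conv", w = paste0(nm, ".w"), b = paste0(nm, ".b"),
               stride = s, pad = pad)
  }
  main <- list()
  main[[1]] <- conv(paste0(prefix, ".c1"), 1L, cin, width, 1L, 0L)
  p <- bn_params(p, paste0(prefix, ".bn1"), width)
  main[[2]] <- bn_layer(paste0(prefix, ".bn1"))
  main[[3]] <- nn_layer("relu")
  main[[4]] <- conv(paste0(prefix, ".c2"), 3L, width, width, stride, 1L,
                    grouped = TRUE)
  p <- bn_params(p, paste0(prefix, ".bn2"), width)
  main[[5]] <- bn_layer(paste0(prefix, ".bn2"))
  main[[6]] <- nn_layer("relu")
  main[[7]] <- conv(paste0(prefix, ".c3"), 1L, width, cout, 1L, 0L)
  p <- bn_params(p, paste0(prefix, ".bn3"), cout)
  main[[8]] <- bn_layer(paste0(prefix, ".bn3"))
  shortcut <- list()
  if (cin != cout || stride != 1) {
    shortcut[[1]] <- conv(paste0(prefix, ".sc"), 1L, cin, cout, stride, 0L)
    p <- bn_params(p, paste0(prefix, ".scbn"), cout)
    shortcut[[2]] <- bn_layer(paste0(prefix, ".scbn"))
  }
  list(params = p, layer = nn_layer("resblock", main = main, shortcut = shortcut))
}

resnext50_backbone <- function(J, S) {
  p <- list()
  p[["bb.stem.w"]] <- init_conv(7, 7, J, 64); p[["bb.stem.b"]] <- numeric(64)
  p <- bn_params(p, "bb.stembn", 64)
  layers <- list(
    nn_layer("resize", size = c(224L, 224L)),
    nn_layer("scale", mul = 1 / 255, add = -0.5),
    nn_layer("conv", w = "bb.stem.w", b = "bb.stem.b", stride = 2L, pad = 3L),
    bn_layer("bb.stembn"),
    nn_layer("relu"),
    nn_layer("maxpool", k = 3L, stride = 2L, pad = 1L))
  blocks <- c(3, 4, 6, 3)
  widths <- c(128, 256, 512, 1024)
  couts <- c(256, 512, 1024, 2048)
  cin <- 64
  for (st in seq_len(4)) {
    for (b in seq_len(blocks[st])) {
      stride <- if (b == 1 && st > 1) 2L else 1L
      r <- resnext_block(p, sprintf("bb.s%db%d", st, b), cin, widths[st],
                         couts[st], stride)
      p <- r$params
      layers <- c(layers, list(r$layer))
      cin <- couts[st]
    }
  }
  p[["bb.fc.w"]] <- init_fc(S + 1, 2048, gain = 1); p[["bb.fc.b"]] <- numeric(S + 1)
  layers <- c(layers, list(nn_layer("gap"),
                           nn_layer("fc", w = "bb.fc.w", b = "bb.fc.b")))
  list(params = p, layers = layers)
}

#' Build a score-classification backbone adapted to joint-descriptor input
#'
#' Constructs the movement-score classifier: the standard architecture of the
#' chosen family with its first convolution re-channeled to `J` input channels
#' (3x3 for the VGG-19 adaptation, 7x7 followed by a 3x3 maxpool for the
#' ResNeXt-50 adaptation, per the adapted first-layer design) and its final FC
#' layer emitting `S + 1` score-class logits. Middle layers are unchanged from
#' the standard architectures. Weights are randomly initialised; optionally
#' the first layer can be seeded from standard 3-channel pretrained weights
#' via [init_first_layer()].
#'
#' @param family `"tiny"`, `"vgg19_adapted"` or `"resnext50_adapted"`.
#' @param J input channels (number of joints), default 15.
#' @param S maximum score; the classifier emits `S + 1` logits.
#' @param pretrained_source optional path to an RDS file holding a named list
#'   with the family's standard 3-channel first-layer kernel under `first.w`;
#'   it is tiled to `J` channels.
#' @param seed RNG seed for weight initialisation.
#' @return a `score_backbone` list with `params`, `layers`, `family`, `J`,
#'   `S`.
#' @export
adapt_backbone <- function(family = c("tiny", "vgg19_adapted", "resnext50_adapted"),
                           J = 15L, S = 4L, pretrained_source = NULL,
                           seed = 1L) {
  family <- match.arg(family)
  bb <- with_local_seed(seed, switch(family,
    tiny = tiny_backbone(J, S),
    vgg19_adapted = vgg19_backbone(J, S),
    resnext50_adapted = resnext50_backbone(J, S)))
  first_w <- switch(family, tiny = "bb.c1.w", vgg19_adapted = "bb.c1.w",
                    resnext50_adapted = "bb.stem.w")
  if (!is.null(pretrained_source)) {
    pre <- readRDS(pretrained_source)
    if (is.null(pre$first.w) || dim(pre$first.w)[3] != 3 ||
        !all(dim(pre$first.w)[c(1, 2, 4)] == dim(bb$params[[first_w]])[c(1, 2, 4)]))
      abort("pretrained weights incompatible with this family",
            class = "trajscore_checkpoint_error")
    bb$params[[first_w]] <- init_first_layer(pre$first.w, J)
  }
  structure(list(params = bb$params, layers = bb$layers, family = family,
                 J = as.integer(J), S = as.integer(S)),
            class = "score_backbone")
}

#' Re-channel pretrained first-layer weights from 3 to J input channels
#'
#' Repeats the 3 pretrained input-channel slices cyclically until `J` channels
#' are filled, then scales all weights by `3 / J`, so the layer's response to
#' a channel-constant input is preserved (exactly when `J` is a multiple of
#' 3).
#'
#' @param pretrained_w `k x k x 3 x C` kernel.
#' @param J target input channel count (>= 1).
#' @return a `k x k x J x C` kernel.
#' @export
init_first_layer <- function(pretrained_w, J) {
  if (J < 1) abort("J must be >= 1", class = "trajscore_invalid_argument")
  d <- dim(pretrained_w)
  if (length(d) != 4 || d[3] != 3)
    abort("pretrained kernel must be k x k x 3 x C", class = "trajscore_shape_error")
  idx <- ((seq_len(J) - 1) %% 3) + 1
  out <- pretrained_w[, , idx, , drop = FALSE] * (3 / J)
  dim(out) <- c(d[1], d[2], J, d[4])
  out
}

#' Classify a global descriptor into score logits
#'
#' Runs the backbone in evaluation mode (running batch-norm statistics, no
#' parameter updates) on one or more stacked descriptors.
#'
#' @param backbone a [adapt_backbone()] result (or a fitted model, whose
#'   backbone is used).
#' @param desc `W x H x J` descriptor or `W x H x J x N` batch.
#' @return numeric vector of `S + 1` logits (a `(S+1) x N` matrix for a
#'   batch).
#' @export
forward_score <- function(backbone, desc) {
  if (inherits(backbone, "traj_model")) {
    bb <- list(params = backbone$params, layers = backbone$bb_layers)
  } else bb <- backbone
  if (any(!is.finite(desc)))
    abort("descriptor contains non-finite values", class = "trajscore_invalid_data")
  single <- length(dim(desc)) == 3
  y <- nn_forward(bb$layers, bb$params, as_dim4(desc), training = FALSE)$y
  if (single) as.numeric(y) else y
}
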