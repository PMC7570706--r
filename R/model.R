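# End-to-end model: per-joint trajectory descriptors with affine view
# normalization, stacked and classified into S+1 integer score classes.

#' Construct an end-to-end movement-scoring model
#'
#' Combines the trajectory-descriptor stage (temporal-aggregation convolution
#' + spatial transformer, weights shared across joints) with a score
#' classification backbone. The model is trained end to end; disabling the
#' spatial transformer (`stn = FALSE`) keeps the temporal-aggregation
#' convolution and drops only the affine resampling — the ablation
#' configuration.
#'
#' @param S maximum movement-quality score; the classifier has `S + 1` output
#'   units.
#' @param backbone `"tiny"`, `"vgg19_adapted"` or `"resnext50_adapted"`.
#' @param J number of joints (input channels), default 15.
#' @param T_len clip length in frames, default 16.
#' @param input_size descriptor resolution (W = H), default 56.
#' @param stn enable the spatial transformer stage.
#' @param sigma heatmap Gaussian spread used when rendering clips.
#' @param seed weight-initialisation seed.
#' @return a `traj_model`.
#' @export
traj_model <- function(S, backbone = "tiny", J = N_JOINTS, T_len = 16L,
                       input_size = 56L, stn = TRUE, sigma = 2, seed = 1L) {
  bb <- adapt_backbone(backbone, J = J, S = S, seed = derive_seed(seed, 2))
  params <- c(with_local_seed(derive_seed(seed, 1),
                              init_vtdm_params(T_len, input_size)),
              bb$params)
  structure(list(
    params = params, bb_layers = bb$layers,
    config = list(S = as.integer(S), backbone = backbone, J = as.integer(J),
                  T_len = as.integer(T_len), input_size = as.integer(input_size),
                  stn = isTRUE(stn), sigma = sigma, seed = as.integer(seed))),
    class = "traj_model")
}

#' @export
print.traj_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<traj_model> backbone %s | J=%d, T=%d, %dx%d descriptors, S=%d (%d classes), STN %s\n",
    cfg$backbone, cfg$J, cfg$T_len, cfg$input_size, cfg$input_size, cfg$S,
    cfg$S + 1, if (cfg$stn) "on" else "off"))
  cat(sprintf("  %d parameter tensors (%s values)\n", length(x$params),
              format(sum(vapply(x$params, length, 1L)), big.mark = ",")))
  if (!is.null(x$loss_trace))
    cat(sprintf("  trained: %d steps, final loss %.4f\n",
                nrow(x$loss_trace), x$loss_trace$loss[nrow(x$loss_trace)]))
  invisible(x)
}

# clips: (W, H, T, J, N). Returns logits (S+1, N) plus caches.
model_forward <- function(model, clips, training = FALSE) {
  d <- dim(clips)
  vf <- vtdm_batch_forward(clips, model$params, stn = model$config$stn,
                           training = training)
  model$params <- vf$params
  desc <- vf$desc
  dim(desc) <- c(d[1], d[2], d[4], d[5])
  bf <- nn_forward(model$bb_layers, model$params, desc, training)
  model$params <- bf$params
  list(logits = bf$y, model = model,
       caches = list(vtdm = vf$cache, bb = bf$caches, dims = d))
}

model_backward <- function(model, caches, dlogits) {
  bb <- nn_backward(model$bb_layers, model$params, caches$bb, dlogits)
  d <- caches$dims
  ddesc <- bb$dx
  dim(ddesc) <- c(d[1], d[2], 1, d[4] * d[5])
  vb <- vtdm_batch_backward(model$params, caches$vtdm, ddesc)
  add_grads(bb$grads, vb$grads)
}

#' Cross-entropy loss for clip score classification
#'
#' `-log softmax(f)[s]` per clip, averaged over the batch.
#'
#' @param f logits: a length-`S+1` vector or an `(S+1) x N` matrix.
#' @param s integer ground-truth score(s), 0-based, in `0..S`.
#' @return scalar mean loss.
#' @export
cross_entropy <- function(f, s) {
  if (is.null(dim(f))) f <- matrix(f, ncol = 1)
  S <- nrow(f) - 1
  if (any(s < 0 | s > S))
    abort(sprintf("labels must be in 0..%d", S), class = "trajscore_label_error")
  if (length(s) == 1) s <- rep(s, ncol(f))
  fm <- sweep(f, 2, apply(f, 2, max))
  lse <- log(colSums(exp(fm)))
  mean(lse - fm[cbind(s + 1, seq_len(ncol(f)))])
}

# softmax - onehot, divided by batch size (gradient of the mean loss)
cross_entropy_grad <- function(f, s) {
  fm <- sweep(f, 2, apply(f, 2, max))
  p <- sweep(exp(fm), 2, colSums(exp(fm)), `/`)
  p[cbind(s + 1, seq_len(ncol(f)))] <- p[cbind(s + 1, seq_len(ncol(f)))] - 1
  p / ncol(f)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS archive of parameters, configuration and loss
#' trace, with a human-readable JSON sidecar (`<path>.json`) recording J, T,
#' W, H, S, backbone family, STN flag and seed.
#'
#' @param model a [traj_model()].
#' @param path checkpoint file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(
    list(J = cfg$J, T = cfg$T_len, W = cfg$input_size, H = cfg$input_size,
         S = cfg$S, backbone = cfg$backbone, stn_enabled = cfg$stn,
         seed = cfg$seed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    abort(paste("no checkpoint at", path), class = "trajscore_io_error")
  m <- readRDS(path)
  if (!inherits(m, "traj_model"))
    abort("file is not a model checkpoint", class = "trajscore_checkpoint_error")
  m
}

#' Tidy the training trace of a fitted model
#'
#' @param x a trained [traj_model()].
#' @param ... unused.
#' @return tibble with `step`, `epoch`, `loss`.
#' @export
tidy.traj_model <- function(x, ...) {
  if (is.null(x$loss_trace)) return(tibble::tibble(step = integer(),
                                                   epoch = integer(),
                                                   loss = numeric()))
  x$loss_trace
}

#' One-row model summary
#'
#' @param x a [traj_model()].
#' @param ... unused.
#' @export
glance.traj_model <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    backbone = cfg$backbone, J = cfg$J, T_len = cfg$T_len, S = cfg$S,
    stn = cfg$stn, n_params = sum(vapply(x$params, length, 1L)),
    trained = !is.null(x$loss_trace),
    final_loss = if (!is.null(x$loss_trace))
      x$loss_trace$loss[nrow(x$loss_trace)] else NA_real_)
}

#' Training-loss curve
#'
#' @param object a trained [traj_model()].
#' @param ... unused.
#' @export
autoplot.traj_model <- function(object, ...) {
  df <- tidy.traj_model(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::labs(x = "SGD step", y = "clip cross-entropy") +
    ggplot2::theme_minimal()
}
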