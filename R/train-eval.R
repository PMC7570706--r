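# Clip construction, SGD training, video-level scoring, Spearman evaluation,
# imbalance handling and the cross-subject / cross-view protocols.

#' Divide a video into non-overlapping fixed-length clips
#'
#' Frames are covered left to right by disjoint windows of `T_len` frames; a
#' trailing remainder shorter than `T_len` is discarded. Every clip carries
#' the video's score label.
#'
#' @param video_id identifier copied into the result.
#' @param n_frames length of the video (>= `T_len`).
#' @param score the video's score label.
#' @param T_len clip length, default 16.
#' @return tibble: `video_id`, `clip_index`, `frame_start`, `frame_end`
#'   (half-open, 0-based) and `score`.
#' @export
split_clips <- function(video_id, n_frames, score = 0L, T_len = 16L) {
  if (n_frames < T_len)
    abort(sprintf("video %s has %d frames; need at least %d", video_id,
                  n_frames, T_len),
          class = "trajscore_too_short")
  m <- n_frames %/% T_len
  tibble::tibble(video_id = video_id, clip_index = seq_len(m),
                 frame_start = (seq_len(m) - 1) * T_len,
                 frame_end = seq_len(m) * T_len, score = as.integer(score))
}

clip_pool <- function(manifest, T_len = 16L) {
  purrr::pmap_dfr(manifest[, c("video_id", "n_frames", "score")],
                  function(video_id, n_frames, score)
                    split_clips(video_id, n_frames, score, T_len))
}

#' Sample a training batch uniformly from the global clip pool
#'
#' Clips are drawn uniformly (with replacement) from all clips of all training
#' videos pooled together, so long videos contribute proportionally more
#' clips. Deterministic given the RNG state.
#'
#' @param pool clip tibble from [clip_pool()] / [split_clips()].
#' @param batch_size number of clips to draw.
#' @return the sampled rows of `pool`.
#' @export
sample_training_clips <- function(pool, batch_size) {
  if (nrow(pool) == 0)
    abort("empty clip pool", class = "trajscore_empty_dataset")
  pool[sample.int(nrow(pool), batch_size, replace = TRUE), ]
}

# Render the (W, H, T, J, N) heatmap tensor for a batch of clips in one C++
# call; numerically identical to stacking per-joint [stack_clip()] results.
render_batch <- function(sequences, batch, input_size, sigma, T_len) {
  N <- nrow(batch)
  cx <- array(0, c(T_len, N_JOINTS, N))
  cy <- cx; cf <- cx
  for (i in seq_len(N)) {
    sq <- sequences[[batch$video_id[i]]]
    frames <- (batch$frame_start[i] + 1):batch$frame_end[i]
    sxy <- input_size / sq$frame_size
    cx[, , i] <- sq$coords[frames, , 1] * sxy[1]
    cy[, , i] <- sq$coords[frames, , 2] * sxy[2]
    cf[, , i] <- sq$coords[frames, , 3]
  }
  render_clips_cpp(cx, cy, cf, input_size, input_size, sigma, 0.1)
}

#' Training configuration
#'
#' Defaults follow the study protocol: stochastic gradient descent with
#' initial learning rate 0.001, batch size 5, 20 epochs. Momentum (0.9) and
#' an optional step decay are conventional extras left configurable.
#'
#' @param lr initial learning rate.
#' @param batch_size clips per SGD step.
#' @param epochs passes over the clip pool.
#' @param momentum SGD momentum.
#' @param lr_decay optional multiplicative decay applied to the learning rate
#'   each epoch (`NULL` for a constant rate).
#' @param max_grad_norm global gradient-norm clip; gradients are rescaled when
#'   their joint norm exceeds it. The 0-255 range normalization can inject
#'   occasional very large gradients when a descriptor's dynamic range is
#'   small, and clipping keeps those spikes from derailing the transformer
#'   weights. `Inf` disables clipping.
#' @param loc_lr_scale multiplier on the learning rate of the localisation
#'   network (the standard spatial-transformer stabilisation): the regressed
#'   transform then drifts slowly from its identity initialisation instead of
#'   co-adapting into input-specific warps that do not generalize across
#'   views.
#' @param seed RNG seed for clip sampling.
#' @export
train_config <- function(lr = 0.001, batch_size = 5L, epochs = 20L,
                         momentum = 0.9, lr_decay = NULL, max_grad_norm = 5,
                         loc_lr_scale = 0.1, seed = 1L) {
  if (lr < 0 || batch_size < 1 || epochs < 1)
    abort("hyperparameters must be positive", class = "trajscore_invalid_argument")
  list(lr = lr, batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       momentum = momentum, lr_decay = lr_decay,
       max_grad_norm = max_grad_norm, loc_lr_scale = loc_lr_scale,
       seed = as.integer(seed))
}

#' Train a movement-scoring model
#'
#' End-to-end SGD on randomly sampled 16-frame clips: each step draws
#' `batch_size` clips from the pooled clips of all training videos, renders
#' their per-joint heatmap stacks, and minimises the clip-level cross-entropy.
#' One epoch is `ceiling(pool / batch_size)` steps. Fully reproducible given
#' `cfg$seed`.
#'
#' @param model a [traj_model()].
#' @param dataset list with `sequences` (named list of [pose_sequence()]) and
#'   `manifest` (tibble with `video_id`, `score`, `n_frames`).
#' @param cfg a [train_config()].
#' @return the trained model, with `$loss_trace` (tibble `step`, `epoch`,
#'   `loss`) and `$train_config` attached.
#' @export
train <- function(model, dataset, cfg = train_config()) {
  if (length(dataset$sequences) == 0)
    abort("empty training set", class = "trajscore_empty_dataset")
  if (max(dataset$manifest$score) > model$config$S)
    abort("dataset scores exceed the model's S", class = "trajscore_config_error")
  pool <- clip_pool(dataset$manifest, model$config$T_len)
  steps_per_epoch <- ceiling(nrow(pool) / cfg$batch_size)
  velocity <- list()
  trainable <- grep("\\.(rmean|rvar)$", names(model$params), value = TRUE,
                    invert = TRUE)
  losses <- numeric(0); epochs_rec <- integer(0)
  with_local_seed(cfg$seed, {
    lr <- cfg$lr
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      for (i in seq_len(steps_per_epoch)) {
        step <- step + 1L
        batch <- sample_training_clips(pool, cfg$batch_size)
        x <- render_batch(dataset$sequences, batch, model$config$input_size,
                          model$config$sigma, model$config$T_len)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        loss <- cross_entropy(fw$logits, batch$score)
        if (!is.finite(loss))
          abort(sprintf("training diverged (non-finite loss) at step %d", step),
                class = "trajscore_training_failure")
        losses[step] <- loss
        epochs_rec[step] <- ep
        if (lr > 0) {
          grads <- model_backward(model, fw$caches,
                                  cross_entropy_grad(fw$logits, batch$score))
          clip <- cfg$max_grad_norm %||% Inf
          if (is.finite(clip)) {
            gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
            if (gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
          }
          lsc <- cfg$loc_lr_scale %||% 1
          if (lsc != 1) {
            loc_nms <- grep("^loc\\.", names(grads), value = TRUE)
            for (nm in loc_nms) grads[[nm]] <- grads[[nm]] * lsc
          }
          upd <- sgd_step(model$params, grads, velocity, lr, cfg$momentum,
                          trainable)
          model$params <- upd$params
          velocity <- upd$velocity
        }
      }
      if (!is.null(cfg$lr_decay)) lr <- lr * cfg$lr_decay
    }
  })
  model$loss_trace <- tibble::tibble(step = seq_along(losses),
                                     epoch = epochs_rec, loss = losses)
  model$train_config <- cfg
  model$final_eval_loss <- pool_eval_loss(model, dataset, pool)
  model
}

# Evaluation-mode cross-entropy over a full clip pool; deterministic for a
# fixed checkpoint, so a reloaded model must reproduce it exactly.
pool_eval_loss <- function(model, dataset, pool = NULL, chunk = 25L) {
  pool <- pool %||% clip_pool(dataset$manifest, model$config$T_len)
  tot <- 0
  for (i in seq(1, nrow(pool), by = chunk)) {
    batch <- pool[i:min(nrow(pool), i + chunk - 1L), ]
    x <- render_batch(dataset$sequences, batch, model$config$input_size,
                      model$config$sigma, model$config$T_len)
    fw <- model_forward(model, x, training = FALSE)
    tot <- tot + cross_entropy(fw$logits, batch$score) * nrow(batch)
  }
  tot / nrow(pool)
}

#' Score a full video
#'
#' Splits the video into its non-overlapping 16-frame clips, classifies each,
#' averages the clip logits per class, and takes the arg-max class as the
#' video score (ties break toward the lower score). The alternative
#' aggregation `"max_clip_score"` takes the maximum of the per-clip arg-max
#' scores instead.
#'
#' @param model a trained [traj_model()].
#' @param seq a [pose_sequence()] of at least `T_len` frames.
#' @param aggregate `"mean_logits"` (default) or `"max_clip_score"`.
#' @return a list with `score`, `mean_logits` (length `S + 1`) and
#'   `clip_logits` (`(S+1) x M`).
#' @export
score_video <- function(model, seq, aggregate = c("mean_logits", "max_clip_score")) {
  aggregate <- match.arg(aggregate)
  clips <- split_clips("video", n_frames(seq), seq$meta$score,
                       model$config$T_len)
  if (nrow(clips) == 0)
    abort("video yields no clips", class = "trajscore_empty_video")
  x <- render_batch(stats::setNames(list(seq), "video"), clips,
                    model$config$input_size, model$config$sigma,
                    model$config$T_len)
  logits <- model_forward(model, x, training = FALSE)$logits
  c(aggregate_clip_logits(logits, aggregate), list(clip_logits = logits))
}

# Video score from an (S+1) x M matrix of clip logits: argmax of the
# class-wise mean (ties to the lowest score), or the maximum of per-clip
# argmax scores under the alternative rule.
aggregate_clip_logits <- function(logits, aggregate = "mean_logits") {
  mean_logits <- rowMeans(logits)
  score <- if (aggregate == "mean_logits") {
    which.max(mean_logits) - 1L       # which.max takes the first (lowest) tie
  } else {
    max(apply(logits, 2, which.max) - 1L)
  }
  list(score = as.integer(score), mean_logits = mean_logits)
}

#' Spearman rank correlation between predicted and true scores
#'
#' Rank correlation with average ranks for ties. A constant truth vector has
#' no rank ordering and is an error; constant predictions return 0 (a
#' degenerate predictor carries no rank information) with a warning.
#'
#' @param predicted,truth numeric vectors of equal length (>= 2).
#' @return a scalar in `[-1, 1]`.
#' @export
spearman_rho <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 2)
    abort("need two vectors of equal length >= 2",
          class = "trajscore_invalid_argument")
  if (stats::sd(truth) == 0)
    abort("rank correlation undefined: all true scores identical",
          class = "trajscore_undefined_correlation")
  if (stats::sd(predicted) == 0) {
    warning("constant predictions: returning rho = 0")
    return(0)
  }
  stats::cor(predicted, truth, method = "spearman")
}

#' Balance a dataset by normal-sequence subsampling and temporal cropping
#'
#' Normal (score 0) videos typically outnumber each abnormal score class, so
#' they are subsampled to `normal_count` videos (as in the emulated study: 15
#' for walk-type movements, 4 for the 13-class sit-stand scale). Minority
#' score classes are then augmented with random temporal crops — contiguous
#' subsequences of at least half the source video and at least `T_len` frames
#' — until every class count is within `max_ratio` of the largest.
#'
#' @param dataset list with `sequences` and `manifest`.
#' @param normal_count number of score-0 videos to retain per view.
#' @param max_ratio maximum allowed ratio between the largest and smallest
#'   per-score class counts.
#' @param T_len minimum crop length, default 16.
#' @param seed RNG seed.
#' @return a balanced dataset (same structure).
#' @export
balance_dataset <- function(dataset, normal_count = 15L, max_ratio = 1.5,
                            T_len = 16L, seed = 1L) {
  man <- dataset$manifest
  smax <- max(man$score)
  missing_scores <- setdiff(0:smax, unique(man$score))
  if (length(missing_scores))
    warning("score classes with zero sequences: ",
            paste(missing_scores, collapse = ", "))
  with_local_seed(seed, {
    keep <- man
    normals <- which(man$score == 0)
    if (length(normals) > normal_count) {
      drop <- setdiff(normals, sample(normals, normal_count))
      keep <- man[-drop, ]
    }
    seqs <- dataset$sequences[keep$video_id]
    counts <- table(factor(keep$score, levels = sort(unique(keep$score))))
    target <- ceiling(max(counts) / max_ratio)
    for (s in setdiff(as.integer(names(counts)), 0L)) {
      # normals stay at the subsampled count; cropping augments the
      # under-represented abnormal classes only
      need <- target - counts[[as.character(s)]]
      donors <- keep$video_id[keep$score == s]
      ci <- 0
      while (need > 0 && length(donors) > 0) {
        donor_id <- donors[(ci %% length(donors)) + 1]
        ci <- ci + 1
        src <- seqs[[donor_id]]
        nf <- n_frames(src)
        len <- max(T_len, ceiling(stats::runif(1, 0.5, 1) * nf))
        if (len >= nf) { if (ci > 10 * length(donors)) break else next }
        start <- sample.int(nf - len + 1, 1)
        cropped <- src
        cropped$coords <- src$coords[start:(start + len - 1), , , drop = FALSE]
        new_id <- sprintf("%s_crop%d", donor_id, ci)
        seqs[[new_id]] <- cropped
        keep <- dplyr::bind_rows(keep, dplyr::mutate(
          keep[keep$video_id == donor_id, ][1, ],
          video_id = new_id, n_frames = len))
        need <- need - 1
      }
    }
    list(sequences = seqs, manifest = keep)
  })
}

#' Build train/test splits for an evaluation protocol
#'
#' * `cross_subject_kfold`: subjects are partitioned into `k` folds (`k`
#'   defaults to the number of distinct scores), stratified so each test fold
#'   sees the full score range; train and test subject sets are disjoint and
#'   all views appear on both sides.
#' * `cross_view_single`: train on one camera view, test on all others (all
#'   subjects on both sides).
#' * `cross_view_pair`: train on a pair of views, test on the remaining
#'   views.
#' * `holdout`: a single subject-disjoint split with `test_fraction` of
#'   subjects held out.
#'
#' @param dataset list with a `manifest` tibble (`video_id`, `subject`,
#'   `view`, `score`).
#' @param protocol one of the four protocol names.
#' @param k number of folds (cross-subject); defaults to the number of
#'   distinct scores.
#' @param train_views view id (cross_view_single) or pair of view ids
#'   (cross_view_pair).
#' @param test_fraction held-out subject fraction for `holdout`.
#' @return a `split_plan`: list with `protocol`, `k` and `folds`, each fold a
#'   list of `train` and `test` video ids.
#' @export
make_splits <- function(dataset,
                        protocol = c("cross_subject_kfold", "cross_view_single",
                                     "cross_view_pair", "holdout"),
                        k = NULL, train_views = NULL, test_fraction = 0.3) {
  protocol <- match.arg(protocol)
  man <- dataset$manifest
  folds <- list()
  if (protocol == "cross_subject_kfold") {
    k <- k %||% length(unique(man$score))
    subjects <- sort(unique(man$subject))
    if (length(subjects) < k)
      abort(sprintf("%d subjects cannot form %d subject-disjoint folds",
                    length(subjects), k),
            class = "trajscore_split_error")
    assign_f <- rep(seq_len(k), length.out = length(subjects))
    for (f in seq_len(k)) {
      test_subj <- subjects[assign_f == f]
      folds[[f]] <- list(train = man$video_id[!man$subject %in% test_subj],
                         test = man$video_id[man$subject %in% test_subj])
    }
  } else if (protocol == "cross_view_single") {
    if (is.null(train_views) || length(train_views) != 1)
      abort("cross_view_single needs one training view",
            class = "trajscore_split_error")
    if (length(unique(man$view)) < 2)
      abort("cross-view protocols need at least two views",
            class = "trajscore_split_error")
    folds[[1]] <- list(train = man$video_id[man$view == train_views],
                       test = man$video_id[man$view != train_views])
  } else if (protocol == "cross_view_pair") {
    if (is.null(train_views) || length(train_views) != 2)
      abort("cross_view_pair needs two training views",
            class = "trajscore_split_error")
    folds[[1]] <- list(train = man$video_id[man$view %in% train_views],
                       test = man$video_id[!man$view %in% train_views])
  } else { # holdout
    subjects <- sort(unique(man$subject))
    n_test <- max(1, round(test_fraction * length(subjects)))
    test_subj <- subjects[seq_len(n_test)]
    folds[[1]] <- list(train = man$video_id[!man$subject %in% test_subj],
                       test = man$video_id[man$subject %in% test_subj])
  }
  for (f in seq_along(folds)) {
    ts <- man$score[man$video_id %in% folds[[f]]$test]
    if (length(unique(ts)) < 2)
      abort(sprintf("fold %d test set has fewer than 2 distinct scores", f),
            class = "trajscore_split_error")
    if (length(folds[[f]]$train) == 0)
      abort(sprintf("fold %d has an empty training set", f),
            class = "trajscore_split_error")
  }
  structure(list(protocol = protocol, k = length(folds), folds = folds),
            class = "split_plan")
}

#' Train and evaluate over the folds of a protocol
#'
#' For each fold a fresh model is initialised (seed = `base seed + fold`),
#' trained on the fold's training videos and used to score the test videos;
#' predicted and true scores are compared by Spearman rank correlation. A fold
#' whose training fails is recorded with `rho = NA` and the experiment
#' continues.
#'
#' @param dataset list with `sequences` and `manifest`.
#' @param plan a [make_splits()] result.
#' @param cfg a [train_config()].
#' @param stn enable the spatial transformer (the ablation toggles only this).
#' @param backbone backbone family, default `"tiny"`.
#' @param S maximum score; defaults to the dataset maximum.
#' @param input_size descriptor resolution.
#' @return an `experiment_report` tibble: `fold`, `protocol`, `stn_flag`,
#'   `n_test_videos`, `rho`, with a `predictions` attribute (tibble:
#'   `fold`, `video_id`, `true_score`, `predicted_score`).
#' @export
run_experiment <- function(dataset, plan, cfg = train_config(), stn = TRUE,
                           backbone = "tiny", S = NULL, input_size = 56L) {
  S <- S %||% max(dataset$manifest$score)
  rows <- list(); preds <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    tr <- list(sequences = dataset$sequences[fold$train],
               manifest = dataset$manifest[dataset$manifest$video_id %in% fold$train, ])
    rho <- NA_real_
    pred_rows <- NULL
    ok <- tryCatch({
      model <- traj_model(S, backbone = backbone, stn = stn,
                          input_size = input_size, seed = cfg$seed + f)
      model <- train(model, tr, cfg)
      pred_rows <- purrr::map_dfr(fold$test, function(vid) {
        sq <- dataset$sequences[[vid]]
        tibble::tibble(fold = f, video_id = vid, true_score = sq$meta$score,
                       predicted_score = score_video(model, sq)$score)
      })
      rho <- suppressWarnings(
        spearman_rho(pred_rows$predicted_score, pred_rows$true_score))
      TRUE
    }, trajscore_training_failure = function(e) {
      warning(sprintf("fold %d: %s", f, conditionMessage(e)))
      FALSE
    })
    n_test <- length(fold$test)
    rows[[f]] <- tibble::tibble(fold = f, protocol = plan$protocol,
                                stn_flag = stn, n_test_videos = n_test,
                                rho = rho)
    if (!is.null(pred_rows)) preds[[f]] <- pred_rows
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  class(out) <- c("experiment_report", class(out))
  out
}

#' @export
tidy.experiment_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(protocol = x$protocol[1], stn = x$stn_flag[1],
                 n_folds = nrow(x), mean_rho = mean(x$rho, na.rm = TRUE),
                 n_failed = sum(is.na(x$rho)))
}

#' Per-fold rank-correlation plot
#'
#' @param object an `experiment_report`.
#' @param ... unused.
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$rho,
                                   fill = .data$stn_flag)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "fold", y = "Spearman rho", fill = "STN") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
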