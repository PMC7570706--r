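# Clip splitting, loss, sampling, scoring, rank correlation, balancing,
# protocol splits, and the training loop contracts.

test_that("videos split into disjoint ordered 16-frame clips", {
  c35 <- split_clips("v", 35, score = 2)
  expect_equal(nrow(c35), 2)
  expect_equal(c35$frame_start, c(0, 16))
  expect_equal(c35$frame_end, c(16, 32))
  expect_true(all(c35$score == 2))

  expect_equal(nrow(split_clips("v", 16)), 1)

  c160 <- split_clips("v", 160)
  expect_equal(nrow(c160), 10)
  covered <- unlist(purrr::map2(c160$frame_start, c160$frame_end,
                                function(a, b) seq(a, b - 1)))
  expect_equal(sort(covered), 0:159)          # disjoint cover of [0, 160)
  expect_equal(anyDuplicated(covered), 0)

  expect_error(split_clips("v", 12), class = "trajscore_too_short")
})

test_that("cross-entropy matches closed forms", {
  expect_equal(cross_entropy(rep(0, 5), 2), log(5), tolerance = 1e-12)
  expect_lt(cross_entropy(c(0, 0, 20, 0, 0), 2), 1e-8)
  expect_equal(cross_entropy(c(1, 2, 3), 2),
               -log(exp(3) / (exp(1) + exp(2) + exp(3))), tolerance = 1e-10)
  expect_equal(cross_entropy(c(1, 2, 3), 2), 0.40761, tolerance = 1e-4)
  # batch loss is the mean of per-clip losses
  f <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2)
  expect_equal(cross_entropy(f, c(0, 2)),
               mean(c(log(3), cross_entropy(c(1, 2, 3), 2))), tolerance = 1e-10)
  expect_error(cross_entropy(rep(0, 5), 7), class = "trajscore_label_error")
})

test_that("clip sampling is uniform over the pooled clips", {
  pool <- split_clips("v", 160)
  set.seed(1)
  b <- sample_training_clips(pool, 5)
  expect_equal(nrow(b), 5)
  expect_true(all(b$clip_index %in% pool$clip_index))

  draws1 <- withr::with_seed(9, replicate(20, sample_training_clips(pool, 5)$clip_index))
  draws2 <- withr::with_seed(9, replicate(20, sample_training_clips(pool, 5)$clip_index))
  expect_identical(draws1, draws2)

  # 10k draws from a 4-clip pool: all frequencies within 3 sigma of uniform
  pool4 <- split_clips("v", 64)
  counts <- withr::with_seed(11, table(sample_training_clips(pool4, 10000)$clip_index))
  expect_true(all(abs(counts - 2500) < 3 * sqrt(10000 * 0.25 * 0.75)))

  expect_error(sample_training_clips(pool[0, ], 5),
               class = "trajscore_empty_dataset")
})

test_that("video scores aggregate clip logits by the mean-then-argmax rule", {
  agg <- trajscore:::aggregate_clip_logits
  expect_equal(agg(matrix(c(0.1, 0.9, 0.2), 3, 1))$score, 1L)
  # clips (2,0) and (0,1): means (1, 0.5) -> score 0
  expect_equal(agg(matrix(c(2, 0, 0, 1), 2, 2))$score, 0L)
  expect_equal(agg(matrix(c(2, 0, 0, 1), 2, 2))$mean_logits, c(1, 0.5))
  # exact tie breaks to the lower score
  expect_equal(agg(matrix(c(1, 1, 1, 1), 2, 2))$score, 0L)
  # prose-variant aggregation: maximum of per-clip argmax scores
  expect_equal(agg(matrix(c(2, 0, 0, 1), 2, 2), "max_clip_score")$score, 1L)
})

test_that("score_video stays within the score range and errors on short input", {
  ds <- make_walk_dataset(n_subjects = 1, score_max = 1, duration = 32, seed = 3)
  m <- traj_model(1, input_size = 28, seed = 3)
  for (sq in ds$sequences) {
    sv <- score_video(m, sq)
    expect_true(sv$score %in% 0:1)
    expect_length(sv$mean_logits, 2)
  }
  short <- simulate_skeleton(movement_spec("walk", 0, 1, duration = 16))
  short$coords <- short$coords[1:12, , , drop = FALSE]
  expect_error(score_video(m, short), class = "trajscore_too_short")
})

test_that("spearman correlation agrees with the rank oracle", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(5:1, 1:5), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 5), c(1, 2, 4, 3)),
               naive_spearman(c(1, 2, 3, 5), c(1, 2, 4, 3)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:100) {
    a <- sample(0:4, 12, replace = TRUE)
    b <- sample(0:4, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), naive_spearman(a, b), tolerance = 1e-9)
  }
  expect_error(spearman_rho(1:4, rep(2, 4)),
               class = "trajscore_undefined_correlation")
  expect_warning(r0 <- spearman_rho(rep(1, 4), 1:4), "constant")
  expect_equal(r0, 0)
})

test_that("balancing subsamples normals and augments by temporal cropping", {
  # 41 normals vs few abnormals, mirroring the imbalance of the emulated corpus
  seqs <- list(); rows <- list()
  for (i in 1:41) {
    sq <- simulate_skeleton(movement_spec("walk", 0, 2, duration = 100, seed = i))
    id <- sprintf("n%02d", i)
    seqs[[id]] <- sq
    rows[[length(rows) + 1]] <- tibble::tibble(
      video_id = id, subject = i, view = 1, action = "walk", score = 0,
      n_frames = 100)
  }
  for (s in 1:2) for (i in 1:4) {
    sq <- simulate_skeleton(movement_spec("walk", s, 2, duration = 100,
                                          seed = 100 + 10 * s + i))
    id <- sprintf("a%d_%d", s, i)
    seqs[[id]] <- sq
    rows[[length(rows) + 1]] <- tibble::tibble(
      video_id = id, subject = 40 + i, view = 1, action = "walk", score = s,
      n_frames = 100)
  }
  ds <- list(sequences = seqs, manifest = dplyr::bind_rows(rows))

  bal <- balance_dataset(ds, normal_count = 15, max_ratio = 1.5, seed = 2)
  counts <- table(bal$manifest$score)
  expect_equal(counts[["0"]], 15)
  # crops are contiguous subsequences of >= half the source and >= 16 frames
  crops <- bal$manifest[grepl("_crop", bal$manifest$video_id), ]
  expect_gt(nrow(crops), 0)
  expect_true(all(crops$n_frames >= 50 & crops$n_frames <= 100))
  # per-score counts within the configured ratio
  expect_lte(max(counts) / min(counts), 1.5)

  # an empty score class is reported, not fabricated
  keep <- ds$manifest$score != 1
  ds_missing <- list(sequences = ds$sequences[ds$manifest$video_id[keep]],
                     manifest = ds$manifest[keep, ])
  expect_warning(bal2 <- balance_dataset(ds_missing, 15, seed = 3),
                 "zero sequences")
  expect_false(1 %in% bal2$manifest$score)
})

test_that("protocol splits partition subjects and views as required", {
  ds <- generate_dataset(n_subjects = 10, views = default_camera_views(2),
                         action = "walk", score_max = 4, videos_per_score = 1,
                         duration = 32, seed = 13)

  plan <- make_splits(ds, "cross_subject_kfold")
  expect_equal(plan$k, 5)                       # k = number of distinct scores
  man <- ds$manifest
  all_test_subj <- integer()
  for (f in plan$folds) {
    tr_subj <- unique(man$subject[man$video_id %in% f$train])
    te_subj <- unique(man$subject[man$video_id %in% f$test])
    expect_length(intersect(tr_subj, te_subj), 0)
    expect_gte(length(unique(man$score[man$video_id %in% f$test])), 2)
    all_test_subj <- c(all_test_subj, te_subj)
  }
  expect_setequal(all_test_subj, 1:10)

  ds6 <- generate_dataset(n_subjects = 2, views = default_camera_views(5),
                          action = "walk", score_max = 2, videos_per_score = 1,
                          duration = 32, seed = 14)
  p1 <- make_splits(ds6, "cross_view_single", train_views = 2)
  tr_views <- unique(ds6$manifest$view[ds6$manifest$video_id %in% p1$folds[[1]]$train])
  te_views <- unique(ds6$manifest$view[ds6$manifest$video_id %in% p1$folds[[1]]$test])
  expect_equal(tr_views, 2)
  expect_setequal(te_views, c(1, 3, 4, 5))

  p2 <- make_splits(ds6, "cross_view_pair", train_views = c(2, 5))
  te2 <- unique(ds6$manifest$view[ds6$manifest$video_id %in% p2$folds[[1]]$test])
  expect_setequal(te2, c(1, 3, 4))

  ds1v <- make_walk_dataset(n_subjects = 2, n_views = 1, score_max = 2,
                            duration = 32, seed = 15)
  expect_error(make_splits(ds1v, "cross_view_single", train_views = 1),
               class = "trajscore_split_error")
})

test_that("training is reproducible and a zero learning rate is a no-op", {
  ds <- make_walk_dataset(n_subjects = 2, score_max = 1, duration = 32, seed = 5)
  m0 <- traj_model(1, input_size = 28, seed = 5)

  m_frozen <- train(m0, ds, train_config(lr = 0, epochs = 1, seed = 2))
  expect_identical(m_frozen$params[["phi.w"]], m0$params[["phi.w"]])
  expect_identical(m_frozen$params[["bb.f2.w"]], m0$params[["bb.f2.w"]])

  cfg <- train_config(epochs = 2, seed = 3)
  m1 <- train(m0, ds, cfg)
  m2 <- train(m0, ds, cfg)
  expect_equal(m1$loss_trace$loss[nrow(m1$loss_trace)],
               m2$loss_trace$loss[nrow(m2$loss_trace)], tolerance = 1e-6)
  expect_identical(m1$params[["bb.c1.w"]], m2$params[["bb.c1.w"]])
})

test_that("training reduces the loss on a small synthetic set", {
  ds <- make_walk_dataset(n_subjects = 6, score_max = 2, duration = 48, seed = 8)
  m <- traj_model(2, input_size = 28, seed = 8)
  m <- train(m, ds, train_config(epochs = 8, seed = 8))
  by_epoch <- tapply(m$loss_trace$loss, m$loss_trace$epoch, mean)
  expect_lt(by_epoch[length(by_epoch)], by_epoch[1])
})

test_that("run_experiment memorizes its training set and reports per fold", {
  ds <- make_walk_dataset(n_subjects = 4, score_max = 2, duration = 48, seed = 9)
  # single fold with test = train: an over-parameterized model must memorize
  plan <- structure(list(protocol = "holdout", k = 1,
                         folds = list(list(train = ds$manifest$video_id,
                                           test = ds$manifest$video_id))),
                    class = "split_plan")
  rep1 <- run_experiment(ds, plan, train_config(epochs = 40, seed = 4),
                         stn = TRUE, input_size = 28)
  expect_equal(nrow(rep1), 1)
  expect_gte(rep1$rho[1], 0.9)

  rep2 <- run_experiment(ds, plan, train_config(epochs = 40, seed = 4),
                         stn = TRUE, input_size = 28)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_equal(attr(rep1, "predictions"), attr(rep2, "predictions"))

  g <- glance(rep1)
  expect_equal(g$n_folds, 1)
  expect_equal(g$mean_rho, rep1$rho[1])
})
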