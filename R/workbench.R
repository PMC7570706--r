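# Workbench: YAML run configuration, dataset storage, and the simulate /
# train / evaluate / ablate commands that tie the simulator, the model and
# the protocols into reproducible runs. Every run directory receives a copy
# of the resolved configuration (including the seed), so a run can be
# reproduced from its outputs alone.

#' Read a run configuration
#'
#' Flat key-value YAML; `overrides` (e.g. parsed CLI flags) replace file
#' values key by key.
#'
#' @param path YAML file path, or `NULL` to start from an empty config.
#' @param overrides named list merged over the file contents.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

write_run_config <- function(cfg, dir) {
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
}

cfg_get <- function(cfg, key, default = NULL) cfg[[key]] %||% default

#' Write a simulated dataset to disk
#'
#' Per-video keypoint CSVs (`keypoints/<video_id>.csv`: frame, joint, x, y,
#' confidence) plus `manifest.csv` carrying the video metadata needed to
#' rebuild each sequence.
#'
#' @param dataset list with `sequences` and `manifest`.
#' @param dir output directory.
#' @return the manifest tibble (with `path` column), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  kdir <- file.path(dir, "keypoints")
  dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$frame_w <- vapply(dataset$sequences[man$video_id],
                        function(s) s$frame_size[1], 1L)
  man$frame_h <- vapply(dataset$sequences[man$video_id],
                        function(s) s$frame_size[2], 1L)
  man$score_max <- vapply(dataset$sequences[man$video_id],
                          function(s) s$meta$score_max, 1L)
  man$path <- file.path("keypoints", paste0(man$video_id, ".csv"))
  for (i in seq_len(nrow(man)))
    readr::write_csv(as_tibble(dataset$sequences[[man$video_id[i]]]),
                     file.path(dir, man$path[i]), progress = FALSE)
  readr::write_csv(man, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(man)
}

#' Load a dataset written by [write_dataset()] / [cmd_simulate()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list with `sequences` and `manifest`.
#' @export
load_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp))
    abort(paste("no manifest.csv under", dir), class = "trajscore_io_error")
  man <- readr::read_csv(mp, show_col_types = FALSE, progress = FALSE)
  seqs <- lapply(seq_len(nrow(man)), function(i) {
    df <- readr::read_csv(file.path(dir, man$path[i]), show_col_types = FALSE,
                          progress = FALSE)
    sequence_from_table(df, c(man$frame_w[i], man$frame_h[i]),
                        subject = man$subject[i], view = man$view[i],
                        action = man$action[i], score = man$score[i],
                        score_max = man$score_max[i])
  })
  names(seqs) <- man$video_id
  list(sequences = seqs,
       manifest = man[, c("video_id", "subject", "view", "action", "score",
                          "n_frames")])
}

resolve_views <- function(cfg) {
  n <- cfg_get(cfg, "n_views", 1L)
  default_camera_views(n)
}

#' Simulate a dataset from a run configuration
#'
#' Config keys (defaults in parentheses): `action` ("walk"), `score_max` (4),
#' `n_subjects` (4), `videos_per_score` (1), `n_views` (1), `duration_min`
#' (64), `duration_max` (96), `occlusion_mode` ("none"), `occlusion_joints`,
#' `occlusion_fraction` (0.25), `seed` (1), `out` (required).
#'
#' @param config a [read_run_config()] list (or plain named list).
#' @return the manifest tibble, invisibly.
#' @export
cmd_simulate <- function(config) {
  out <- cfg_get(config, "out")
  if (is.null(out)) abort("config needs `out`", class = "trajscore_io_error")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out))
    abort(paste("cannot create output directory", out),
          class = "trajscore_io_error")
  occ <- NULL
  if (cfg_get(config, "occlusion_mode", "none") != "none")
    occ <- occlusion_spec(config$occlusion_mode,
                          cfg_get(config, "occlusion_joints", 12L),
                          cfg_get(config, "occlusion_fraction", 0.25),
                          seed = cfg_get(config, "seed", 1L))
  ds <- generate_dataset(
    n_subjects = cfg_get(config, "n_subjects", 4L),
    views = resolve_views(config),
    action = cfg_get(config, "action", "walk"),
    score_max = cfg_get(config, "score_max", 4L),
    videos_per_score = cfg_get(config, "videos_per_score", 1L),
    duration = c(cfg_get(config, "duration_min", 64L),
                 cfg_get(config, "duration_max", 96L)),
    occlusion = occ,
    seed = cfg_get(config, "seed", 1L))
  man <- write_dataset(ds, out)
  write_run_config(config, out)
  invisible(man)
}

#' Train a model from a run configuration
#'
#' Config keys: `dataset` (dir from [cmd_simulate()]), `out`, `backbone`
#' ("tiny"), `stn` (TRUE), `S` (dataset max score), `train_views` (optional
#' view filter), `lr`, `batch_size`, `epochs`, `seed`. Writes
#' `checkpoint.rds` (+ JSON sidecar), `loss.csv`, `log.txt` and the config
#' copy.
#'
#' @param config run configuration.
#' @return the trained model, invisibly.
#' @export
cmd_train <- function(config) {
  out <- cfg_get(config, "out")
  ds_dir <- cfg_get(config, "dataset")
  if (is.null(out) || is.null(ds_dir))
    abort("config needs `dataset` and `out`", class = "trajscore_io_error")
  ds <- load_dataset(ds_dir)
  tv <- cfg_get(config, "train_views")
  if (!is.null(tv)) {
    keep <- ds$manifest$view %in% tv
    ds <- list(sequences = ds$sequences[ds$manifest$video_id[keep]],
               manifest = ds$manifest[keep, ])
  }
  S <- cfg_get(config, "S", max(ds$manifest$score))
  if (max(ds$manifest$score) > S)
    abort("manifest scores exceed configured S", class = "trajscore_config_error")
  cfg <- train_config(lr = cfg_get(config, "lr", 0.001),
                      batch_size = cfg_get(config, "batch_size", 5L),
                      epochs = cfg_get(config, "epochs", 20L),
                      seed = cfg_get(config, "seed", 1L))
  model <- traj_model(S, backbone = cfg_get(config, "backbone", "tiny"),
                      stn = cfg_get(config, "stn", TRUE),
                      seed = cfg_get(config, "seed", 1L))
  model <- train(model, ds, cfg)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(model, file.path(out, "checkpoint.rds"))
  readr::write_csv(model$loss_trace, file.path(out, "loss.csv"),
                   progress = FALSE)
  writeLines(c(sprintf("lr: %g", cfg$lr),
               sprintf("batch_size: %d", cfg$batch_size),
               sprintf("epochs: %d", cfg$epochs),
               sprintf("seed: %d", cfg$seed),
               sprintf("n_train_videos: %d", nrow(ds$manifest)),
               sprintf("final_loss: %.6f",
                       model$loss_trace$loss[nrow(model$loss_trace)])),
             file.path(out, "log.txt"))
  write_run_config(config, out)
  invisible(model)
}

#' Evaluate a checkpoint from a run configuration
#'
#' Config keys: `checkpoint`, `dataset`, `out`, `test_views` (optional view
#' filter). Writes `predictions.csv` (video_id, true_score, predicted_score,
#' per-class mean logits) and `report.csv` (fold, protocol, stn_flag,
#' n_test_videos, rho).
#'
#' @param config run configuration.
#' @return the report tibble, invisibly.
#' @export
cmd_evaluate <- function(config) {
  out <- cfg_get(config, "out")
  ckpt <- cfg_get(config, "checkpoint")
  if (is.null(out) || is.null(ckpt) || is.null(cfg_get(config, "dataset")))
    abort("config needs `checkpoint`, `dataset` and `out`",
          class = "trajscore_io_error")
  model <- load_checkpoint(ckpt)
  ds <- load_dataset(config$dataset)
  tv <- cfg_get(config, "test_views")
  if (!is.null(tv)) {
    keep <- ds$manifest$view %in% tv
    ds <- list(sequences = ds$sequences[ds$manifest$video_id[keep]],
               manifest = ds$manifest[keep, ])
  }
  preds <- purrr::map_dfr(ds$manifest$video_id, function(vid) {
    sv <- score_video(model, ds$sequences[[vid]])
    out_row <- tibble::tibble(video_id = vid,
                              true_score = ds$sequences[[vid]]$meta$score,
                              predicted_score = sv$score)
    lg <- tibble::as_tibble(as.list(stats::setNames(
      sv$mean_logits, paste0("mean_logit_", seq_along(sv$mean_logits) - 1))))
    dplyr::bind_cols(out_row, lg)
  })
  rho <- suppressWarnings(spearman_rho(preds$predicted_score, preds$true_score))
  report <- tibble::tibble(fold = 1L, protocol = "evaluate",
                           stn_flag = model$config$stn,
                           n_test_videos = nrow(preds), rho = rho)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(preds, file.path(out, "predictions.csv"), progress = FALSE)
  readr::write_csv(report, file.path(out, "report.csv"), progress = FALSE)
  write_run_config(config, out)
  invisible(report)
}

#' Run the spatial-transformer ablation back to back
#'
#' Trains and evaluates the configured protocol twice — with and without the
#' spatial transformer — on the same dataset, seeds and splits. Config keys:
#' `dataset`, `out`, `protocol` ("cross_view_single"), `train_views`,
#' `lr`/`batch_size`/`epochs`/`seed`, `backbone`.
#'
#' @param config run configuration.
#' @return combined report tibble, invisibly.
#' @export
cmd_ablate <- function(config) {
  out <- cfg_get(config, "out")
  if (is.null(out) || is.null(cfg_get(config, "dataset")))
    abort("config needs `dataset` and `out`", class = "trajscore_io_error")
  ds <- load_dataset(config$dataset)
  plan <- make_splits(ds, cfg_get(config, "protocol", "cross_view_single"),
                      train_views = cfg_get(config, "train_views", 1L))
  cfg <- train_config(lr = cfg_get(config, "lr", 0.001),
                      batch_size = cfg_get(config, "batch_size", 5L),
                      epochs = cfg_get(config, "epochs", 20L),
                      seed = cfg_get(config, "seed", 1L))
  bb <- cfg_get(config, "backbone", "tiny")
  rep_on <- run_experiment(ds, plan, cfg, stn = TRUE, backbone = bb)
  rep_off <- run_experiment(ds, plan, cfg, stn = FALSE, backbone = bb)
  report <- dplyr::bind_rows(tibble::as_tibble(rep_on),
                             tibble::as_tibble(rep_off))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report, file.path(out, "report.csv"), progress = FALSE)
  jsonlite::write_json(
    list(mean_rho_stn = mean(rep_on$rho, na.rm = TRUE),
         mean_rho_no_stn = mean(rep_off$rho, na.rm = TRUE)),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_run_config(config, out)
  invisible(report)
}
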