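#' @import tibble
#' @importFrom rlang abort .data
#' @importFrom dplyr arrange mutate filter group_by ungroup summarise select
#'   bind_rows n
NULL

# Number of joints retained from a 25-keypoint pose layout: head, neck,
# shoulders, elbows, wrists, mid-hip, hips, knees, ankles.
N_JOINTS <- 15L

#' Construct a scored 2D pose sequence
#'
#' A `pose_sequence` holds per-frame 2D pixel coordinates and detection
#' confidences for the 15 retained body joints of the 25-keypoint pose layout,
#' together with video-level metadata (subject, camera view, action, integer
#' movement-quality score). It is the common currency between the movement
#' simulator, the keypoint parsers, and the heatmap renderer.
#'
#' @param coords numeric array `c(n_frames, 15, 3)`; the last axis is
#'   `(x, y, confidence)`. Coordinates are 0-based pixels, pixel-center
#'   convention, x rightward, y downward.
#' @param frame_size integer `(W, H)` in pixels.
#' @param subject,view identifiers (integers or strings).
#' @param action action label, e.g. `"walk"` or `"sit_stand"`.
#' @param score integer movement-quality score, 0 = normal.
#' @param score_max maximum score `S` for this action type.
#' @return an object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, frame_size, subject = 1L, view = 1L,
                          action = "walk", score = 0L, score_max = 4L) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != N_JOINTS || dim(coords)[3] != 3)
    abort("`coords` must be an (n_frames x 15 x 3) array",
          class = "trajscore_invalid_argument")
  if (dim(coords)[1] < 1)
    abort("a pose sequence needs at least one frame",
          class = "trajscore_invalid_argument")
  if (score < 0 || score > score_max)
    abort(sprintf("score %d outside [0, %d]", score, score_max),
          class = "trajscore_invalid_argument")
  conf <- coords[, , 3, drop = FALSE]
  if (any(conf < 0 | conf > 1))
    abort("confidences must lie in [0, 1]", class = "trajscore_invalid_data")
  vis <- conf > 0
  xs <- coords[, , 1, drop = FALSE][vis]
  ys <- coords[, , 2, drop = FALSE][vis]
  if (length(xs) && (any(xs < 0 | xs >= frame_size[1]) ||
                     any(ys < 0 | ys >= frame_size[2])))
    abort("visible joint coordinates must lie inside the frame",
          class = "trajscore_invalid_data")
  structure(
    list(coords = coords, frame_size = as.integer(frame_size),
         meta = list(subject = subject, view = view, action = action,
                     score = as.integer(score), score_max = as.integer(score_max))),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<pose_sequence> %d frames, %dx%d px | subject %s, view %s, %s, score %d/%d\n",
    n_frames(x), x$frame_size[1], x$frame_size[2], m$subject, m$view,
    m$action, m$score, m$score_max))
  invisible(x)
}

#' @rdname pose_sequence
#' @param seq a `pose_sequence`.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Tidy a pose sequence into a keypoint table
#'
#' @param x a [pose_sequence()].
#' @param ... unused.
#' @return a tibble with columns `frame`, `joint`, `x`, `y`, `confidence`
#'   (frames and joints 1-based).
#' @export
as_tibble.pose_sequence <- function(x, ...) {
  nf <- n_frames(x)
  xs <- as.vector(x$coords[, , 1])
  ys <- as.vector(x$coords[, , 2])
  cf <- as.vector(x$coords[, , 3])
  tibble::tibble(
    frame = rep(seq_len(nf), times = N_JOINTS),
    joint = rep(seq_len(N_JOINTS), each = nf),
    x = xs, y = ys, confidence = cf
  ) |> dplyr::arrange(.data$frame, .data$joint)
}

#' Rebuild a pose sequence from a keypoint table
#'
#' Inverse of [as_tibble.pose_sequence()]: takes a `frame, joint, x, y,
#' confidence` table (one row per frame/joint) and the video metadata.
#'
#' @param df keypoint tibble.
#' @param frame_size `(W, H)` pixels.
#' @inheritParams pose_sequence
#' @export
sequence_from_table <- function(df, frame_size, subject = 1L, view = 1L,
                                action = "walk", score = 0L, score_max = 4L) {
  req <- c("frame", "joint", "x", "y", "confidence")
  if (!all(req %in% names(df)))
    abort(paste("keypoint table needs columns:", paste(req, collapse = ", ")),
          class = "trajscore_format_error")
  nf <- max(df$frame)
  coords <- array(0, c(nf, N_JOINTS, 3))
  idx <- cbind(df$frame, df$joint)
  coords[cbind(idx, 1)] <- df$x
  coords[cbind(idx, 2)] <- df$y
  coords[cbind(idx, 3)] <- df$confidence
  pose_sequence(coords, frame_size, subject, view, action, score, score_max)
}

#' Parse per-frame 25-keypoint records into a pose sequence
#'
#' Accepts the per-frame JSON layout written by common 2D pose estimators
#' (a `people` list whose entries carry a flat `pose_keypoints_2d` vector of
#' `x, y, confidence` triples). Only the first 15 keypoints are retained;
#' frames with no detected person yield 15 zero-confidence joints. Out-of-frame
#' coordinates of visible joints are clamped inside the frame.
#'
#' @param records either a character vector of JSON file paths (one per frame,
#'   in frame order) or a list of already-parsed per-frame records. A record
#'   may also be a bare numeric vector of at least 45 values (15 triples).
#' @param frame_size `(W, H)` pixels of the source video.
#' @inheritParams pose_sequence
#' @return a [pose_sequence()].
#' @export
parse_keypoint_frames <- function(records, frame_size, subject = 1L, view = 1L,
                                  action = "walk", score = 0L, score_max = 4L) {
  if (is.character(records))
    records <- lapply(records, jsonlite::read_json, simplifyVector = TRUE)
  nf <- length(records)
  if (nf < 1)
    abort("no frame records supplied", class = "trajscore_format_error")
  coords <- array(0, c(nf, N_JOINTS, 3))
  for (f in seq_len(nf)) {
    rec <- records[[f]]
    kp <- NULL
    if (is.numeric(rec)) {
      kp <- rec
    } else if (is.list(rec) && !is.null(rec$people)) {
      ppl <- rec$people
      if (is.data.frame(ppl)) {
        if (nrow(ppl) > 0) kp <- unlist(ppl$pose_keypoints_2d[1])
      } else if (length(ppl) > 0) {
        kp <- unlist(ppl[[1]]$pose_keypoints_2d)
      }
    } else {
      abort(sprintf("malformed keypoint record at frame %d", f),
            class = "trajscore_format_error")
    }
    if (is.null(kp)) next # empty person list: keep zero-confidence joints
    if (length(kp) < 3 * N_JOINTS)
      abort(sprintf("frame %d carries %d values; need at least %d (15 triples)",
                    f, length(kp), 3 * N_JOINTS),
            class = "trajscore_format_error")
    tri <- matrix(kp[seq_len(3 * N_JOINTS)], ncol = 3, byrow = TRUE)
    tri[, 1] <- pmin(pmax(tri[, 1], 0), frame_size[1] - 1e-9)
    tri[, 2] <- pmin(pmax(tri[, 2], 0), frame_size[2] - 1e-9)
    coords[f, , ] <- tri
  }
  pose_sequence(coords, frame_size, subject, view, action, score, score_max)
}

#' Write a pose sequence as per-frame keypoint JSON files
#'
#' One JSON file per frame in the 25-keypoint layout consumed by
#' [parse_keypoint_frames()] (the 10 discarded keypoints are written as zeros).
#'
#' @param seq a [pose_sequence()].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths in frame order.
#' @export
write_keypoint_frames <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- n_frames(seq)
  paths <- file.path(dir, sprintf("frame_%06d_keypoints.json", seq_len(nf)))
  for (f in seq_len(nf)) {
    tri <- t(seq$coords[f, , ])           # 3 x 15, flattens triple-wise
    kp <- c(as.vector(tri), rep(0, 3 * 10))
    jsonlite::write_json(
      list(version = 1.3,
           people = list(list(pose_keypoints_2d = kp))),
      paths[f], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
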