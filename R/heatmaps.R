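# Rendering per-joint pose-probability heatmaps and stacking them into the
# W x H x T clip tensors consumed by the trajectory-descriptor module.
# Heatmap matrices are indexed [x + 1, y + 1] (x rightward, y downward,
# 0-based pixel-center coordinates), matching the pose_sequence convention.

#' Render a Gaussian pose heatmap for one joint in one frame
#'
#' Produces `confidence * exp(-d^2 / (2 sigma^2))` at every pixel, where `d`
#' is the distance from the pixel center to the joint location. The Gaussian is
#' separable, so the map is computed as an outer product and is exact. A joint
#' whose confidence falls below `conf_threshold` is treated as missing
#' (occluded) and yields an all-zero map.
#'
#' @param center numeric `(x, y)` joint location in 0-based pixel coordinates.
#' @param confidence detection confidence in `[0, 1]`.
#' @param frame_size integer `(W, H)`, at least `(8, 8)`.
#' @param sigma Gaussian spread in pixels (> 0); default 2.
#' @param conf_threshold confidences strictly below this render as all-zero;
#'   default 0.1.
#' @return a `W x H` matrix, `m[x + 1, y + 1]`.
#' @export
render_joint_heatmap <- function(center, confidence, frame_size = c(56, 56),
                                 sigma = 2, conf_threshold = 0.1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    abort("`sigma` must be a positive number", class = "trajscore_invalid_argument")
  if (any(frame_size < 8))
    abort("`frame_size` must be at least (8, 8)", class = "trajscore_invalid_argument")
  W <- frame_size[1]; H <- frame_size[2]
  if (confidence < conf_threshold) return(matrix(0, W, H))
  gx <- exp(-((seq_len(W) - 1) - center[1])^2 / (2 * sigma^2))
  gy <- exp(-((seq_len(H) - 1) - center[2])^2 / (2 * sigma^2))
  confidence * outer(gx, gy)
}

#' Stack one joint's heatmaps over a clip
#'
#' Renders the given joint in each frame of `frame_range` and stacks the maps
#' into the `W x H x T` tensor that the temporal-aggregation convolution
#' consumes. Slice `t` equals [render_joint_heatmap()] of frame
#' `frame_range[t]`.
#'
#' @param seq a [pose_sequence()].
#' @param joint_id joint index in 1..15.
#' @param frame_range integer vector of frame indices (1-based), typically of
#'   length 16; must lie within the sequence.
#' @param sigma Gaussian spread in pixels.
#' @param frame_size heatmap resolution `(W, H)`; defaults to the sequence's
#'   frame size.
#' @return numeric array `c(W, H, T)` with attributes `joint_id`.
#' @export
stack_clip <- function(seq, joint_id, frame_range, sigma = 2,
                       frame_size = seq$frame_size) {
  if (joint_id < 1 || joint_id > N_JOINTS)
    abort("`joint_id` must be in 1..15", class = "trajscore_invalid_argument")
  if (any(frame_range < 1) || any(frame_range > n_frames(seq)))
    abort(sprintf("frame range [%d, %d] exceeds sequence of %d frames",
                  min(frame_range), max(frame_range), n_frames(seq)),
          class = "trajscore_out_of_range")
  sx <- frame_size[1] / seq$frame_size[1]
  sy <- frame_size[2] / seq$frame_size[2]
  Tn <- length(frame_range)
  out <- render_clips_cpp(
    array(seq$coords[frame_range, joint_id, 1] * sx, c(Tn, 1, 1)),
    array(seq$coords[frame_range, joint_id, 2] * sy, c(Tn, 1, 1)),
    array(seq$coords[frame_range, joint_id, 3], c(Tn, 1, 1)),
    frame_size[1], frame_size[2], sigma, 0.1)
  dim(out) <- c(frame_size[1], frame_size[2], Tn)
  attr(out, "joint_id") <- joint_id
  out
}

#' Rescale a map to the 0-255 image range
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 255, matching
#' the intensity range of the natural images that standard backbones were
#' trained on. An all-constant map (e.g. the all-zero descriptor of a fully
#' occluded joint) returns all zeros rather than dividing by zero.
#'
#' @param map a finite numeric matrix or array.
#' @return the rescaled map, same shape.
#' @export
normalize_to_image_range <- function(map) {
  if (any(!is.finite(map)))
    abort("map contains non-finite values", class = "trajscore_invalid_data")
  rng <- range(map)
  if (rng[2] - rng[1] == 0) return(map * 0)
  (map - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Whole-sequence trajectory heatmap of one joint
#'
#' Sums the per-frame Gaussian heatmaps of a joint over (a range of) the whole
#' sequence, tracing where the joint's probability mass travelled. Used for
#' visual checks of the affine-trajectory hypothesis: the trajectory map of a
#' viewed sequence should be an affine warp of the canonical one.
#'
#' @inheritParams stack_clip
#' @param frames frame indices to include; default all.
#' @param normalize rescale the result to 0-255 (default `TRUE`).
#' @return a `W x H` matrix.
#' @export
trajectory_heatmap <- function(seq, joint_id, sigma = 2,
                               frame_size = seq$frame_size,
                               frames = seq_len(n_frames(seq)),
                               normalize = TRUE) {
  clip <- stack_clip(seq, joint_id, frames, sigma, frame_size)
  m <- apply(clip, c(1, 2), sum)
  if (normalize) m <- normalize_to_image_range(m)
  m
}

#' Display a heatmap or descriptor map
#'
#' @param map a `W x H` matrix as returned by [render_joint_heatmap()] or
#'   [trajectory_heatmap()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_heatmap <- function(map, title = NULL) {
  df <- tibble::tibble(
    x = rep(seq_len(nrow(map)) - 1, times = ncol(map)),
    y = rep(seq_len(ncol(map)) - 1, each = nrow(map)),
    value = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, fill = "intensity") +
    ggplot2::theme_minimal()
}
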