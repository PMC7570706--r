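# Synthetic multi-view scored movement generator. Emulates the structure of a
# multi-camera rehabilitation-movement corpus: two action families (walk,
# sit-stand), integer quality scores 0..S where 0 is a normal execution,
# several camera views related by 2D affine transforms, and short-/long-term
# joint occlusion. Severity is a monotone kinematic proxy (tremor, asymmetry,
# slowed cadence, reduced stride, lean), not a clinical model.

# Joint order (1-based): 1 head, 2 neck, 3/6 shoulders, 4/7 elbows, 5/8 wrists,
# 9 mid-hip, 10/13 hips, 11/14 knees, 12/15 ankles (right then left per pair).
JOINT_NAMES <- c("head", "neck", "r_shoulder", "r_elbow", "r_wrist",
                 "l_shoulder", "l_elbow", "l_wrist", "mid_hip", "r_hip",
                 "r_knee", "r_ankle", "l_hip", "l_knee", "l_ankle")

# Run code under a private RNG stream, restoring the caller's stream after.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fold several small integers into one reproducible 31-bit seed.
derive_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 7919 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}

#' Specify one synthetic movement performance
#'
#' Kinematic severity parameters default to a monotone mapping of the relative
#' score `r = score / score_max`: tremor amplitude `2.5 r` px, left/right
#' asymmetry `0.5 r`, cadence `1.0 (1 - 0.4 r)` Hz, stride `12 (1 - 0.45 r)`
#' px, lean `10 r` degrees. A score of 0 therefore has zero tremor and zero
#' asymmetry by construction. Any parameter can be overridden.
#'
#' @param action `"walk"` or `"sit_stand"`.
#' @param score integer quality score, 0 (normal) .. `score_max`.
#' @param score_max maximum score `S` for the movement type (4, 5 or 12 in the
#'   emulated corpus).
#' @param duration number of frames (>= 16).
#' @param fps nominal frame rate used to interpret Hz parameters; default 30.
#' @param frame_size canvas `(W, H)` px.
#' @param stride,cadence,tremor_amp,tremor_freq,asymmetry,lean optional
#'   overrides (px, Hz, px, Hz, fraction in `[0,1]`, degrees).
#' @param seed integer controlling the performance's random phases/jitter.
#' @return a `movement_spec` list.
#' @export
movement_spec <- function(action = c("walk", "sit_stand"), score = 0L,
                          score_max = 4L, duration = 64L, fps = 30,
                          frame_size = c(56, 56), stride = NULL,
                          cadence = NULL, tremor_amp = NULL, tremor_freq = 5,
                          asymmetry = NULL, lean = NULL, seed = 1L) {
  action <- match.arg(action)
  if (score < 0 || score > score_max)
    abort("score outside [0, score_max]", class = "trajscore_invalid_argument")
  r <- score / score_max
  spec <- list(
    action = action, score = as.integer(score),
    score_max = as.integer(score_max),
    duration = as.integer(duration), fps = fps, frame_size = frame_size,
    stride = stride %||% 12 * (1 - 0.45 * r),
    cadence = cadence %||% 1.0 * (1 - 0.4 * r),
    tremor_amp = tremor_amp %||% 2.5 * r,
    tremor_freq = tremor_freq,
    asymmetry = asymmetry %||% 0.5 * r,
    lean = lean %||% 10 * r,
    seed = as.integer(seed))
  class(spec) <- "movement_spec"
  spec
}

# Standing and seated joint offsets relative to the mid-hip (x, y; y downward).
stand_pose <- function() {
  rbind(head = c(0, -18), neck = c(0, -14),
        r_shoulder = c(3, -13), r_elbow = c(4, -8), r_wrist = c(4.5, -3),
        l_shoulder = c(-3, -13), l_elbow = c(-4, -8), l_wrist = c(-4.5, -3),
        mid_hip = c(0, 0), r_hip = c(2, 0), r_knee = c(2, 7), r_ankle = c(2, 14),
        l_hip = c(-2, 0), l_knee = c(-2, 7), l_ankle = c(-2, 14))
}

sit_pose <- function() {
  rbind(head = c(3, -14), neck = c(2.5, -11),
        r_shoulder = c(5, -10), r_elbow = c(7, -6), r_wrist = c(8, -2),
        l_shoulder = c(0, -10), l_elbow = c(2, -6), l_wrist = c(3, -2),
        mid_hip = c(0, 0), r_hip = c(2, 0), r_knee = c(7, 3), r_ankle = c(6, 11),
        l_hip = c(-2, 0), l_knee = c(3, 3), l_ankle = c(2, 11))
}

#' Simulate a 15-joint articulated movement in the canonical view
#'
#' Walking is a smooth out-and-back horizontal root translation with sinusoidal
#' limb swing; sit-stand interpolates between seated and standing keyposes over
#' repeated rise-sit cycles. Severity perturbations (distal tremor jitter,
#' left/right amplitude asymmetry, slowed cadence, reduced stride/rise, trunk
#' lean) are scaled by `score / score_max`. Deterministic given `spec$seed`.
#'
#' @param spec a [movement_spec()].
#' @param subject optional per-subject kinematics: a list with `limb_scale`
#'   (multiplies all limb offsets), `phase` (radians added to the gait phase)
#'   and `y_offset` (px). Defaults to the neutral subject.
#' @return a [pose_sequence()] in the canonical view (view id 1), confidences
#'   all 1.
#' @export
simulate_skeleton <- function(spec, subject = NULL) {
  if (spec$duration < 16)
    abort("duration must be at least 16 frames", class = "trajscore_too_short")
  subject <- subject %||% list(limb_scale = 1, phase = 0, y_offset = 0, id = 1L)
  W <- spec$frame_size[1]; H <- spec$frame_size[2]
  nf <- spec$duration
  tt <- (seq_len(nf) - 1) / spec$fps
  r <- spec$score / spec$score_max

  with_local_seed(spec$seed, {
    # tremor phases per joint and axis, plus small per-frame jitter
    ph <- matrix(stats::runif(N_JOINTS * 2, 0, 2 * pi), N_JOINTS, 2)
    distal <- c(1, 0.4, 0.4, 0.7, 1, 0.4, 0.7, 1, 0.3, 0.3, 0.5, 0.7, 0.3, 0.5, 0.7)
    jitter <- array(stats::rnorm(nf * N_JOINTS * 2, sd = 0.25 * spec$tremor_amp),
                    c(nf, N_JOINTS, 2))

    base <- stand_pose() * subject$limb_scale
    coords <- array(0, c(nf, N_JOINTS, 3))
    phase <- 2 * pi * spec$cadence * tt + subject$phase
    cx <- (W - 1) / 2
    rooty <- 32 + subject$y_offset

    if (spec$action == "walk") {
      speed <- spec$stride * spec$cadence            # px/s average
      amp_w <- min(speed * (nf / spec$fps) / 4, 10)  # out-and-back excursion
      rootx <- cx + amp_w * sin(2 * pi * tt / (nf / spec$fps))
      swing <- 0.4 * spec$stride
      lift <- 1.5
      for (f in seq_len(nf)) {
        off <- base
        sR <- sin(phase[f]); sL <- sin(phase[f] + pi)
        aL <- 1 - spec$asymmetry
        off["r_knee", 1] <- off["r_knee", 1] + 0.5 * swing * sR
        off["r_ankle", 1] <- off["r_ankle", 1] + swing * sR
        off["r_ankle", 2] <- off["r_ankle", 2] - lift * pmax(0, sR)
        off["l_knee", 1] <- off["l_knee", 1] + 0.5 * swing * aL * sL
        off["l_ankle", 1] <- off["l_ankle", 1] + swing * aL * sL
        off["l_ankle", 2] <- off["l_ankle", 2] - lift * aL * pmax(0, sL)
        off["r_wrist", 1] <- off["r_wrist", 1] + 0.3 * spec$stride * sL
        off["l_wrist", 1] <- off["l_wrist", 1] + 0.3 * spec$stride * aL * sR
        coords[f, , 1] <- rootx[f] + off[, 1]
        coords[f, , 2] <- rooty + off[, 2]
      }
    } else { # sit_stand
      sitp <- sit_pose() * subject$limb_scale
      n_cycles <- max(1, round(spec$cadence * nf / spec$fps))
      # seatedness in [0, 1]: starts seated, rises and sits n_cycles times
      s_t <- (1 + cos(2 * pi * n_cycles * seq(0, 1, length.out = nf))) / 2
      rise_range <- 8 * (1 - 0.3 * r)
      for (f in seq_len(nf)) {
        s <- s_t[f]
        off <- (1 - s) * base + s * sitp
        aL <- 1 - 0.5 * spec$asymmetry
        off[c("l_knee", "l_ankle"), 1] <- off[c("l_knee", "l_ankle"), 1] * aL
        coords[f, , 1] <- cx + off[, 1]
        coords[f, , 2] <- (rooty - 4) + rise_range * s + off[, 2]
      }
    }

    # trunk lean about the mid-hip
    if (spec$lean != 0) {
      th <- spec$lean * pi / 180
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      for (f in seq_len(nf)) {
        root <- coords[f, 9, 1:2]
        rel <- sweep(coords[f, , 1:2], 2, root)
        coords[f, , 1:2] <- sweep(rel %*% t(Rm), 2, root, `+`)
      }
    }

    # distal tremor: sinusoid at tremor_freq plus gaussian jitter
    if (spec$tremor_amp > 0) {
      for (ax in 1:2) {
        tr <- outer(tt, rep(1, N_JOINTS))
        tr <- sin(2 * pi * spec$tremor_freq * tr +
                    matrix(ph[, ax], nf, N_JOINTS, byrow = TRUE))
        tr <- tr * matrix(distal, nf, N_JOINTS, byrow = TRUE) * spec$tremor_amp
        coords[, , ax] <- coords[, , ax] + tr + jitter[, , ax] *
          matrix(distal, nf, N_JOINTS, byrow = TRUE)
      }
    }

    coords[, , 1] <- pmin(pmax(coords[, , 1], 0), W - 1e-6)
    coords[, , 2] <- pmin(pmax(coords[, , 2], 0), H - 1e-6)
    coords[, , 3] <- 1
    pose_sequence(coords, spec$frame_size, subject = subject$id %||% 1L,
                  view = 1L, action = spec$action, score = spec$score,
                  score_max = spec$score_max)
  })
}

#' Specify a camera view as a 2D affine transform
#'
#' Views are modelled as in-plane rotation, anisotropic scale and shear — the
#' affine-trajectory hypothesis under which joint trajectories seen from
#' different cameras are affine transformations of each other.
#'
#' @param rotation degrees, positive counter-clockwise in image coordinates.
#' @param scale length-2 `(sx, sy)` or scalar.
#' @param shear horizontal shear coefficient.
#' @param translation `(tx, ty)` px added after the linear map.
#' @param view_id integer identifier.
#' @param A optionally, give the 2x2 matrix directly (overrides
#'   rotation/scale/shear).
#' @return a `view_spec` with components `A`, `t`, `view_id`.
#' @export
view_spec <- function(rotation = 0, scale = c(1, 1), shear = 0,
                      translation = c(0, 0), view_id = 1L, A = NULL) {
  if (is.null(A)) {
    th <- rotation * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    if (length(scale) == 1) scale <- rep(scale, 2)
    Sh <- matrix(c(1, 0, shear, 1), 2, 2)
    A <- R %*% diag(scale) %*% Sh
  }
  if (abs(det(A)) <= 0.05)
    abort("view transform is (near-)degenerate: |det A| <= 0.05",
          class = "trajscore_invalid_view")
  structure(list(A = A, t = as.numeric(translation), view_id = as.integer(view_id)),
            class = "view_spec")
}

#' A deterministic bank of synthetic camera placements
#'
#' Five fixed affine views spanning rotations in roughly \[-70, 55\] degrees
#' with mild anisotropic scaling and shear; view 1 is the canonical (identity)
#' view. Used as the default multi-camera rig of the simulator.
#'
#' @param n number of views (1..5).
#' @return a list of [view_spec()]s.
#' @export
default_camera_views <- function(n = 5) {
  all <- list(
    view_spec(0, c(1, 1), 0, view_id = 1L),
    view_spec(-35, c(0.9, 1.05), 0.05, view_id = 2L),
    view_spec(30, c(1.1, 0.95), -0.05, view_id = 3L),
    view_spec(-70, c(0.8, 1.0), 0.08, view_id = 4L),
    view_spec(55, c(1.0, 0.85), -0.08, view_id = 5L))
  all[seq_len(n)]
}

#' Draw a random affine view
#'
#' Rotation uniform in \[-90, 90\] degrees, per-axis scale uniform in
#' \[0.6, 1.4\], shear uniform in \[-0.2, 0.2\]. Uses the current RNG stream.
#'
#' @param view_id identifier for the drawn view.
#' @export
random_view_spec <- function(view_id = 1L) {
  view_spec(stats::runif(1, -90, 90), stats::runif(2, 0.6, 1.4),
            stats::runif(1, -0.2, 0.2), view_id = view_id)
}

#' Apply a camera view to a pose sequence
#'
#' Maps every joint coordinate `p` to `A p + t`, leaving confidences
#' unchanged. If the transformed content leaves the frame it is shifted back by
#' the minimal translation that fits (`recenter = "auto"`, the default); the
#' effective transform actually applied is recorded in the
#' `"view_transform"` attribute as `list(A, t)`.
#'
#' @param seq a [pose_sequence()].
#' @param view a [view_spec()].
#' @param recenter `"auto"` (shift minimally into frame) or `"none"` (error if
#'   out of frame).
#' @return the transformed [pose_sequence()] with the view's id in its
#'   metadata.
#' @export
apply_view <- function(seq, view, recenter = c("auto", "none")) {
  recenter <- match.arg(recenter)
  if (abs(det(view$A)) <= 0.05)
    abort("degenerate view transform", class = "trajscore_invalid_view")
  W <- seq$frame_size[1]; H <- seq$frame_size[2]
  nf <- n_frames(seq)
  pts <- matrix(aperm(seq$coords[, , 1:2, drop = FALSE], c(3, 1, 2)), nrow = 2)
  newp <- view$A %*% pts + view$t
  t_eff <- view$t
  if (recenter == "auto") {
    rx <- range(newp[1, ]); ry <- range(newp[2, ])
    if (diff(rx) > W - 1 || diff(ry) > H - 1)
      abort("transformed sequence does not fit the frame at any translation",
            class = "trajscore_invalid_view")
    shift <- c(max(0, -rx[1]) - max(0, rx[2] - (W - 1e-6)),
               max(0, -ry[1]) - max(0, ry[2] - (H - 1e-6)))
    newp <- newp + shift
    t_eff <- t_eff + shift
  }
  coords <- seq$coords
  coords[, , 1] <- matrix(newp[1, ], nf, N_JOINTS)
  coords[, , 2] <- matrix(newp[2, ], nf, N_JOINTS)
  m <- seq$meta
  out <- pose_sequence(coords, seq$frame_size, m$subject, view$view_id,
                       m$action, m$score, m$score_max)
  attr(out, "view_transform") <- list(A = view$A, t = t_eff)
  out
}

#' Specify joint occlusion
#'
#' @param mode `"none"`, `"short_term"` (one contiguous run of dropped frames)
#'   or `"long_term"` (the entire sequence).
#' @param joints affected joint indices (subset of 1..15).
#' @param fraction fraction of frames dropped in short-term mode, in `[0, 1]`.
#' @param seed controls where the short-term run starts.
#' @export
occlusion_spec <- function(mode = c("none", "short_term", "long_term"),
                           joints = integer(), fraction = 0.25, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "none" && length(joints) == 0)
    abort("occlusion needs a non-empty joint set", class = "trajscore_invalid_argument")
  if (any(joints < 1 | joints > N_JOINTS))
    abort("joints must be in 1..15", class = "trajscore_invalid_argument")
  if (fraction < 0 || fraction > 1)
    abort("fraction must be in [0, 1]", class = "trajscore_invalid_argument")
  structure(list(mode = mode, joints = as.integer(joints),
                 fraction = fraction, seed = as.integer(seed)),
            class = "occlusion_spec")
}

#' Occlude joints in a pose sequence
#'
#' Sets the affected joints' confidence to zero either for the whole sequence
#' (long-term, e.g. a body side never visible from a camera) or for one
#' contiguous run of `ceil(fraction * n_frames)` frames (short-term, a few
#' seconds of lost tracking). Deterministic given `occ$seed`.
#'
#' @param seq a [pose_sequence()].
#' @param occ an [occlusion_spec()].
#' @export
apply_occlusion <- function(seq, occ) {
  if (occ$mode == "none") return(seq)
  coords <- seq$coords
  nf <- n_frames(seq)
  if (occ$mode == "long_term") {
    coords[, occ$joints, 3] <- 0
  } else {
    nd <- ceiling(occ$fraction * nf)
    if (nd > 0) {
      start <- with_local_seed(occ$seed, sample.int(nf - nd + 1, 1))
      coords[start:(start + nd - 1), occ$joints, 3] <- 0
    }
  }
  m <- seq$meta
  pose_sequence(coords, seq$frame_size, m$subject, m$view, m$action,
                m$score, m$score_max)
}

#' Generate a multi-view scored movement dataset
#'
#' For every subject, score level and repetition, a canonical performance is
#' simulated with subject-specific kinematics (limb lengths with 10%
#' coefficient of variation, uniform gait phase) and rendered under every
#' requested camera view, so the same performance is observed from all views —
#' the structure cross-view protocols rely on.
#'
#' @param n_subjects number of subjects.
#' @param views list of [view_spec()]s; default [default_camera_views()].
#' @param action `"walk"` or `"sit_stand"`.
#' @param score_max maximum score `S`.
#' @param videos_per_score repetitions per (subject, score); scalar or vector
#'   of length `score_max + 1`.
#' @param duration frames per video; scalar, or a `(min, max)` range sampled
#'   per performance.
#' @param occlusion optional [occlusion_spec()] applied to every video (with a
#'   per-video derived seed).
#' @param frame_size canvas size.
#' @param seed master seed; the full dataset is reproducible from it.
#' @return a list with `sequences` (named list of [pose_sequence()]) and
#'   `manifest` (tibble: video_id, subject, view, action, score, n_frames).
#' @export
generate_dataset <- function(n_subjects = 4, views = default_camera_views(1),
                             action = "walk", score_max = 4L,
                             videos_per_score = 1L, duration = c(64L, 96L),
                             occlusion = NULL, frame_size = c(56, 56),
                             seed = 1L) {
  if (inherits(views, "view_spec")) views <- list(views)
  counts <- if (length(videos_per_score) == 1)
    rep(videos_per_score, score_max + 1) else videos_per_score
  if (length(counts) != score_max + 1)
    abort("videos_per_score must have length score_max + 1",
          class = "trajscore_config_error")
  if (any(counts < 1))
    abort("per-score counts must be >= 1", class = "trajscore_config_error")

  subjects <- with_local_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_subjects), function(i)
      list(id = i, limb_scale = max(0.7, stats::rnorm(1, 1, 0.1)),
           phase = stats::runif(1, 0, 2 * pi),
           y_offset = stats::rnorm(1, 0, 1)))
  })

  sequences <- list()
  rows <- list()
  for (si in seq_len(n_subjects)) {
    for (s in 0:score_max) {
      for (rep_i in seq_len(counts[s + 1])) {
        vseed <- derive_seed(seed, si, s, rep_i)
        dur <- if (length(duration) > 1 && duration[2] > duration[1])
          with_local_seed(vseed, {
            choices <- seq(duration[1], duration[2])
            choices[sample.int(length(choices), 1)]
          })
        else duration[1]
        spec <- movement_spec(action, s, score_max, duration = dur,
                              frame_size = frame_size, seed = vseed)
        canon <- simulate_skeleton(spec, subject = subjects[[si]])
        for (v in views) {
          sq <- apply_view(canon, v)
          if (!is.null(occlusion) && occlusion$mode != "none") {
            occ <- occlusion
            occ$seed <- derive_seed(vseed, v$view_id)
            sq <- apply_occlusion(sq, occ)
          }
          vid <- sprintf("S%02d_%s_s%02d_r%02d_v%d", si, action, s, rep_i,
                         v$view_id)
          sequences[[vid]] <- sq
          rows[[length(rows) + 1]] <- tibble::tibble(
            video_id = vid, subject = si, view = v$view_id, action = action,
            score = s, n_frames = dur)
        }
      }
    }
  }
  list(sequences = sequences, manifest = dplyr::bind_rows(rows))
}
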