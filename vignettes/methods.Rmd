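---
title: "View-invariant movement quality scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{View-invariant movement quality scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscore)
```

## The problem

Clinicians grade the quality of movements such as walking or sit-to-stand on
integer severity scales (0 = normal up to a movement-specific maximum S, with
S = 4, 5 or 12 for the movement families emulated here). Automating that
grading from ordinary video runs into a basic obstacle: appearance changes
drastically with the camera view, so a scorer trained on one viewpoint fails
on others. `trajscore` implements a two-stage architecture built on a simple
geometric observation: while appearance is view-dependent, the *2D
trajectories traced by body joints* over a short clip are, to a good
approximation, 2D affine transformations of each other across views. A
descriptor of joint trajectories that is normalized for affine distortion is
therefore usable from viewpoints never seen in training.

## The model

**Inputs.** Per-frame 2D pose evidence for the first 15 joints of the
25-keypoint body layout (head, neck, shoulders, elbows, wrists, mid-hip,
hips, knees, ankles), either as pose-probability heatmaps or as keypoint
coordinates from which Gaussian heatmaps are rendered
(`render_joint_heatmap()`, peak value = detection confidence). Videos are cut
into non-overlapping clips of T = 16 frames; per joint j the clip's heatmaps
are stacked into a W×H×T tensor (`stack_clip()`).

**Trajectory descriptor.** A single learned 3×3 convolution filter with T
input channels (stride 1, zero padding 1), followed by batch normalization
and ReLU, collapses the temporal stack into one W×H trajectory descriptor
map per joint — an image tracing where that joint's probability mass
travelled during the clip (`trajectory_descriptor()`). The filter is shared
across joints.

**Affine view normalization.** A spatial transformer makes the descriptor
view-invariant. A small localisation network — 10 conv filters 5×5 (1→10),
2×2 maxpool, ReLU, 10 filters 5×5 (10→10), 2×2 maxpool, ReLU, FC(32), ReLU,
FC(4) — regresses four parameters per joint, reshaped to a 2×2 matrix θ.
The sampling grid applies θ to the normalized pixel-center coordinates of the
output (in [−1, 1]², origin at the map center): there is deliberately *no*
translation column, so the transform covers rotation, scale and shear about
the map center only (`make_sampling_grid()`). The descriptor is resampled on
that grid by bilinear interpolation (`bilinear_sample()`); source points
outside the input contribute zero, matching the zero background of
trajectory maps. The 15 view-normalized maps, each rescaled to the 0–255
image range, are stacked into the W×H×15 global descriptor
(`vtdm_forward()`).

**Score classification.** The global descriptor is classified into S+1
integer score classes by an image backbone whose first convolution is
re-channeled from 3 (RGB) to 15 joint channels and whose final FC layer emits
S+1 logits (`adapt_backbone()`). Three families are provided: faithful
adaptations of VGG-19 (3×3 first layer with batch norm) and ResNeXt-50 32x4d
(7×7 stride-2 first layer + 3×3 maxpool), and a `tiny` family (three 3×3
conv blocks, global average pooling, two FC layers) sized so the whole
pipeline trains in minutes on one CPU core. When standard 3-channel
pretrained first-layer weights are available they are tiled cyclically to 15
channels and scaled by 3/15, preserving the response to channel-constant
input (`init_first_layer()`); by default all weights are randomly
initialised, since shipping or downloading pretrained weights is out of
scope.

**Training and scoring.** The network is trained end to end with SGD on
clip-level cross-entropy, drawing each batch uniformly from the pooled clips
of all training videos. A video's score is the arg-max over classes of the
clip-averaged logits (`score_video()`); agreement with ground truth is
summarized by Spearman rank correlation over test videos.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| W = H | 56 px | descriptor resolution; small enough for CPU training, large enough to resolve trajectory structure |
| T | 16 frames | clip length; ~0.5 s at 30 fps |
| σ | 2 px | Gaussian heatmap spread at 56×56 |
| confidence threshold | 0.1 | detections below it are treated as occluded (all-zero heatmap) |
| learning rate | 0.001 | SGD, constant (an optional per-epoch decay hook exists) |
| batch size | 5 clips | |
| epochs | 20 | one epoch = ⌈pool/batch⌉ steps |
| momentum | 0.9 | conventional SGD momentum; the protocol source specifies plain SGD with initial learning rate 0.001 and is silent on momentum |
| max_grad_norm | 5 | global gradient-norm clip (see numerical choices) |
| loc_lr_scale | 0.1 | learning-rate multiplier for the localisation network (see numerical choices) |

## The synthetic data generator

Real multi-view scored recordings cannot ship with a package, so
`generate_dataset()` emulates the *statistical structure* such a corpus
needs: two action families (walk: horizontal out-and-back root translation
with sinusoidal limb swing; sit-stand: interpolation between seated and
standing keyposes over repeated cycles); integer scores 0..S whose severity
enters through a monotone kinematic proxy — distal tremor (amplitude 2.5·s/S
px plus matched jitter), left/right asymmetry (0.5·s/S), slowed cadence
(×(1 − 0.4·s/S)), shortened stride (×(1 − 0.45·s/S)) and trunk lean
(10·s/S degrees); per-subject kinematics (limb lengths with 10% coefficient
of variation, uniform gait phase); multiple camera views realized as fixed
2D affine transforms (rotations −70°..55°, mild anisotropic scale and
shear) applied to the same canonical performance, so every performance is
observed from every view; and short-term (one contiguous dropped run) or
long-term (whole-sequence) joint occlusion. Everything is deterministic
given the master seed.

What the simulator does *not* model: perspective (views are exactly affine,
so the affine-trajectory hypothesis holds by construction rather than
approximately), pose-estimator noise correlated with image content,
camera-specific detection failure, and real Parkinsonian or post-stroke
biomechanics — the severity mapping is a monotone proxy, not a clinical
model (the clinical rubric distinguishing adjacent scores is not public).
Passing tests therefore demonstrate that the architecture, training loop and
protocols behave as designed under the stated geometry, not that the method
reaches any particular accuracy on real patients.

## Numerical and design choices

- **Grid convention.** Normalized coordinates in [−1, 1] with the origin at
  the map center and y pointing down; pixel centers at the interval
  endpoints, so the identity θ samples exact pixel centers and identity
  sampling is exact (tested to 1e−6). Because the 4-parameter transform has
  no translation, centering the grid at the map center is the only choice
  that makes rotation/scale/shear meaningful.
- **Localisation initialisation.** Final FC weights zero, bias (1, 0, 0, 1):
  the transformer starts as an exact no-op, which stabilises early training
  and makes the ablation (transformer off) exactly equal to the transformer
  at initialisation — a tested invariant.
- **Sharing across joints.** The localisation weights are shared across
  joints (one transformer applied per joint, θ regressed per joint); a
  per-joint alternative would multiply parameters 15-fold with no mechanism
  to see other joints anyway.
- **0–255 normalization placement.** The rescaling is applied per joint to
  the *view-normalized* descriptor just before channel stacking (a switch
  exists). Backpropagation through the min–max rescaling uses the exact
  subgradient, including the argmin/argmax terms; when the minimum sits on
  the zero background the extra term is absorbed by the upstream ReLU, so
  gradients match finite differences (tested).
- **Out-of-bounds sampling** contributes zero (neighbours outside the image
  are dropped), consistent with zero-background trajectory maps and still
  differentiable.
- **Batch norm** uses per-batch statistics in training and running averages
  (momentum 0.1) in evaluation; a bypass switch supports closed-form
  oracles.
- **Clip splitting** discards the trailing remainder shorter than 16 frames:
  non-overlapping fixed-length clips force either truncation or padding, and
  truncation avoids inventing frames.
- **Video-score aggregation.** The score is the arg-max of clip-averaged
  logits (pre-softmax outputs of the final FC layer, not probabilities),
  with ties broken toward the lower score (conservative severity, and
  deterministic). An alternative reading — the maximum of per-clip arg-max
  scores — is available via `aggregate = "max_clip_score"`; the averaged
  form is the default because it is the one stated as a formula rather than
  prose in the protocol this package follows.
- **Spearman ties** use average ranks. A constant truth vector is an error;
  constant *predictions* return ρ = 0 with a warning (a degenerate predictor
  carries no rank information).
- **Per-fold seeding.** Each fold of an experiment trains from a fresh
  initialisation with seed = base seed + fold index, so whole experiments
  are bit-reproducible.
- **Gradient clipping.** The per-map 0–255 rescaling multiplies incoming
  gradients by 255/(max − min); a descriptor with a small dynamic range can
  therefore inject a gradient spike large enough to throw the localisation
  weights far from useful transforms, after which training rarely recovers.
  Clipping the global gradient norm (default 5) suppresses exactly these
  spikes while leaving ordinary steps untouched.
- **Localisation learning rate.** The localisation network trains at 0.1x
  the main learning rate, the standard spatial-transformer stabilisation.
  Trained at full rate on a single camera view, the regressor happily learns
  input-specific warps that lower the training loss but act as a covert
  classification channel; those warps are meaningless on unseen views and
  destroy cross-view transfer. Slowing the regressor keeps the transform
  anchored to its identity initialisation while still allowing gradual view
  normalization.
- **Engine.** Convolution, pooling, bilinear sampling and backpropagation
  are implemented natively (C++/BLAS): stride-1 same-size convolutions are
  evaluated as sums of row-shifted GEMMs with scalar edge corrections, which
  is exactly equivalent to zero-padded convolution and keeps all heavy
  arithmetic in BLAS; every kernel is tested against brute-force oracles and
  finite differences.

## Problem sizes used by the tests and the acceptance script

The package's experiment-level checks run at desk scale, chosen so the whole
suite completes on one CPU core in well under half an hour: same-view
recovery trains on 50 walk videos (10 per score, S = 4, 64 frames each, one
view) and tests on 20 videos of four held-out subjects; the cross-view
ablation uses 5 subjects × 5 scores × 5 affine views (64-frame videos),
trains on view 1 and tests on the other four views, repeated over three
training seeds with and without the spatial transformer; the
affine-hypothesis check compares 20 random affine views of a walk's ankle
trajectory map against dense warps of the canonical map. At these sizes the
same-view rank correlation reaches ≈ 0.9 and warped-trajectory agreement
exceeds 0.9 normalized cross-correlation; the corresponding checks assert
ρ ≥ 0.8 and NCC ≥ 0.9.

## Known limitations

- The affine view model ignores perspective; strongly foreshortened real
  views will violate it more than the simulator does.
- Long-term occlusion zeroes a joint's channel entirely; the classifier can
  learn around it only if such occlusion also occurs in training.
- The tiny backbone's global average pooling discards descriptor layout
  except through local feature statistics; it is sized for testability, not
  accuracy — the adapted standard backbones are the intended production
  choice when pretrained weights are available.
- Scores are treated as classes; ordinal structure enters only through the
  rank-correlation evaluation, not the loss.
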