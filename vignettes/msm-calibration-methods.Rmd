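---
title: "Multi-scale projected markers for multi-camera extrinsic calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale projected markers for multi-camera extrinsic calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msmcalib)
```

## The calibration problem

A rig of cameras observes a common scene from very different positions and
zoom levels; the task is to recover each camera's pose (rotation and
translation, world-to-camera) given known intrinsics and lens distortion.
The defining difficulty of the surgical-scene setting is *limited
overlapping fields of view through scale*: a ceiling camera and a zoomed
close-up camera may see the same floor region at an apparent scale ratio
above 10, which defeats both natural-feature matching and fixed-size
fiducial boards (a board small enough for the zoomed view is invisible to
the far view, and vice versa).

The package's answer is the multi-scale marker (MSM): one floor location,
projected as the same square fiducial symbol at several scales `λ ∈ Λ`
about a common center `p`. Every projected instance is the image of the
base pattern under the planar scaling `s(x) = λ(x − p) + p`, which fixes
`p` exactly; since the marker center is extracted as the intersection of
the imaged diagonals — a projective invariant — all scales of one marker,
seen through any composition of the projector-to-floor and floor-to-image
homographies, yield the *same* image point. Each camera decodes whichever
scales its resolution allows, and the fused centers are exact multi-view
correspondences.

## Model and estimation pipeline

Writing `π(K, P, X)` for the full camera model (rigid transform, perspective
division, radial–tangential distortion `(k1, k2, p1, p2, k3)`, calibration
matrix), calibration minimizes the summed squared reprojection error over
all camera poses and marker centers, with `v_ck` indicating visibility.
Intrinsics are held fixed throughout; the pipeline undistorts observations
once at the start and works with an ideal pinhole model internally,
applying distortion only at the image interface.

The problem is solved incrementally:

1. **Initial pair.** Every camera pair sharing at least `min_shared = 50`
   correspondences is scored by the smaller of its two pair-restricted
   view scores (below); pairs are tried in descending order. Because all
   scene points lie on the floor, the essential matrix is degenerate; the
   relative motion comes instead from the inter-image homography, estimated
   by seeded RANSAC (adaptive iterations at 0.999 confidence, cap 10,000)
   and decomposed analytically into the up-to-four `{R, t/d, n}` solutions.
   The 3 px threshold is converted to normalized coordinates as
   `3 / sqrt(fx·fy)`, taking the more conservative camera; the inlier
   criterion is the one-sided transfer error in the second image (the
   symmetric variant costs a second homography application and changed
   nothing in trials). The provisional gauge is fixed by a unit baseline.
2. **Decomposition disambiguation.** Cheirality plus hard feasibility
   (every observed ray meets the candidate plane at positive depth; the
   second camera lies on the same side of the plane) reduces the four
   analytic solutions to at most two. The surviving twins of the classical
   plane ambiguity can *both* be physically valid — two views of a plane
   genuinely admit two rigid interpretations — so the tie is resolved by an
   upright-camera prior: for a roll-free camera above a floor the floor
   normal lies in the camera's y–z plane, hence the candidate with smaller
   `|n_x|` wins, then the normal best aligned with the mean observed ray,
   then the lower transfer error. This rule recovered the generating motion
   to below 1e-6 across far–far, near–near, far–near and varied-height
   two-view scenes (400 scenes × 4 seeds each); without the prior,
   cross-height pairs mis-selected the twin in a few percent of scenes.
3. **Incremental registration.** The unregistered camera with the highest
   view score on already-triangulated points is registered by robust PnP
   (planar-aware: minimal samples with singular-value ratio `d3/d1 < 0.05`
   use the homography-based pose, since the 6-point DLT is degenerate for
   the near-coplanar sets that noisy floor points form), followed by
   triangulation of newly observable tracks and an intermediate bundle
   adjustment over all registered cameras. A camera whose PnP fails is
   deferred, not fatal. New points must pass a 1° minimum triangulation
   angle, positive depths, and a 4 px reprojection gate; previously
   rejected tracks are re-attempted every third registration.
4. **Final refinement.** A full bundle adjustment, one robust outlier pass
   (observations beyond 4 MAD-based sigmas of the residual norm are
   dropped), and a concluding bundle adjustment, optionally with the
   coplanarity constraint.

**View score.** For levels `l = 1..6` the image is split into `2^l × 2^l`
cells; each occupied cell at level `l` adds `2^l`. The score grows with
both the number and the spatial spread of correspondences, which is what
makes a camera a reliable anchor. The exact weighting used by mainstream
SfM systems is not normative here; this multi-level occupancy form is the
package's documented choice, and only the induced *ordering* of cameras
matters to the pipeline.

## Bundle adjustment

The optimizer is Levenberg–Marquardt on the plain (unweighted) squared
reprojection error with analytic Jacobians, rotations updated by composing
axis-angle increments, and the structure parameters eliminated by the Schur
complement; the sparse normal equations are assembled with the `Matrix`
package. Three structure models share the engine:

* **free** — each point is a free 3-vector (the general pipeline);
* **plane** — each point is `(u, v)` in a floor plane parametrized by a
  3-dof frame (two tilts about in-plane axes and an offset), fitted by
  total least squares and refined jointly with the poses. The coplanarity
  constraint is thus *hard* — points cannot leave the plane — rather than a
  penalty, which keeps the normal-equation structure and needs no weight
  tuning;
* **board** — points are rigid boards of known local geometry; each board
  contributes one 6-dof pose block (the moving-board gold standard).

Gauge: the first registered camera is frozen; the scale, unobservable from
image measurements alone, is fixed by freezing one translation coordinate
(the largest) of the initial pair's second camera. The board-constrained
variant frees that coordinate again, because the known board size makes the
metric scale observable — freezing it at its initialization value
measurably biased the gold standard in trials (rotation RMSE roughly 5×
worse at 0.5 px noise). Convergence: relative objective decrease below
1e-10 (1e-8 for intermediate runs) or 200 (30) iterations; accepted steps
only ever decrease the objective. Degenerate blocks (a point losing its
second observation after the outlier pass) are dropped before assembly.

## The synthetic study

`run_experiment()` reproduces the package's validation design. Cameras sit
on two horizontal circles — six far-field at radius 2.8 m, height 2.8 m and
four near-field at radius 1.2 m, height 1.4 m, azimuths uniform, optical
axes through the scene center, no roll (world up maps to image up) — all
Full HD with a 915 px focal length, a typical action-camera value; an
11,100 px long-focal template is available for close-up views. Three point
distributions are compared at matched observation counts (means of ~2,000
per near and ~3,000 per far camera, enforced by uniform per-camera
subsampling):

* `board_volume` — 1.20 × 0.85 m boards carrying a 12 × 8 point grid,
  uniformly placed in a cylinder of radius 3 m and height 1.5 m with
  uniformly random orientation, resampled until the board fits the volume
  and at least two cameras face its front; calibrated with the
  board-constrained gold standard. 150 boards are generated so that the
  per-category targets are reachable for every sampled rig.
* `board_floor` — the same boards flat on the floor inside a 3 m disc
  (40 boards); gold-standard calibration.
* `grid_floor` — a regular 80 × 40 grid of 3,200 points over a 4 × 2 m
  floor rectangle, matching the density and footprint of the projected
  marker schedule; calibrated with the incremental pipeline, without the
  coplanarity constraint (the most general setting).

Observations get isotropic zero-mean Gaussian pixel noise; the swept
standard deviations default to `{0, 0.25, 0.5, 1}` px, a range bracketing
sub-pixel fiducial detection accuracy. Accuracy is reported as rotation and
translation RMSE over cameras after a Sim(3) (Umeyama) alignment of the
estimated camera centers to ground truth — orientation errors are geodesic
angles after applying the fitted rotation, in degrees. Per-repeat seeds
derive deterministically from the master seed.

What the simulator deliberately does *not* model: lens distortion residuals
(intrinsics are treated as exact), non-planar floors, detection failures or
decode errors (the rendered-fixture path covers those), exposure and blur,
and correlated noise. Passing the synthetic suite therefore demonstrates
the estimator's correctness and conditioning, not robustness to a
mis-calibrated camera model.

## Rendering, detection and the fixture

The package defines its own square fiducial family ("msq6"): an 8 × 8 cell
grid whose outer ring is bright and whose inner 6 × 6 payload carries a
12-bit symbol id plus a 24-bit checksum. Projected markers are
high-contrast, so no error correction is used; the checksum rejects
corrupted reads and resolves the four-fold rotation ambiguity. Frames are
rasterized with 4 × 4 sub-pixel supersampling; detection segments bright
connected components, fits the four quad edges to the 50%-intensity
crossings along edge normals (total-least-squares line fits with one
reweighting pass) and intersects them, giving centers accurate to a few
hundredths of a pixel at marker sides above ~25 px. Scale fusion takes the
coordinate-wise median of per-scale centers with MAD-based rejection at 3.5
robust sigmas and a 2 px absolute gate; frames of the same (array, scale)
slot are averaged first. No temporal synchronization is needed — the
projections are static, and the decoded symbol id alone associates a
detection with its schedule slot.

`make_fixture()` builds the end-to-end test bed: a reduced schedule
(9 arrays × 8 MSMs, scales {1, 2.8, 8}, 2 cm base side on a 2.4 × 1.35 m
projector footprint) seen by four wide cameras (915 px focal, ~3.8 m away)
and one 8,000 px long-focal camera. The wide cameras decode only the λ = 8
instances (~40 px) while the close-up camera decodes the smallest — the
exact scale gap the markers exist to bridge — and the shared centers still
calibrate the five cameras to below 0.1° rotation RMSE. The
projector-to-floor homography is a scale-and-center map with a flipped Y
axis: any downward projector's pixel-to-floor map is orientation-reversing,
and the flip is what makes the projected symbols right-reading for cameras
above the floor.

## Numerical choices and degenerate inputs

* Homographies are stored at unit Frobenius norm with a positive last
  element; estimation uses Hartley-normalized DLT.
* RANSAC minimal samples are rejected if any three points are collinear;
  the adaptive iteration formula guards the `log(1 − w^k)` underflow when
  early hypotheses have near-zero support.
* Triangulation is linear (SVD) plus Gauss–Newton refinement in the pixel
  domain; coincident camera centers raise an ill-conditioned error, and
  negative depths raise cheirality failures rather than returning points.
* Undistortion inverts the lens model by Newton iteration to 1e-12.
* Problem sizes in the shipped tests (rigs of 4–10 cameras, hundreds to
  3,200 points, 10–20 simulation repeats per condition) were chosen as the
  smallest that exercise every code path and keep the statistical
  assertions stable under their fixed seeds.

## Known limitations

Two views of a plane cannot always be disambiguated from the data alone;
the upright-camera prior covers rigs whose cameras are roughly roll-free,
which the projection protocol assumes anyway. The detector expects
high-contrast markers on a dark background and straight marker edges
(strong lens distortion would bend them; on the real-data path detection
runs on raw frames and only the fused centers are undistorted, which is
exact for point features). Metric scale is not recoverable from projected
markers alone — results are defined up to a similarity unless a known
length (e.g., a board) is present, which is precisely why accuracy is
evaluated after Sim(3) alignment.
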