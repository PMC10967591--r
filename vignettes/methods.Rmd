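---
title: "Measuring animal locomotion speed from tracked video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring animal locomotion speed from tracked video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockmotion)
```

## The measurement problem

An overhead camera watching a floor pen foreshortens the scene: a bird
crossing the far end of the pen moves fewer pixels per metre than one
under the lens. Any speed estimate computed directly from pixel
displacement is therefore biased by position. `flockmotion` removes that
bias with a planar projective rectification and then treats speed
estimation, and the evaluation of the trackers that feed it, as a single
reproducible pipeline.

The package assumes the animals move on a plane (the pen floor), that the
camera is fixed, and that lens distortion is negligible relative to the
matching gates and speed windows in use. It does not model 3-D posture,
flight, or multi-camera fusion.

## Rectification and the pixel scale

A homography between the image and the floor plane is determined exactly
by four point correspondences in general position; in practice these are
the corners of a rectangle of known physical size (a marked calibration
board, a feeder mat, the pen itself). `fit_homography()` solves the
direct linear transform on Hartley-normalized coordinates (each point set
translated to its centroid and scaled to RMS distance √2) and takes the
null vector of the 8×9 design matrix by SVD. Normalization matters: with
raw pixel coordinates in the thousands, the design matrix mixes scales of
1 and 10⁶ and the recovered matrix loses 4–6 digits of accuracy. The
result is normalized so the bottom-right entry is exactly 1, and three
nearly collinear points (cross product below 10⁻⁹ of the squared point
spread) are rejected as a degenerate calibration rather than solved
through.

The top-down raster is sized so the reference rectangle of physical width
`w` metres spans `p` pixels (default `p` = 1000), fixing the scale
`W = w/p` metres per pixel. All speed output is linear in `W`, so an
error in the measured rectangle propagates proportionally — the largest
practical error source, and one no software check can catch.

Conventions, fixed once: pixel coordinates are 0-based with the origin at
the top-left and v increasing downward; the world origin sits at the
rectangle corner listed first, with corners in cyclic order.

## Speed from frame windows

For one track in the top-down view, speed over the window `[N, M]` is

$$V = \frac{\Delta Y \cdot W}{(M-N)\,\Delta t}, \qquad \Delta t = 1/\mathrm{fps},$$

with `ΔY` the displacement in top-down pixels. Defaults: 18 FPS (so
Δt = 55.56 ms) and an 18-frame window — displacement is measured over one
second, long enough that centroid jitter of a pixel or two stays small
against genuine walking displacement, short enough to resolve bouts of
activity. The window length is the main smoothing parameter: shorter
windows amplify jitter (the error in `V` scales as `W·σ√2/(window·Δt)`),
longer ones average over speed changes.

Two displacement modes exist. The default uses the vertical component
only, `ΔY = |y_M − y_N|`, matching rigs where the rectification is
constructed so vertical shifts track distance travelled; it is a lower
bound on planar speed and underestimates oblique motion (a bird walking
at 45° reads ≈29% slow, and a cohort of random headings reads low on
average — visible in the worked example). The Euclidean mode
`√(Δx² + Δy²)` removes that bias and is preferred whenever the full
planar calibration is trusted. Displacement is taken as an absolute
value: the output is speed, not signed velocity.

Two degenerate cases are decided conservatively. Tracks shorter than
`window + 1` detections yield an empty series with a warning. Windows
containing a missed detection are skipped entirely rather than
interpolated: interpolation would fabricate displacement for precisely
the frames in which the tracker was blind, and the skipped windows are
visible in the output (missing `N` values) for audit.

## Evaluation protocol

The matching rule follows CLEAR-MOT. Per frame, ground-truth and
predicted detections are paired by minimum-cost bipartite assignment
(Hungarian method, via `clue::solve_LSAP`) on centroid Euclidean
distance, gated at a threshold defaulting to 10% of the frame height. An
established ground-truth/prediction pairing is kept while it remains
within the gate — the memory survives frames where either party is
absent — and only unpaired detections enter the assignment, which
maximizes the number of in-gate matches first and minimizes total
distance second (the padding constant is sized `n·gate + 1` so
cardinality strictly dominates). Unmatched ground truth is a miss,
unmatched predictions are false positives, and a matched ground-truth
object whose paired identity differs from its previous pairing is charged
one identity switch at that frame. MOTA then follows its formula; it can
be negative when errors outnumber ground-truth detections.

Identity metrics are computed at trajectory level: the number of in-gate
frames is tallied for every (ground-truth identity, predicted identity)
pair, a one-to-one mapping maximizing total in-gate frames is chosen by
the same assignment solver, and IDTP is the total under that mapping,
giving IDP = IDTP/№pred, IDR = IDTP/№gt, and IDF1 as their harmonic mean
(defined as 0 when both are 0; two empty track sets score 1 with a
warning, there being no evidence of error).

Boundary decisions: the IoU of two empty masks is 0 with a warning —
agreement about nothing is not evidence of segmentation quality — and
classes present in neither prediction nor ground truth are excluded from
the mIoU mean rather than contributing either 0 or 1. Throughput FPS is
reported but never asserted against, being hardware-dependent.

The test suite verifies the whole protocol against an independent
reference evaluator that shares no code with the package: assignments are
solved by exhaustive dynamic programming over column subsets, and the
scenarios are kept to ≤6 tracks so the enumeration is exact.

## What the simulator emulates — and what it does not

The generator produces a flock of 1–20 birds in a rectangular arena
(default 4 m × 3 m) observed at 18 FPS in a 1440 × 1080 frame. Each bird
follows a correlated random walk: heading evolves as
`θ' = θ + (1−κ)·η` with `η ~ N(0, turn_sd²)` (κ = 0.8, turn_sd = 0.5 rad
by default — persistent but meandering paths), and speed follows a
mean-reverting walk around 0.05 m/s (reversion 0.05/frame, innovation
s.d. 0.01 m/s) clipped to 0.00–0.21 m/s, the range a slow-walking
domestic fowl cohort actually occupies. Walls reflect. Each bird draws
from its own seeded RNG substream (offset `seed + 10007·bird`), so
enlarging the flock never perturbs existing trajectories — a property the
determinism tests rely on.

Observation noise mimics tracker failure modes, not image formation:
isotropic centroid jitter, per-detection misses, Poisson false positives
under fresh identities, and momentary identity swaps between the two
nearest birds. Swaps are momentary (one frame) rather than persistent:
they model occlusion-induced confusion from which a tracker recovers, and
they make the noise presets' effect on the identity metrics scale with
the swap *rate* — a single persistent early swap would dominate IDF1
regardless of how rare swaps are. Two presets bracket an easy and a hard
condition, named for the marking experiment they emulate: birds dyed
with high-contrast colour are tracked with less jitter and fewer identity
errors than unmarked, visually similar birds. The magnitudes
("dyed": σ = 1 px, miss 0.02, false positives 0.02/frame, swap 0.001;
"undyed": σ = 2 px, miss 0.05, false positives 0.05/frame, swap 0.005)
are package choices that reproduce the qualitative ordering between the
conditions; they are not measurements, and the printed scores of any real
tracker are not reproduction targets.

Passing the simulator-based suites therefore shows that the geometry,
speed and metric machinery is correct and well-conditioned; it does not
show that any particular tracker reaches any particular score on real
video. Real data add lens distortion, non-planar birds (pecking,
perching), lighting change and correlated occlusions, none of which the
noise model represents.

## Validation problem sizes

The shipped suites run: noiseless speed recovery with 5 birds × 90
frames through an oblique camera (exact to 10⁻⁶ m/s, observed ≈10⁻¹⁵);
1000 random homography fits recovered to 10⁻⁸; 100 random tracking
scenarios (2–5 tracks, 25–50 frames) matched exactly against the
independent evaluator; and a 2000-frame, 8-bird run on which the "dyed"
preset scores strictly higher MOTA and IDF1 and strictly lower speed RMSE
than "undyed". `scripts/acceptance.R` recomputes these quantities from
scratch at any seed. These sizes were chosen as the smallest at which the
stochastic properties are stable across seeds.

## Known limitations

- Planar motion only; heights above the calibrated plane bias positions
  outward from the principal point.
- Vertical-only speed is a lower bound; use the Euclidean mode unless
  replicating a vertical-rig analysis.
- The label-PNG mask format carries at most 255 identities.
- The matching gate is a single global distance; no per-animal or
  IoU-adaptive gating.
- Simulator kinematics are stationary: no diurnal activity cycles,
  social attraction, or wall-following behaviour.
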