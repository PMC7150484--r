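---
title: "Morphological contour tracking and focus planning for HIFU guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological contour tracking and focus planning for HIFU guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifutrack)
```

## The problem

High-intensity focused ultrasound (HIFU) ablates uterine fibroids by
depositing acoustic energy at a movable focal point. During treatment the
only live image is B-mode ultrasound: noisy, speckled, and showing a
lesion that drifts with breathing, deforms with tissue pressure, and
occasionally leaps when the patient moves. A guidance system must

1. keep a closed contour locked on the lesion in real time,
2. notice large unexpected movement and pause sonication, and
3. convert the tracked contour into a grid of sonication foci.

`hifutrack` implements this pipeline with a morphological active contour
(no PDE integration, only binary morphology), an image-similarity movement
monitor, and a geometric focus planner, together with a speckle phantom
generator that provides ground truth for every stage.

## Contour model

The contour is the boundary of the 1-region of a binary embedding
$u : \mathbb{Z}^2 \to \{0, 1\}$ (the level set $1/2$). Each incoming
frame triggers `iters_per_frame` iterations of three morphological steps,
the unit-parameter regime of the region-competition (Chan–Vese) model
($\mu = \nu = \lambda_1 = \lambda_2 = 1$):

1. **Balloon**: one binary dilation of $u$ by a $3\times3$ cross
   ($\nu = +1$; an erosion for $\nu = -1$). A uniform inflation term that
   keeps the contour from stalling on flat intensity plateaus.
2. **Attachment**: with $c_1, c_2$ the mean intensities inside and
   outside the contour, every contour pixel is set by the sign of
   $\lambda_1 (I - c_1)^2 - \lambda_2 (I - c_2)^2$ — negative joins the
   inside, positive the outside, an exact tie changes nothing. The
   contour pixels are those with nonzero central-difference gradient of
   the **pre-balloon** embedding. This detail matters: if the sign test
   only saw the dilated mask's own boundary, it could undo the new layer
   but never reach the original boundary one pixel further in, so the
   contour could inflate but never retreat, and the model would stall at
   the union of initialization and target.
3. **Smoothing**: `mu` repetitions of the compound sup-inf/inf-sup
   operator $SI \circ IS$ over a set of discrete line segments
   (`operator_set`), approximating mean-curvature motion at the scale of
   the segment.

Region means use an $\varepsilon = 10^{-8}$ regularized denominator so
they stay defined (and flagged) when a region empties.

### Structuring segments and the minimum feature scale

The classical operator set $\mathcal{K}_3$ uses four 3-pixel segments at
0°, 45°, 90° and 135°. Its short support makes the contour follow every
fine structure — including speckle dimples and the bright internal
sub-structures of fibroids, which clinicians deliberately ignore: the
treatment target is the outer contour. The package's default,
$\mathcal{K}_{15}$, lengthens the segments to fifteen pixels. Because the
sup-inf extrema are taken over segments *centred* at each pixel, a pixel
survives smoothing only if a full segment fits inside the region around
it; boundary features smaller than about half the segment length
(≈ 7 px) are therefore erased. Two consequences drive the package's
study conditions:

* structures to be *kept* (the lesion) must be several times larger than
  the segment — lesions much below ~30 px across are progressively
  shaved away by repeated smoothing;
* structures to be *ignored* (internal blobs, narrow notches,
  filaments) are bridged or removed when narrower than the segment.

We implement $\mathcal{K}_{15}$ as four 15-pixel segments (same
orientations as $\mathcal{K}_3$) for rotation robustness; the literal
single-segment reading is available as
`k15(single_orientation = ...)`.

All morphology in the package — smoothing, balloon, the preprocessing
opening/closing — shares one border policy: structuring elements are
clipped at the image border and out-of-grid pixels are ignored (no padded
value). Border behaviour is then governed by the overflow guard, not by
an arbitrary padding convention.

## Frame preprocessing

Ultrasound speckle has spatial structure, so frames are denoised with a
grayscale morphological opening followed by closing over a disk
(`kappa_radius`, default 2 px), which removes bright and dark granules
smaller than the disk while preserving edges. Contrast is then stretched
with an affine window map: the window defaults to
$[m - k s,\ m + k s]$ with $m, s$ the mean and standard deviation of the
denoised frame inside the initial contour and $k$ = `roi_stat_k`
(default 2). This keeps the lesion mid-gray, saturates the brighter
background toward 1, and clips the anechoic bladder-like distractor to 0
— "removing" it without any explicit region operation.

`track_lesion()` resolves the window **once**, on the first frame, and
holds it fixed for the whole run. The echogenicity classes of a scene do
not change over a sequence, and a stationary mapping keeps frames
comparable for the movement monitor; a window recomputed per frame from
the tracked region couples the preprocessing to tracking errors and
degrades badly once the contour is displaced (the ROI then measures
background statistics).

## Incomplete lesions and the overflow guard

When the lesion is cut by the edge of the field of view — common under
tissue deformation, and emulated by the `"truncated"` phantom preset with
its black out-of-fan band — the region statistics degrade and the
inflating contour can overflow into whatever dark content neighbours the
truncation. The guard measures, at each iteration, the fraction $f$ of
contour pixels whose attachment force points outward. If $f$ exceeds
`overflow_tau` (default 0.5, "most") *and* the candidate contour touches
the image border, only non-growing changes are accepted (the candidate is
intersected with the previous embedding). Whether the gate should apply
only at borders or globally is genuinely open; we default to the border
scope — a global gate would also clamp legitimate growth during normal
tracking, where the inward contour pixels alone already push $f$ near
0.5 — and expose `overflow_scope = "global"` for the other reading.

## Movement monitoring

Every `cadence` frames (default 10) the monitor compares the current
preprocessed frame with a reference by joint-histogram mutual
information. The first checkpoint after tracking start establishes the
baseline; an alarm fires when MI drops below `mi_threshold` (default 0.6)
times that baseline. Two estimator choices deserve note:

* **Bins.** The histogram MI estimator has a positive finite-sample bias
  of roughly $(B-1)^2 / (2N)$ nats for $B$ bins and $N$ pixels. At 64
  bins on a $128^2$ frame that bias (~0.12 nats) is comparable to the
  structural MI of a small lesion, compressing the alarm margin; the
  default is therefore `bins = 32`.
* **Reference refresh.** The reference is the last *stable* checkpoint
  frame, not frame 0, so slow drift — which tracking absorbs — never
  accumulates into a false alarm. When an alarm fires, the reference
  refreshes to the current (post-movement) frame: the scene has changed
  for good, and "stable" must mean *stable again*, not *back to the old
  scene*. One stable checkpoint clears the alarm
  (`stable_checkpoints_required`, configurable).

On alarm, normalized cross-correlation matches the stored template (the
initial-contour bounding box, cut from the tracking-start frame) in a
Chebyshev annulus of displacements `search_range` (default 0–30 px,
chosen as a generous bound on inter-checkpoint lesion displacement).
The matching runs on the *denoised but unwindowed* frames: the contrast
window saturates the background and stretches the lesion interior across
the full range, leaving almost no correlatable intensity topography,
whereas the pre-window frames retain the lesion/background contrast that
makes the correlation peak sharp. The
vector from the current contour centroid to the matched position is the
moving force $m$, applied as integer translations over the next $\alpha$
frames (default 5) using a cumulative-ceiling split — the per-frame
shifts are as even as integers allow and sum to $m$ exactly, e.g.
$m = (5, 0), \alpha = 2$ gives $(3,0)$ then $(2,0)$. While alarmed,
contour evolution pauses (only the moving force acts) and the sonication
permission flag is withdrawn; the planner's `gate_by_alarm()` reads it.

## Focus planning

The treatment area is the central quarter of the tracked lesion: the
mask scaled by $1/2$ about its centroid (area ratio $1/4$ up to
pixelization) and intersected with the lesion. Foci are laid on a square
grid with 5 mm (0.5 cm) pitch anchored at the region centroid — anchoring
at the centroid makes the plan translation-equivariant with the lesion —
and kept where the grid point falls inside the region. Per-slice 2D plans
stack into a 3D plan at `z = slice_index * slice_spacing_mm`. Grid
anchoring and boundary rounding (nearest pixel) are design choices; the
alternative reading of "one quarter" as erosion to 25 % area is not
implemented. Masks below 16 px have no meaningful quarter region and are
rejected (empty layers are preserved when assembling stacks).

## The speckle phantom

The generator emulates what the tracker actually faces: a hypoechoic
deformable elliptical lesion (intensity 0.35 on a 0.6 background),
brighter internal blobs that move rigidly with it and cross its boundary,
an anechoic bladder-like ellipse, an optional black out-of-fan band,
fully developed speckle as unit-mean multiplicative gamma noise
(`speckle_shape` k = 30 by default, i.e. ~18 % intensity fluctuation),
and a motion schedule of linear drift, sinusoidal axial oscillation
(respiration-like), axis pulsation, and step jumps. It does **not**
model point-spread-function blur, attenuation, shadowing, scan
conversion, or out-of-plane motion — passing on the phantom shows the
algorithmic properties hold under speckle and the scripted motions, not
clinical performance.

Four presets (`phantom_preset()`) define the study conditions:

* **standard** (220×220 px at 0.35 mm/px, lesion semi-axes 50×40,
  60 frames): end-to-end runs. The lesion size sits comfortably above
  the $\mathcal{K}_{15}$ feature scale.
* **internal-blob** (8 frames of the standard scene): the two 9-px-radius
  boundary-crossing blobs are wide enough that the short operator carves
  deep notches around them, yet narrower than 15 px so the long operator
  bridges them.
* **jump** (128×128, lesion semi-axes 12×9, a (12,16) px jump — magnitude
  20 px — at frame 40 of 120): monitoring. The lesion is deliberately
  compact so the jump exceeds its directional extent; an uncorrected
  contour is left stranded on background, where the inverted region
  statistics make it flood away from the vanished target. This preset is
  tracked with $\mathcal{K}_3$: a lesion small enough to be lost by a
  20 px jump is below the long operator's stable scale, and the monitor
  under test is operator-independent.
* **truncated** (one frame, lesion cut by the bottom border beside a
  30-px black out-of-fan band): the overflow guard. The dark band is the
  adjacent "incomplete area" the unguarded contour leaks into.

The analytic validation shapes (`analytic_shape_case()`: disk r = 60,
ellipse 70×45, square side 160 in 220×220, noiseless two-level images
with a 60 %-overlap initialization) are sized so that the residual
corner/rim shaving of $\mathcal{K}_{15}$ — a fixed absolute loss set by
the segment length, e.g. four ≈ 14-px corner fillets on a square — stays
below 2 % of the area. Convergence is run for 50 iterations.

## Numerical choices

* Coordinates are 1-based `(row, col)` matching R matrix indexing, origin
  at the top-left pixel; frame time is 0-based so motion laws read
  naturally. Millimetre coordinates place the origin at the centre of the
  top-left pixel; `x` runs along columns, `y` along rows.
* Ties: an exactly zero attachment force leaves the pixel unchanged; NCC
  score ties break by smaller displacement, then row-major order.
* All randomness flows through the phantom seed; each frame derives a
  private sub-stream, so any frame can be re-rendered independently and
  runs are bit-reproducible.
* Degenerate inputs: empty masks are rejected where an operation needs a
  region (with the last valid mask carried in tracking-lost conditions);
  an all-zero mask still round-trips through I/O; zero-variance
  enhancement ROIs and NCC templates raise explicit errors.

## Problem sizes in the validation suite

The shipped tests and the acceptance script use: 100 random 32×32 scenes
for the brute-force equivalence of one contour update; the three
220×220 analytic shapes at 50 iterations; 20 replicate 8-frame
internal-blob sequences per operator; one 200-iteration truncated-lesion
run per guard setting; ten 120-frame jump sequences for alarm/NCC
statistics plus two full tracked runs for the corrected/uncorrected
contrast; and two full 60-frame standard runs for determinism. These
sizes were chosen as the smallest at which each property is comfortably
away from its decision boundary.

## Limitations

* The tracker assumes a single connected lesion darker than its
  surroundings after windowing; multiple lesions need one tracker
  instance each.
* In-plane rigid translation is the only correction the moving force can
  express; rotation or scaling during an alarm is not recovered.
* The overflow guard reasons about the image border; a lesion occluded
  mid-image (e.g. by shadowing) is outside its scope.
* Phantom realism is limited as described above; parameters of the
  generator are calibration knobs for algorithmic stress, not claims
  about clinical ultrasound statistics.
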