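# hifutrack

Real-time lesion tracking and sonication planning for image-guided
high-intensity focused ultrasound (HIFU) therapy of uterine fibroids.

During HIFU treatment the only live image is B-mode ultrasound: speckled,
low-contrast, and showing a lesion that drifts with breathing, deforms
under tissue pressure, and occasionally jumps when the patient moves.
`hifutrack` is aimed at researchers building or evaluating such guidance
pipelines. It provides:

* **Contour tracking** by morphological active contours without edges
  (MACWE): the contour is the boundary of a binary embedding
  *u* : Z² → {0, 1}, updated per frame by a balloon dilation, the
  Chan–Vese region-competition sign test
  λ₁(I − c₁)² − λ₂(I − c₂)² at the contour pixels, and sup-inf/inf-sup
  smoothing over discrete line segments — all with unit parameters
  (μ = ν = λ₁ = λ₂ = 1). The default operator set 𝒦₁₅ (15-pixel
  segments) ignores fine internal structure of fibroids so the contour
  follows the clinically relevant outer boundary; the classical 𝒦₃
  (3-pixel segments) is available for comparison.
* **Frame preprocessing**: grayscale morphological opening/closing
  (speckle suppression) plus an affine intensity window derived from the
  initial-contour ROI, which enhances the lesion and clips the
  bladder-like anechoic distractor to black.
* **An incomplete-area guard** that stops the contour from overflowing
  into dark out-of-fan regions when the lesion is truncated by the edge
  of the field of view.
* **Movement monitoring**: joint-histogram mutual information between
  the current frame and a stable reference every 10 frames; on alarm,
  normalized cross-correlation re-locates the lesion and the resulting
  moving force translates the contour over the next α frames while
  sonication is held.
* **Focus planning**: the central quarter of the tracked lesion (linear
  scale 1/2 about the centroid) receives an even 0.5 cm grid of
  sonication foci, assembled per image slice into a 3D plan.
* **Evaluation metrics** (Dice, IoU, Hausdorff distance in mm) and a
  **speckle phantom generator** with exact ground truth — multiplicative
  gamma speckle, deformable lesion, internal blobs, bladder distractor,
  drift/oscillation/jump motion — so the whole pipeline is testable
  without clinical data.

## Worked example

Track the standard phantom (220×220 px at 0.35 mm/px, 60 frames,
hypoechoic lesion with two bright internal blobs, bladder distractor,
drift + respiration-like oscillation), then plan foci on the final
contour:

```r
library(hifutrack)

cfg <- phantom_config(seed = 1)        # the standard phantom
seqs <- generate_phantom_sequence(cfg)
tr <- track_lesion(seqs$frames, seqs$truth_masks[[1]],
                   params = acwe_params(operator_set = k15()),
                   spacing_mm = cfg$pixel_spacing_mm)
print(tr)
#> MACWE lesion track: 60 frames, operator set of 4 segment(s) (length 15)
#>   0 frame(s) under movement alarm, 0 overflow-guard activation(s)
#>   contour area: first 5886 px, last 6270 px

summary(tr, truth = seqs$truth_masks)$report
#> Tracking report over 60 frames:
#>   dsc    mean 0.9471  sd 0.0088
#>   iou    mean 0.8997  sd 0.0158
#>   hd_mm  mean 3.5467  sd 0.3049

plan <- assemble_3d(list(list(slice_index = 0L,
                              lesion_mask = tr$masks[[60]])),
                    slice_spacing_mm = 5, spacing_mm = 5,
                    pixel_spacing_mm = cfg$pixel_spacing_mm)
print(plan)
#> HIFU focus plan: 1 slice(s), 9 foci total, grid pitch 5.0 mm
#>   slice 0 (z = 0.0 mm): 9 foci
```

A mean Dice of ~0.95 against the moving, deforming ground truth says the
contour hugs the true outer boundary for the whole sequence (the ~3.5 mm
Hausdorff distance is dominated by the smoothed corners the 15-pixel
operator cuts across the two boundary-crossing blobs); the 9 foci cover
the central quarter-area of the ~35 × 28 mm tracked lesion at 5 mm
pitch.

The same pipeline is scriptable end-to-end (`run_pipeline()`, or the
thin CLI at `inst/cli/hifutrack.R` with subcommands
`simulate | track | plan | eval | run`), writing per-frame mask PNGs,
`plan.json`, `report.json` and a JSON-lines run log.

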