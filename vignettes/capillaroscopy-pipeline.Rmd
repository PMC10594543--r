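---
title: "Wide-field capillaroscopy analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-field capillaroscopy analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(capiwide)
```

## The measurement problem

Contact capillaroscopy images the superficial capillary bed of the skin
under visible light. Only capillaries currently carrying red blood cells
(RBCs) are visible — the vessel wall itself has no usable contrast — and
RBC supply is intermittent, so any single frame shows a fragmented subset
of the bed. A wide-field device (here: 7.4 mm × 5.5 mm at 1.85 µm/px,
30 frames/s) sees on the order of a thousand capillaries at once, each only
a few pixels wide, along with stains, sweat-gland openings and hairs that
share their color range. The package's job is to (i) integrate the temporal
RBC signal into one still image, (ii) segment capillaries against the
distractors, and (iii) reduce the mask to the variables used in practice:
number of capillary regions, total area, and average area.

## Pipeline and assumptions

**Stabilization.** The camera and subject drift by a few to a few tens of
pixels; the model is a per-frame integer translation (no rotation, no
non-rigid deformation — reasonable for a hand-held contact probe over a
5 s clip). The central crop of frame 1 with margin $m$ (default 50 px) is
the template; each frame is matched by *exhaustive* search of the zero-mean
normalized cross-correlation on the green channel over every valid integer
position. Exhaustive search is chosen over pyramidal refinement for
determinism: the result is the global maximum, with ties broken by the
smallest $(y, x)$ position. Correctable drift is $\pm m$ px. A zero-variance
template ("untextured") is an error rather than an arbitrary answer.
Sub-pixel alignment is deliberately not implemented; the downstream
composite operates on integer grids.

**Minimum-green composite.** RBCs are redder than the surroundings, so their
passage depresses the green channel. For each pixel the composite keeps the
full RGB triplet of the frame with the minimal G value (earliest frame on
ties — a fixed, documented rule so the operation is a pure function of the
stack). Taking the minimum rather than the mean preserves vessels through
which RBCs pass only rarely. The assumption is that G-minima are caused by
RBCs rather than by illumination flicker; the stabilized, short clip makes
that a good approximation. The composite satisfies two testable contracts:
its G channel is a per-pixel lower bound of every aligned frame, and
`image[p]` is bit-identical to the source frame recorded in
`source_frame_index[p]`.

**Flat-fielding.** Illumination falls off toward the field edges. Each
channel is divided by a box-mean-filtered copy of itself (kernel *radius*
300 px at full scale, i.e. a 601 × 601 window — large relative to any
vessel, small relative to the vignette), then rescaled to 8 bits by the
channel's global mean ("a constant image is a fixed point"). Numerical
choices the underlying method leaves open, fixed here: reflection padding
for the filter (replicate available as an option), denominator floored at
1 so dark corners cannot divide by zero, and half-up rounding on the way
back to 8 bits.

**Contrast enhancement.** Per channel: 256-bin histogram equalization using
the cumulative histogram normalized from its first occupied bin (the common
8-bit convention), then the gamma map $v \mapsto \mathrm{round}(255\,
(v/255)^{0.3})$. Equalization runs first — the fixed order matters because
the two maps do not commute. A constant channel is returned unchanged
(degenerate histogram), and the gamma map fixes both endpoints
($0 \to 0$, $255 \to 255$) for any $\gamma > 0$.

**Segmentation.** A U-Net — encoder/decoder with skip connections — with
size-preserving 3 × 3 convolutions so the output grid equals the input grid.
Depth (default 4) and base width (default 16 channels, doubling per level)
are configurable because full-size networks are unnecessary for desk-scale
work. The implementation (im2col + GEMM convolutions, 2 × 2 max pooling,
nearest-neighbor upsampling with skip concatenation, a 1 × 1 sigmoid head,
BCE / soft-Dice / combined losses, Adam, full backpropagation) lives in the
package with RcppArmadillo kernels; training is single-threaded and fully
seeded, so checkpoints and predictions are reproducible bit for bit. The
backward pass is verified against central-difference numerical gradients in
development; the shipped tests verify learning on a constructed-learnable
task and checkpoint round-trips.

Inference tiles the still with `window_px` = 512 windows at
`stride_px` = 50 in both axes, the last window of each row/column clamped to
the image edge so coverage is total; overlapping predictions are averaged
(max is available) and thresholded at 0.5 (`>=` is foreground, so raising
the threshold can only remove pixels). Clamping re-covers edge pixels
rather than inventing zero-padding context.

**Quantification.** Connected components of the binary mask under
8-connectivity by default — thin diagonal vessels stay single regions;
4-connectivity is available. Labeling is deterministic (raster-scan order
of first-encountered pixels) with no minimum-size filter by default. The
variables are `number`, `total_area_px` and `average_area_px = total/number`
(`NA`, never 0, when no regions), with µm² equivalents via
`area_px × um_per_px²`.

**Calibration.** Automated counts differ systematically from manual
annotation; a through-origin regression $y = b\,x$ (detected on manual) per
variable captures the scale, fitted as $b = \sum x_i y_i / \sum x_i^2$ with
Pearson $r$ stored alongside. The through-origin form is the contract
because the bundled reference calibration is expressed that way (slopes
2.014 / 1.311 / 0.604 for number / total area / average area); an intercept
option exists but is off by default. Calibrated estimates invert the fit:
$\hat x = y / b$.

**Agreement evaluation.** Pixel-level metrics come from the per-pixel
confusion table; every 0/0 ratio is reported as missing (`NA`) rather than
0, and Dice/IoU satisfy $\mathrm{IoU} = \mathrm{Dice}/(2 - \mathrm{Dice})$
to 1e-12 whenever both are defined. For structures a few pixels wide,
pixel overlap understates detection quality, so the region level counts a
ground-truth region as TP if *any* of its pixels is predicted, FN
otherwise, and a predicted region as FP if it overlaps no ground-truth
foreground. Note the deliberately mixed units (TP/FN in ground-truth
regions, FP in predicted regions): one predicted blob touching several
ground-truth regions credits each of them, and precision = TP/(TP+FP)
mixes the units accordingly. There are no region-level TN or IoU fields —
there is no meaningful region unit for true negatives. Across images,
metrics are averaged per image with equal weights, not pooled. Bland–Altman
agreement uses the sample standard deviation ($n-1$) and
$\mathrm{LoA} = \bar d \pm 1.96\,s_d$; the sign convention of the
differences is an explicit flag (default prediction − ground truth) because
published conventions vary.

## The synthetic scene simulator

With no public data for this device class, the simulator is the package's
test bed. It renders, deterministically for a given seed:

- a static background: smooth low-frequency color field plus fine Gaussian
  texture (the texture is what template matching locks onto);
- tortuous vessels as smoothed 2-D random walks (unit steps, bounded
  curvature), stroked at a width drawn from 2–6 px — matching capillary
  outer diameters of ~10 µm at 1.85 µm/px; placement retries to avoid
  overlap so the ground-truth region count is well-defined, but the count
  is always *recomputed* from the emitted mask, never assumed;
- RBC packets as 1-D arc-length intervals advancing at constant per-vessel
  speed with wrap-around; their pixel effect is a green (and milder blue)
  depression — directly exercising the min-G composite. A configurable
  fraction of vessels is intermittent (one packet covering 25–50% of the
  arc); the rest are filled along their whole length in every frame;
- a multiplicative radial vignette fixed to the camera;
- per-frame integer viewport jitter with replicate-edge fill (frame 1 is
  the unshifted reference, which puts the stabilized still on the central
  crop of the scene grid — see `crop_margin()`);
- static distractors (stains, sweat-gland spots, hairs) that darken all
  channels, not specifically green.

The RBC/background contrast is a free parameter (default 60 of 255 in G)
because no measured value is available for the reference device.

What the simulator does *not* emulate — and therefore what passing tests do
not establish about clinical data: specular highlights and wet-film optics,
depth blur and scattering, non-rigid skin deformation, rolling shutter,
sensor noise statistics, hemodynamics beyond constant-speed packets, and
photorealistic skin texture. Results on simulated scenes validate the
*mechanics* of the pipeline (alignment, compositing, learning, counting,
metrics), not clinical segmentation accuracy.

## Problem sizes used by the test suite

Scaled-down sizes are the package's own choice for a fast, deterministic
suite; every operation is size-generic and the full-scale defaults (150
frames of 4000 × 3000 px, margin 50, kernel radius 300, 512 px windows at
50 px stride) remain the documented configuration:

- oracle-equivalence batches: 100 seeded random instances per operation on
  grids of ≤ 12 × 10 px;
- stabilization exactness: 20 textured scenes of 128 × 120 px, 4 frames,
  jitter up to ±50 px against a 50 px margin;
- flat-fielding: a 600 × 600 uniform scene under a 0.7-strength vignette,
  kernel radius 50 (coefficient of variation is compared excluding a
  kernel-radius border, where the filter support is truncated);
- the learned end-to-end check: two training and three held-out scenes of
  256 × 192 px × 30 frames with 8 vessels each, a depth-3 / 16-channel
  network trained for 8 epochs on 48 patches of 64 × 64 px
  (BCE + Dice loss, Adam at 3e-3), inference with 64 px windows at 32 px
  stride, scored by mean region-level recall against ground truth.

The same experiments, re-seeded from the command line, are what
`scripts/acceptance.R` reports.

## Known limitations

- Exhaustive ZNCC matching is exact but quadratic in the search margin;
  full-scale 4000 × 3000 stacks are best stabilized once and cached.
- Integer-only alignment leaves up to half a pixel of residual motion,
  which slightly thickens composited vessels.
- The training loop is CPU-bound and intended for reduced networks;
  reproducing a full-scale 50-epoch training run is out of scope.
- The bundled calibration slopes transfer only to data comparable to the
  reference workflow; refit `fit_calibration()` for any new device or
  annotator.
- Region-level precision inherits the mixed-unit convention above; when a
  predicted blob bridges several true regions, precision can exceed what a
  one-to-one matching would report. The convention is kept because it is
  the field's stated counting rule for this evaluation.
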