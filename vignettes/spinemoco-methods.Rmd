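---
title: "SpineMoCo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpineMoCo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SpineMoCo performs retrospective motion correction of axial spinal-cord
fMRI time series. This vignette describes the model and the choices behind
the implementation: what is computed, which parameters matter, what the
synthetic phantom does and does not emulate, and where the design was
genuinely open.

## The problem

Axial gradient-echo EPI of the cervical cord has a small cross-section,
low signal, and suffers bulk motion plus breathing-driven displacement of
the spinal column. Rigid-body volume registration developed for the brain
is a poor fit: the cord moves non-rigidly, slice by slice, dominated by
anterior-posterior (y) translation from chest motion, while lateral (x)
motion is small because the shoulders are fixed. SpineMoCo therefore works
slicewise and in two stages:

1. **Centerline realignment** (translation-only, y-only by default)
   removes the bulk per-slice displacement.
2. An **unsupervised registration network** predicts a dense in-plane
   displacement field per (slice, volume) pair against a reference volume
   and resamples the slice, capturing the residual non-rigid part.

## Stage 1: centerline realignment

For every slice `z` and volume `t` the cord center is estimated as the
intensity-weighted centroid, either over a supplied cord mask or over
voxels at or above the slice's half-range threshold. Tracks along time are
cleaned with Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by
linear interpolation of order statistics, per slice and per coordinate);
flagged or unmeasurable entries are replaced by evaluating a degree-3
B-spline fitted along time to the inliers (`splines::interpSpline`; with
fewer than 4 inliers the inlier median is used). Each slice-time image is
then translated by `reference - center` with subpixel bilinear resampling.

Choices worth knowing:

* **y-only by default.** The anterior-posterior translation variance is
  roughly twice the lateral one (variance ratio about 1.1 : 0.52 in
  cervical-cord data), and the network's dense field corrects x residuals
  anyway. `mode = "xy"` is available.
* **Fences and spline run along time, per slice** — temporal tracks are
  the thing that wobbles; no smoothing along z is applied (and no z
  correction at all: axial acquisitions move minimally through-plane).
  Pooling the IQR across slices would couple unrelated slices.
* **The reference centerline defaults to the first volume's centers**, in
  line with the default reference-volume policy below.
* A shift exceeding half the field of view is treated as an implausible
  track and raised as an error rather than applied.

## Stage 2: unsupervised deformable registration

Given the reference (fixed) slice `F` and a moving slice `M`, a UNet-style
encoder-decoder with skip connections maps the 2-channel concatenation
`(F, M)` to a dense field `u` with one 2-vector per pixel. The warped
image is `M(p + u(p))`, evaluated with bilinear interpolation at
non-integer positions and edge-clamped sampling. Training minimizes

```
L = L_sim(F, M(u)) + lambda * L_reg(u)
```

with no ground-truth fields or anatomical labels — the similarity itself
is the supervision.

* `L_sim` is either MSE, `(1/sigma^2) * mean((F - W)^2)` with
  `sigma = 1`, or the default **windowed NCC**: at every pixel the squared
  Pearson correlation of the two images over the 3x3 window centered
  there, averaged and negated, so both losses are minimized. NCC is
  invariant to local affine intensity changes, which matters for T2*
  signal drift. The denominator carries a stabilizer `eps = 1e-5`;
  perfectly matched images therefore score slightly above -1 in
  low-variance regions.
* `L_reg` penalizes squared forward differences of each field component
  along each axis, each difference set averaged over its own valid
  positions and summed. Mean (not sum) reductions are used in both terms
  so that `lambda` transfers across image sizes; `lambda = 0.01` is the
  default, the value at which validation tSNR peaks, and large values
  visibly degrade the correction (the package ships a `sweepLambda()`
  utility reproducing that direction).

### Architecture

Two capacity presets are provided. Both use 3x3 convolutions,
leaky-ReLU (slope 0.2), batch normalization everywhere except the final
flow layer, stride-2 convolutions down, nearest-neighbor x2 upsampling
with skip concatenation up, and a linear 2-channel flow head initialized
near zero so the untrained map is near-identity (this stabilizes early
training). `drm2` (compact) uses encoder widths [16, 32, 32, 32], decoder
[32, 32, 32, 32] and one full-resolution refinement layer of width 16:
89,474 parameters. `drm1` doubles the widths and refines with [32, 16]:
358,418 parameters. The per-layer widths are this package's own plan in
the established dense-displacement-registration style; the architectural
contract is the relative capacity (the larger preset strictly
out-parameterizes the compact one and carries the longer refinement
tail), and the counts are pinned by a test.

The encoder depth of 4 requires spatial dims divisible by 16; whole-run
correction symmetrically edge-pads other sizes and crops the result back.

### Training

Defaults mirror a full-scale run: Adam at `1e-4`, batches of 100 slice
pairs, 200 epochs of 150 iterations, subjects split 70:30 into training
and validation **at the subject level** (pairs never straddle the split),
pairs drawn by sampling subject, run, slice and volume uniformly with the
fixed image taken from the run's reference volume. The reference-volume
policy is `first` by default (`mid` and `mean` are available); model
selection across epochs keeps the weights with the best cord tSNR on
corrected validation data, falling back to validation loss when no cord
mask is supplied — quality of the corrected signal, not the raw loss, is
the quantity of interest.

Everything in this package runs at *desk scale* in its tests and in the
shipped end-to-end study: 64x64x4x40 phantoms, three subjects, batches of
8, a few hundred optimizer steps at learning rate `1e-3`. Those sizes are
the package's own choice of a study small enough to rerun routinely while
still exercising every stage; the full-scale defaults above remain in
place for real runs. Since the network, warper, losses and backpropagation
are implemented in this package (R orchestration over im2col + GEMM and
analytic adjoints in compiled code), the gradient path is verified
directly: finite-difference agreement tests cover the warper, both
losses, and the full network including batch normalization and skip
connections.

Two conventions are easy to get backwards and are therefore spelled out:
fields are in voxels with the sampling convention `out(p) = img(p + u(p))`,
and the field that aligns a moving volume back to the template equals the
*content* displacement that corrupted it (the generator stores both; the
recovery tests compare predicted fields against `+translation + warp`,
folding in whatever translation the centerline stage already removed).

## Quality control

* **tSNR**: voxelwise temporal mean over temporal SD (sample SD,
  denominator `nt - 1`; zero-SD voxels score 0), reported globally and
  within cord/CSF masks.
* **DVARS**: RMS over voxels of the frame-to-frame difference, per frame
  pair, computed on min-max normalized data so methods are comparable;
  the square root keeps units of intensity.
* **Pearson correlation** of every volume against the reference volume,
  flattened; constant volumes are flagged and scored 0 rather than NA.

Directionally: good correction raises tSNR, lowers mean DVARS, raises CC.
The acceptance study checks all three orderings plus the mean endpoint
error of the predicted fields against ground truth (< 1 voxel in the
cord).

## The synthetic phantom

`makePhantom()` draws a bright cord disk (radius 3.5 voxels by default)
inside a CSF ring on a dark background, slightly curved along z, lightly
blurred so image gradients exist away from pure edges. Volume 1 is the
uncorrupted template; later volumes are moved by a per-volume translation
shared across slices — `sd_y = sqrt(1.1)`, `sd_x = sqrt(0.52)` voxels,
matching the anisotropy observed in cervical-cord data — plus a smooth
residual warp (Gaussian-smoothed white-noise field, smoothness scale 8
voxels, scaled to 1 voxel peak by default) applied with the package's own
warper, plus additive Gaussian noise (sd 0.02 on unit intensities). The
generator is bitwise deterministic under its seed and returns the full
ground truth.

What it emulates: geometry and contrast of an axial cervical-cord EPI
slice stack, dominant-y translational motion, mild non-rigid deformation,
thermal noise. What it does **not** emulate: ghosting, B0 drift and
field-fluctuation artifacts, physiological signal, partial-volume and
receive-coil profiles, intensity drift. Passing tests on phantoms
therefore demonstrate correct mechanics and recoverable motion, not
clinical performance on real acquisitions. One deliberate asymmetry
remains: corruption and correction share the same warper (a unit-test
convenience); the added noise and the network's imperfect inverse keep
the recovery problem non-trivial.

## Numerical notes and edge cases

* Min-max normalization is per volume, so global intensity drift cannot
  leak across the pair sampler; constant volumes map to zeros; double
  normalization is refused outright.
* Warp sampling is edge-clamped; field gradients are zero where the clamp
  saturates (the output there is genuinely insensitive to the field).
* Windowed sums in the NCC use edge-clamped windows with multiplicity;
  the analytic gradient uses the exact adjoint of that operator.
* Batch-norm running statistics (momentum 0.9) are used at inference;
  batch statistics during training.
* Quantiles are type-7 (linear interpolation); with IQR 0 the fences
  collapse to the quartile value, so any deviation is flagged — the
  desired behavior for a flat track with one spike.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.

## Known limitations

* 2D slicewise only; no through-plane (z) correction, by design.
* The exact layer widths of the two presets are this package's plan;
  capacities in the low-hundreds-of-thousands of parameters, with the
  documented ordering, are the contract.
* The reference centerline and reference volume are free parameters;
  `first` is the default for both, and better data-driven choices are
  plausible.
* Training on a CPU at paper scale is impractical; the desk-scale
  configuration exists precisely so the full pipeline stays testable.
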