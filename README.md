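# SpineMoCo

Retrospective motion correction for **axial spinal-cord fMRI** time series,
for researchers preprocessing cervical-cord gradient-echo EPI data. Rigid
whole-volume registration built for the brain fits the cord poorly: the
spinal column moves non-rigidly, slice by slice, dominated by
anterior-posterior (y) translation from breathing while lateral (x) motion
stays small. SpineMoCo corrects this in two slicewise stages:

1. **Centerline realignment** — the cord center is tracked per slice over
   time (intensity-weighted centroid), outliers are rejected with Tukey
   IQR fences and repaired by a degree-3 B-spline along time, and each
   slice-time image is translated back to the reference centerline
   (y-only by default).
2. **Unsupervised deformable registration** — a UNet-style encoder-decoder
   g_θ maps the channel-concatenated pair (F, M) of reference and moving
   slices to a dense displacement field φ with one in-plane 2-vector per
   pixel; the moving slice is resampled as M(p + φ(p)) with a
   differentiable bilinear warper. Training needs no ground truth: it
   minimizes

       L(F, M, φ) = L_sim(F, M(φ)) + λ · L_reg(φ),

   where L_sim is MSE or a locally windowed (3×3) squared normalized
   cross-correlation and L_reg penalizes the field's spatial gradients
   (λ = 0.01 by default). Two capacity presets are provided (`drm1`,
   `drm2`); the network, losses, warper and backpropagation are
   implemented in the package (R over im2col + GEMM and analytic adjoints
   in compiled code) and are gradient-checked against finite differences.

Correction quality is quantified by temporal SNR (mean/SD over time, up is
better), DVARS (RMS frame-to-frame change, down is better) and the Pearson
correlation of each volume with the reference (up is better). A synthetic
phantom generator with stored ground-truth motion makes the whole pipeline
testable end to end: recovery is scored as the mean endpoint error between
predicted and true displacement inside the cord.

## Worked example

```r
library(SpineMoCo)

# simulate a motion-corrupted cord phantom (known ground truth)
ph <- makePhantom(phantomConfig(shape = c(32, 32, 2, 16), cordRadius = 3,
                                csfRadius = 6, seed = 7))
ph$series
#> VolumeSeries: 32 x 32 x 2 voxels, 16 volumes (raw)
#>   voxel size: 1.2 x 1.2 x 5 mm

# full pipeline: normalize -> centerline realign -> train (desk scale) -> QC
out <- runPipeline(ph$series, tempfile("demo"),
                   cordMask = ph$cordMask, csfMask = ph$csfMask,
                   config = list(seed = 7,
                                 train = list(epochs = 2, stepsPerEpoch = 40,
                                              batchSize = 8,
                                              learningRate = 1e-3)))
print(out$qcReport$table, row.names = FALSE, digits = 3)
#>     method metric    roi   value
#>        raw   tsnr global  2.8215
#>        raw   tsnr   cord 13.0049
#>        raw   tsnr    csf  4.1839
#>        raw  dvars global  0.0745
#>        raw     cc global  0.9594
#>  corrected   tsnr global  7.2780
#>  corrected   tsnr   cord 49.3827
#>  corrected   tsnr    csf 31.4444
#>  corrected  dvars global  0.0251
#>  corrected     cc global  0.9972
```

Reading the table: after correction the cord tSNR rises (13.0 → 49.4,
i.e. the cord time courses become far steadier), mean DVARS falls
(0.075 → 0.025, fewer abrupt frame-to-frame jumps) and the per-volume
correlation with the reference rises (0.959 → 0.997). Pre-trained weights
can be reused across runs via `weights =`; `correctSeries()`,
`trainModel()`, `qcReport()` and the centerline functions are also usable
individually, and `inst/cli/spinemoco` exposes `simulate`, `prep`,
`train`, `correct`, `qc` and `sweep-lambda` subcommands for shell use.

See the methods vignette (`vignettes/spinemoco-methods.Rmd`) for the
model, its assumptions, parameter choices and limitations.

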