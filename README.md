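# spatheRFR

Image completion for occluded plant organs, built for anthurium spathe
phenotyping. Overhead grading images of potted anthurium routinely show
spathes partially hidden by neighbouring leaves or spathes; measuring the
visible contour under-sizes the organ. `spatheRFR` repairs the occluded
image first — with a recurrent feature reasoning network whose reasoning
layers are multi-scale Inception blocks — and then scores contour recovery
with a centroid-anchored polar metric.

## What is inside

* **Completion network.** Partial convolutions identify the thin ring of
  missing pixels that can be inferred this round; an Inception-block
  encoder–decoder (parallel 1×1 / 3×3 / 5×5 convolutions plus 3×3 max
  pooling, concatenated and fused by a 3×3 convolution) fills it; the two
  steps alternate recurrently with shared weights, per-round features are
  merged by validity-weighted averaging
  (Σ fₜ⊙mₜ / Σ mₜ), and a skip-connected head decodes back to RGB. Known
  pixels are returned bit-for-bit.
* **Training objective.** `L = λ_hole·L_hole + λ_valid·L_valid +
  λ_perc·L_perc + λ_style·L_style` with defaults λ_hole = 1, λ_valid = 6,
  λ_perc = 0.05, λ_style = 120; L1 content terms, perceptual/style terms on
  a pluggable feature extractor (a deterministic seeded random-convolution
  bank by default), Adam optimization, on-the-fly random occlusion masks.
* **Test protocol.** Occlusion masks of three missing types (top, side,
  bottom) × five missing-proportion bins (0–10% … 40–50% of the organ
  area): 15 groups, one per taxonomy cell, grown as single connected blobs
  anchored at the organ extremity.
* **Accuracy metric.** MSE = (1/2π)∮(r₁(θ) − r₂(θ))² dθ between the polar
  contours of the completed and the real organ about their centroids, in
  pixels².
* **Synthetic data.** A seeded generator of star-convex spathe-like organs
  (teardrop outline, base-to-tip colour gradient, uniform background) makes
  every module testable without proprietary imagery.
* **Diagnostics.** Channel-wise feature-map grids and low-activity channel
  counts, for comparing how much the encoder still extracts under small vs
  large holes.

All network numerics run on a compact reverse-mode autodiff tape with
C++ (Armadillo) convolution kernels — no deep-learning framework required;
the whole pipeline trains and runs on one CPU.

## Worked example

```r
library(spatheRFR)

# a synthetic organ and a side occlusion covering 20-30% of it
s    <- generateSpathe(SpatheParams(canvasSize = 64L, scale = 18, seed = 7L))
mask <- generateMask(s$foreground, MaskSpec("side", bin = 3, seed = 7L))
measureProportion(mask, s$foreground)
#> [1] 0.2335766

# a small model, untrained here for brevity
model <- createModel(ModelConfig(imageSize = 64L, baseChannels = 16L,
                                 recurrenceCount = 3L, encoderDepth = 2L))
out <- recurrentInference(model, s$image, mask)
identical(out$completed[rep(mask == 1, 3)], s$image[rep(mask == 1, 3)])
#> [1] TRUE

# contour accuracy of a completion, against the true foreground
ct  <- polarContour(s$foreground)
ct
#> PolarContour: N=360, pole=(32.5, 37.1), r in [15.5, 16.8] px

# a short desk-scale training run
ds  <- generateSpatheDataset(32, SpatheParams(canvasSize = 64L, scale = 18),
                             spatheJitter(64L), seed = 1L)
fit <- fitModel(model, ds, TrainConfig(learningRate = 1e-3, batchSize = 2L,
                                       iterations = 120L, seed = 1L))
tail(fit$log$L_sum, 1) < median(head(fit$log$L_sum, 100))
#> [1] TRUE
```

The numbers printed above are what the code produces: the mask generator
hits the requested 20–30% bin exactly (measured against the organ area),
composite inference preserves every known pixel bit-for-bit, and the short
training run drives the joint loss below its starting level.

A command-line front end covering fixture generation, test-set
construction, training, completion, evaluation and visualization is
installed at `inst/scripts/msrfr` (see `?runCLI`).

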