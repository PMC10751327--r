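# Shared fixtures, built in code. Small canvases keep the suite fast; the
# jitter ranges are the 256 px study conditions scaled to the canvas.

rep3 <- spatheRFR:::rep3

tinySpathe <- function(size = 64L, scale = round(size * 0.28), seed = 1L,
                       ...) {
  generateSpathe(SpatheParams(canvasSize = as.integer(size), scale = scale,
                              seed = as.integer(seed), ...))
}

smallDataset <- function(n, size = 64L, seed = 1L) {
  j <- spatheJitter(size)
  generateSpatheDataset(n, SpatheParams(canvasSize = as.integer(size),
                                        scale = mean(j$scale)),
                        j, seed = seed)
}

tinyModelConfig <- function(size = 32L, base = 8L, rec = 3L, depth = 1L)
  ModelConfig(imageSize = as.integer(size), baseChannels = as.integer(base),
              recurrenceCount = as.integer(rec),
              encoderDepth = as.integer(depth))

rasterDisk <- function(n, ctr, R)
  outer(seq_len(n), seq_len(n),
        function(r, c) ((r - ctr[1])^2 + (c - ctr[2])^2 <= R^2) + 0)

# Area-coverage (anti-aliased) rasterization of an analytic indicator
# f(row, col); used by the analytic contour-metric validation, where
# centre-binarized rasters would add aliasing noise unrelated to the metric.
coverRaster <- function(n, f, ss = 4L) {
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- matrix(0, n, n)
  for (dr in off) for (dc in off)
    acc <- acc + outer(seq_len(n) + dr, seq_len(n) + dc, f)
  acc / ss^2
}

# Cache for expensive artefacts shared across test files (e.g. the
# desk-trained smoke model).
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

# Desk-scale smoke training run: 32 synthetic 64x64 images, base_channels 16,
# recurrence 3, batch 2, lr 1e-3, 2000 Adam iterations.
deskSmokeRun <- function() {
  cachedFixture("deskSmoke", function() {
    ds <- smallDataset(32, size = 64L, seed = 11L)
    cfg <- ModelConfig(imageSize = 64L, baseChannels = 16L,
                       recurrenceCount = 3L, encoderDepth = 2L)
    model <- createModel(cfg, seed = 11L)
    tc <- TrainConfig(learningRate = 1e-3, batchSize = 2L,
                      iterations = 2000L, seed = 11L)
    fit <- fitModel(model, ds, tc)
    list(fit = fit, dataset = ds, config = cfg)
  })
}

# Single-image overfit run: one 32x32 synthetic sample, base_channels 8,
# one fixed side-type mask (20-30% bin), Adam lr 5e-3, 500 steps.
overfitSmokeRun <- function(seed = 20L, steps = 500L) {
  j <- spatheJitter(32L)
  s <- generateSpatheDataset(1, SpatheParams(canvasSize = 32L,
                                             scale = mean(j$scale)),
                             j, seed = seed)[[1]]
  mask <- generateMask(s$foreground, MaskSpec("side", 3, seed = seed + 1L))
  cfg <- ModelConfig(imageSize = 32L, baseChannels = 8L,
                     recurrenceCount = 3L, encoderDepth = 1L)
  model <- createModel(cfg, seed = seed)
  ex <- randomFeatureExtractor()
  batch <- list(list(image = s$image, mask = mask))
  opt <- NULL
  sums <- numeric(steps)
  for (i in seq_len(steps)) {
    st <- trainStep(model, batch, opt = opt, lr = 5e-3, extractor = ex)
    model <- st$model
    opt <- st$opt
    sums[i] <- st$loss@sum
  }
  out <- recurrentInference(model, s$image, mask)
  list(holeL1 = regionL1(out$pred, s$image, 1 - mask), lossTrace = sums,
       sample = s, mask = mask, model = model)
}
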