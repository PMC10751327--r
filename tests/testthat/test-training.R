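# Training loop: augmentation geometry, optimizer mechanics, seeded
# reproducibility, checkpoint round trips and resumption.

test_that("identity augmentation ranges return the input unchanged", {
  s <- tinySpathe(seed = 1L)
  out <- augmentSample(s$image, s$foreground, scale = c(1, 1), rotate = 0,
                       translate = 0)
  expect_identical(out$image, s$image)
  expect_identical(out$foreground, s$foreground)
})

test_that("rotating a disk by 90 degrees leaves it unchanged up to interpolation", {
  disk <- rasterDisk(64, c(32.5, 32.5), 18)
  img <- array(0.5, c(64, 64, 3)) * rep3(disk, 3) + 0.2
  rot <- affineTransform(img, disk, angle = 90)
  iou <- sum(rot$foreground & disk) / sum(rot$foreground | disk)
  expect_gt(iou, 0.98)
})

test_that("augmentation is deterministic under the RNG seed and bounded", {
  s <- tinySpathe(seed = 2L)
  set.seed(99); a <- augmentSample(s$image, s$foreground)
  set.seed(99); b <- augmentSample(s$image, s$foreground)
  expect_identical(a, b)
  d <- dim(a$foreground)
  border <- c(a$foreground[1:2, ], a$foreground[d[1] - 1:0, ],
              a$foreground[, 1:2], a$foreground[, d[2] - 1:0])
  expect_true(all(border == 0))
})

test_that("a zero learning rate leaves the weights unchanged", {
  cfg <- tinyModelConfig()
  model <- createModel(cfg, seed = 4L)
  s <- tinySpathe(size = 32L, seed = 4L)
  mask <- generateMask(s$foreground, MaskSpec("side", 3, seed = 2L))
  batch <- list(list(image = s$image, mask = mask))
  st <- trainStep(model, batch, lr = 0, extractor = randomFeatureExtractor())
  expect_equal(st$model$params, model$params, tolerance = 1e-15)
  comp <- lossComponents(st$loss)
  expect_true(all(is.finite(comp)))
  expect_true(all(comp >= 0))
})

test_that("the seeded loss log reproduces exactly and checkpoints round-trip", {
  ds <- smallDataset(4, size = 32L, seed = 6L)
  cfg <- tinyModelConfig(size = 32L, base = 4L, rec = 2L, depth = 1L)
  tc <- TrainConfig(learningRate = 1e-3, batchSize = 2L, iterations = 6L,
                    seed = 5L, augScale = c(0.95, 1.05), augRotate = 10,
                    augTranslate = 2)
  ex <- randomFeatureExtractor()
  m1 <- createModel(cfg, seed = 5L)
  f1 <- fitModel(m1, ds, tc, extractor = ex)
  f2 <- fitModel(createModel(cfg, seed = 5L), ds, tc, extractor = ex)
  expect_equal(f1$log, f2$log, tolerance = 1e-15)
  expect_identical(nrow(f1$log), 6L)
  # checkpoint round trip: save -> load -> forward is bit-identical
  ck <- file.path(tempdir(), "ck-roundtrip.rds")
  saveCheckpoint(f1$model, ck)
  re <- loadCheckpoint(ck)$model
  img <- ds[[1]]$image
  mask <- generateMask(ds[[1]]$foreground, MaskSpec("top", 2, seed = 8L))
  expect_identical(recurrentInference(re, img, mask)$completed,
                   recurrentInference(f1$model, img, mask)$completed)
})

test_that("training resumes bit-identically from a mid-run checkpoint", {
  ds <- smallDataset(4, size = 32L, seed = 7L)
  cfg <- tinyModelConfig(size = 32L, base = 4L, rec = 2L, depth = 1L)
  ex <- randomFeatureExtractor()
  outA <- file.path(tempdir(), "run-straight")
  outB <- file.path(tempdir(), "run-resumed")
  tcFull <- TrainConfig(learningRate = 1e-3, batchSize = 2L,
                        iterations = 8L, seed = 9L, checkpointEvery = 4L)
  full <- fitModel(createModel(cfg, seed = 9L), ds, tcFull, extractor = ex,
                   outDir = outA)
  resumed <- fitModel(createModel(cfg, seed = 9L), ds, tcFull,
                      extractor = ex, outDir = outB,
                      resume = file.path(outA, "checkpoint_000004.rds"))
  expect_equal(tail(full$log$L_sum, 4), tail(resumed$log$L_sum, 4),
               tolerance = 1e-6)
  expect_equal(full$model$params, resumed$model$params, tolerance = 1e-12)
})

test_that("zero iterations yield a checkpoint equal to the initialization", {
  ds <- smallDataset(1, size = 32L, seed = 8L)
  cfg <- tinyModelConfig(size = 32L, base = 4L, rec = 2L, depth = 1L)
  model <- createModel(cfg, seed = 3L)
  out <- file.path(tempdir(), "run-zero")
  f <- fitModel(model, ds, TrainConfig(iterations = 0L, seed = 1L),
                outDir = out)
  expect_identical(nrow(f$log), 0L)
  ck <- loadCheckpoint(f$checkpoint)
  expect_equal(ck$model$params, model$params, tolerance = 1e-15)
})

test_that("YAML configuration maps onto the constructors", {
  yml <- file.path(tempdir(), "cfg.yaml")
  writeLines(c(
    "model:", "  imageSize: 64", "  baseChannels: 16",
    "  recurrenceCount: 3", "  encoderDepth: 2",
    "train:", "  learningRate: 1.0e-3", "  batchSize: 2",
    "  iterations: 50",
    "loss:", "  style: 60"), yml)
  cfg <- loadConfigYAML(yml)
  expect_identical(cfg$model@imageSize, 64L)
  expect_identical(cfg$train@batchSize, 2L)
  expect_equal(cfg$loss@style, 60)
  expect_equal(cfg$loss@valid, 6)   # untouched default
})
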