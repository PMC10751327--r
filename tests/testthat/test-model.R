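# Network core: partial convolution, Inception layers, recurrent inference
# and feature merging, each checked against brute-force per-pixel oracles.

test_that("partial convolution matches the sliding-window oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    H <- sample(5:8, 1); cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    x <- array(rnorm(H * H * cin), c(H, H, cin))
    mask <- matrix(rbinom(H * H, 1, 0.6), H, H)
    w <- array(rnorm(9 * cin * cout), c(3, 3, cin, cout))
    b <- rnorm(cout)
    got <- partialConv(x, mask, w, b, stride = 1, pad = 1)
    want <- pconvOracle(x, mask, w, b, pad = 1)
    expect_equal(got$feature, want$feature, tolerance = 1e-10)
    expect_identical(got$mask + 0, want$mask)
  }
})

test_that("partial convolution limits: full mask is plain convolution, empty mask is zero", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(9 * 2 * 2), c(3, 3, 2, 2))
  b <- rnorm(2)
  full <- partialConv(x, matrix(1, 6, 6), w, b)
  plain <- spatheRFR:::convRaw(x, w, b, 1L, 1L)
  expect_equal(full$feature, plain, tolerance = 1e-12)
  expect_identical(full$mask, matrix(1, 6, 6))
  empty <- partialConv(x, matrix(0, 6, 6), w, b)
  expect_true(all(empty$feature == 0))
  expect_true(all(empty$mask == 0))
  # single centre hole in a field of ones: renormalization recovers the sum
  ones <- array(1, c(5, 5, 1))
  m <- matrix(1, 5, 5); m[3, 3] <- 0
  wk <- array(1, c(3, 3, 1, 1))
  got <- partialConv(ones, m, wk, 0)
  want <- pconvOracle(ones, m, wk, 0, pad = 1)
  expect_equal(got$feature, want$feature, tolerance = 1e-12)
  expect_equal(got$feature[3, 3, 1], 8 * 9 / 8)
  expect_error(partialConv(array(1, c(2, 2, 1)), matrix(1, 2, 2),
                           array(1, c(7, 7, 1, 1)), 0, pad = 0), "larger")
})

test_that("area identification dilates the mask like its kernel support", {
  cfg <- tinyModelConfig(size = 32L, base = 4L, rec = 2L, depth = 1L)
  model <- createModel(cfg, seed = 2L)
  f <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  m <- matrix(1, 16, 16); m[5:12, 5:12] <- 0
  r <- areaIdentify(model, f, m)
  # oracle: two 3x3 partial convs dilate the valid set by 1 px each
  dil <- spatheRFR:::dilateBinary(m, 2L)
  expect_identical(r$mask, dil)
  expect_identical(r$inferRegion, dil - m)
  expect_true(all(r$mask >= m))
  # fully known mask: nothing to infer
  r2 <- areaIdentify(model, f, matrix(1, 16, 16))
  expect_true(all(r2$inferRegion == 0))
})

test_that("inception layer follows the four-branch fusion arithmetic", {
  lay <- initInceptionLayer(2L, 3L, 4L, seed = 8L)
  z <- array(0, c(6, 6, 2))
  expect_true(all(inceptionLayer(z, lay) == 0))
  # 1x1 spatial input: every branch collapses to scalar arithmetic
  set.seed(9)
  x1 <- array(rnorm(2), c(1, 1, 2))
  got <- inceptionLayer(x1, lay, leakySlope = 0.2)
  h1 <- pmax(colSums(x1[1, 1, ] * lay$w1[1, 1, , ]) + lay$b1, 0)
  h3 <- pmax(colSums(x1[1, 1, ] * lay$w3[2, 2, , ]) + lay$b3, 0)
  h5 <- pmax(colSums(x1[1, 1, ] * lay$w5[3, 3, , ]) + lay$b5, 0)
  h4 <- x1[1, 1, ]
  cat14 <- c(h1, h3, h5, h4)
  fused <- colSums(cat14 * lay$wf[2, 2, , ])
  want <- ifelse(fused > 0, fused, 0.2 * fused)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  # shape contract: fusion input channels = 3*branch + in
  expect_identical(dim(lay$wf)[3], 3L * 3L + 2L)
  expect_error(inceptionLayer(array(0, c(4, 4, 5)), lay), "mismatch")
})

test_that("feature merge equals the per-pixel validity-weighted loop", {
  for (seed in 1:5) {
    set.seed(seed)
    fs <- lapply(1:3, function(t) array(rnorm(4 * 4 * 2), c(4, 4, 2)))
    ms <- lapply(1:3, function(t) matrix(rbinom(16, 1, 0.5), 4, 4))
    expect_equal(featureMerge(fs, ms), mergeOracle(fs, ms),
                 tolerance = 1e-10)
  }
  one <- array(rnorm(8), c(2, 2, 2))
  expect_identical(featureMerge(list(one), list(matrix(1, 2, 2))), one)
  a <- array(1, c(2, 2, 1)); b <- array(3, c(2, 2, 1))
  expect_equal(featureMerge(list(a, b), list(matrix(1, 2, 2),
                                             matrix(1, 2, 2))),
               array(2, c(2, 2, 1)))
  expect_error(featureMerge(list(), list()), "empty")
})

test_that("recurrent inference composites, monotonically fills and preserves shape", {
  set.seed(30)
  for (trial in 1:6) {
    size <- sample(c(16L, 32L), 1)
    depth <- if (size == 16L) 1L else sample(1:2, 1)
    cfg <- ModelConfig(imageSize = size, baseChannels = sample(c(4L, 8L), 1),
                       recurrenceCount = 6L, encoderDepth = depth)
    model <- createModel(cfg, seed = trial)
    img <- array(runif(size * size * 3), c(size, size, 3))
    mask <- matrix(1, size, size)
    h <- sample(3:(size %/% 2), 1)
    mask[3:(3 + h), 3:(3 + h)] <- 0
    out <- recurrentInference(model, img, mask)
    expect_identical(dim(out$completed), dim(img))
    known <- rep3(mask, 3) == 1
    expect_identical(out$completed[known], img[known])
    covered <- vapply(out$states$featureMasks, sum, numeric(1))
    expect_true(all(diff(covered) >= 0))
  }
})

test_that("a fully known image passes through unchanged and a finite hole fills", {
  cfg <- tinyModelConfig(size = 32L, base = 4L, rec = 6L, depth = 1L)
  model <- createModel(cfg, seed = 3L)
  img <- tinySpathe(size = 32L, seed = 6L)$image
  full <- recurrentInference(model, img, matrix(1, 32, 32))
  expect_identical(full$completed, img)
  expect_true(all(full$states$featureMasks[[1]] == 1))
  # hole spanning half the image: per-round dilation (2 px at feature
  # resolution per identification, plus the front-end) closes it within
  # the 6 rounds
  mask <- matrix(1, 32, 32); mask[8:24, 8:24] <- 0
  out <- recurrentInference(model, img, mask)
  expect_true(all(out$states$featureMasks[[6]] == 1))
})
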