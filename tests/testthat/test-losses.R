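# Joint objective: content, perceptual and style components against
# hand-computed and loop-based oracles, plus the published coefficients.

test_that("region L1 equals the explicit per-pixel loop", {
  set.seed(1)
  for (i in 1:10) {
    p <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    g <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    r <- matrix(rbinom(25, 1, 0.5), 5, 5)
    acc <- 0
    for (a in 1:5) for (b in 1:5) for (c in 1:3)
      acc <- acc + abs(p[a, b, c] - g[a, b, c]) * r[a, b]
    want <- if (sum(r) > 0) acc / (sum(r) * 3) else 0
    expect_equal(regionL1(p, g, r), want, tolerance = 1e-12)
  }
  p <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_identical(regionL1(p, p, matrix(1, 4, 4)), 0)
  r10 <- matrix(0, 4, 4); r10[seq_len(10)] <- 1   # 10 region pixels
  expect_equal(regionL1(p + 0.5, p, r10), 0.5, tolerance = 1e-12)
  expect_identical(regionL1(p, p + 1, matrix(0, 4, 4)), 0)
})

test_that("gram matrix is the normalized channel co-activation", {
  expect_identical(gramMatrix(array(0, c(3, 3, 2))), matrix(0, 2, 2))
  # 2-channel 1x2 feature [[1,0],[0,1]]: G = I/4
  f <- array(0, c(1, 2, 2))
  f[1, 1, 1] <- 1; f[1, 2, 2] <- 1
  expect_equal(gramMatrix(f), diag(2) / 4, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
    G <- gramMatrix(x)
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_true(all(eigen(G, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-8))
    # loop oracle
    Fm <- t(matrix(x, 20, 3))
    expect_lt(max(abs(G - Fm %*% t(Fm) / 60)), 1e-12)
  }
})

test_that("perceptual and style losses vanish at equality and reduce correctly", {
  set.seed(3)
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  g <- array(runif(16 * 16 * 3), c(16, 16, 3))
  ex <- randomFeatureExtractor()
  eq <- perceptualStyleLosses(p, p, ex)
  expect_equal(unname(eq), c(0, 0))
  ne <- perceptualStyleLosses(p, g, ex)
  expect_true(all(ne >= 0))
  # identity extractor: perceptual loss reduces to whole-image L1
  idl <- perceptualStyleLosses(p, g, identityExtractor())
  expect_equal(unname(idl["perceptual"]),
               regionL1(p, g, matrix(1, 16, 16)) * 1,
               tolerance = 1e-12)
  # extractor is deterministic across instantiations
  ex2 <- randomFeatureExtractor()
  expect_identical(perceptualStyleLosses(p, g, ex2), ne)
})

test_that("joint loss combines the published coefficients linearly", {
  w <- LossWeights()
  expect_identical(lossWeightVector(w),
                   c(hole = 1, valid = 6, perceptual = 0.05, style = 120))
  # components forced to one: weighted sum of the printed coefficients
  expect_equal(sum(lossWeightVector(w) * 1), 127.05)
  set.seed(4)
  img <- tinySpathe(size = 32L, seed = 5L)$image
  mask <- matrix(1, 32, 32); mask[10:22, 10:22] <- 0
  pred <- pmin(pmax(img + array(rnorm(32 * 32 * 3, sd = 0.2),
                                c(32, 32, 3)), 0), 1)
  ex <- randomFeatureExtractor()
  lb <- jointLoss(pred, img, mask, w, ex)
  comp <- lossComponents(lb)
  expect_equal(comp[["sum"]],
               comp[["hole"]] + 6 * comp[["valid"]] +
                 0.05 * comp[["perceptual"]] + 120 * comp[["style"]],
               tolerance = 1e-12)
  # recomputation oracle for the content parts
  expect_equal(comp[["hole"]], regionL1(pred, img, 1 - mask),
               tolerance = 1e-12)
  expect_equal(comp[["valid"]], regionL1(pred, img, mask),
               tolerance = 1e-12)
  compImg <- img * rep3(mask, 3) + pred * rep3(1 - mask, 3)
  ps <- perceptualStyleLosses(compImg, img, ex)
  expect_equal(comp[["perceptual"]], ps[["perceptual"]], tolerance = 1e-10)
  expect_equal(comp[["style"]], ps[["style"]], tolerance = 1e-10)
  # equality: every component zero
  z <- lossComponents(jointLoss(img, img, mask, w, ex))
  expect_equal(unname(z), rep(0, 5))
})

test_that("scaling one component scales the sum by its weight", {
  # doubling the style weight with others fixed raises the sum by
  # lambda_style * L_style (Eq. linearity)
  set.seed(5)
  img <- tinySpathe(size = 32L, seed = 7L)$image
  mask <- matrix(1, 32, 32); mask[5:15, 5:25] <- 0
  pred <- pmin(pmax(img + 0.1, 0), 1)
  ex <- randomFeatureExtractor()
  base <- lossComponents(jointLoss(pred, img, mask, LossWeights(), ex))
  up <- lossComponents(jointLoss(pred, img, mask,
                                 LossWeights(style = 240), ex))
  expect_equal(up[["sum"]] - base[["sum"]], 120 * base[["style"]],
               tolerance = 1e-9)
  expect_equal(up[["style"]], base[["style"]], tolerance = 1e-12)
})

test_that("valid-region interpretations are selectable", {
  set.seed(6)
  s <- tinySpathe(size = 32L, seed = 8L)
  mask <- generateMask(s$foreground, MaskSpec("bottom", 2, seed = 3L))
  pred <- pmin(pmax(s$image + 0.05, 0), 1)
  ex <- identityExtractor()
  known <- jointLoss(pred, s$image, mask, extractor = ex,
                     validRegion = "known")
  whole <- jointLoss(pred, s$image, mask, extractor = ex,
                     validRegion = "image")
  fg <- jointLoss(pred, s$image, mask, extractor = ex,
                  validRegion = "foreground", foreground = s$foreground)
  expect_equal(known@valid, regionL1(pred, s$image, mask), tolerance = 1e-12)
  expect_equal(whole@valid, regionL1(pred, s$image, matrix(1, 32, 32)),
               tolerance = 1e-12)
  expect_equal(fg@valid, regionL1(pred, s$image, s$foreground),
               tolerance = 1e-12)
  expect_error(jointLoss(pred, s$image, mask, extractor = ex,
                         validRegion = "foreground"), "foreground")
})
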