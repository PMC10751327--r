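# Polar-contour metric: analytic shapes, quadrature oracle, invariances and
# manifest-level aggregation.

test_that("centroid is the arithmetic mean of foreground coordinates", {
  disk <- rasterDisk(101, c(51, 51), 30)
  expect_equal(regionCentroid(disk), c(51, 51), tolerance = 0.5)
  single <- matrix(0, 30, 30); single[10, 20] <- 1
  expect_identical(regionCentroid(single), c(10, 20))
  two <- rasterDisk(101, c(30, 30), 10) + rasterDisk(101, c(70, 70), 10)
  m1 <- sum(rasterDisk(101, c(30, 30), 10))
  expect_equal(regionCentroid(two), c(50, 50), tolerance = 0.2)
  expect_error(regionCentroid(matrix(0, 5, 5)), "empty")
})

test_that("polar radii recover analytic circles and squares", {
  disk <- rasterDisk(121, c(61, 61), 50)
  pc <- polarContour(disk)
  expect_identical(nAngles(pc), 360L)
  expect_true(all(abs(radii(pc) - 50) <= 0.75))
  pc4 <- polarContour(disk, N = 4L)
  expect_identical(nAngles(pc4), 4L)
  expect_lt(diff(range(radii(pc4))), 0.6)
  # axis-aligned square of half-side a
  a <- 20
  sq <- matrix(0, 101, 101)
  sq[51 + (-a:a), 51 + (-a:a)] <- 1
  ps <- polarContour(sq, N = 8L)
  expect_equal(radii(ps)[1], a, tolerance = 1)          # 0 deg
  expect_equal(radii(ps)[2], a * sqrt(2), tolerance = 1) # 45 deg
})

test_that("contour MSE matches constants and the quadrature oracle", {
  d50 <- rasterDisk(141, c(71, 71), 50)
  d40 <- rasterDisk(141, c(71, 71), 40)
  c50 <- polarContour(d50)
  expect_identical(contourMSE(c50, c50), 0)
  mse <- contourMSE(c50, polarContour(d40))
  expect_equal(mse, 100, tolerance = 1.5)
  # ellipse (a=60, b=40) vs circle r=50, against 1e5-point quadrature of
  # the analytic integrand; coverage rasterization keeps binarization
  # aliasing out of the comparison
  ell <- coverRaster(161, function(r, c)
    (((c - 81) / 60)^2 + ((r - 81) / 40)^2 <= 1) + 0)
  d50b <- coverRaster(161, function(r, c)
    ((r - 81)^2 + (c - 81)^2 <= 50^2) + 0)
  got <- contourMSE(polarContour(ell), polarContour(d50b))
  th <- 2 * pi * (seq_len(1e5) - 1) / 1e5
  rEll <- 60 * 40 / sqrt((40 * cos(th))^2 + (60 * sin(th))^2)
  oracle <- mean((rEll - 50)^2)
  expect_equal(got, oracle, tolerance = 0.01 * oracle)
  expect_error(contourMSE(c50, polarContour(d40, N = 180L)), "resolution")
})

test_that("contour MSE is symmetric, translation-invariant and scales as s^2", {
  d1 <- rasterDisk(161, c(60, 60), 35)
  e1 <- outer(seq_len(161), seq_len(161), function(r, c)
    (((c - 60) / 45)^2 + ((r - 60) / 30)^2 <= 1) + 0)
  c1 <- polarContour(d1); c2 <- polarContour(e1)
  expect_equal(contourMSE(c1, c2), contourMSE(c2, c1), tolerance = 1e-12)
  # translate both regions by the same offset
  d1t <- rasterDisk(161, c(95, 90), 35)
  e1t <- outer(seq_len(161), seq_len(161), function(r, c)
    (((c - 90) / 45)^2 + ((r - 95) / 30)^2 <= 1) + 0)
  expect_equal(contourMSE(polarContour(d1t), polarContour(e1t)),
               contourMSE(c1, c2), tolerance = 1e-6)
  # scale both by 2: MSE scales by 4 (within rasterization error)
  d2 <- rasterDisk(321, c(120, 120), 70)
  e2 <- outer(seq_len(321), seq_len(321), function(r, c)
    (((c - 120) / 90)^2 + ((r - 120) / 60)^2 <= 1) + 0)
  expect_equal(contourMSE(polarContour(d2), polarContour(e2)),
               4 * contourMSE(c1, c2), tolerance = 0.04 * 4 *
                 contourMSE(c1, c2))
  # refinement convergence: N vs 2N
  mA <- contourMSE(polarContour(d1, N = 360L), polarContour(e1, N = 360L))
  mB <- contourMSE(polarContour(d1, N = 720L), polarContour(e1, N = 720L))
  expect_lt(abs(mB - mA) / mA, 0.01)
})

test_that("segmentation recovers synthetic foregrounds and rejects blanks", {
  for (seed in c(2L, 10L)) {
    s <- smallDataset(1, size = 96L, seed = seed)[[1]]
    seg <- segmentSpathe(s$image)
    iou <- sum(seg & s$foreground) / sum(seg | s$foreground)
    expect_gte(iou, 0.98)
    # idempotence on its own binarized output rendered as an image
    render <- rep3(seg, 3) * 0.8 + 0.05
    seg2 <- segmentSpathe(render)
    expect_identical(seg2, seg)
  }
  expect_error(segmentSpathe(array(0.5, c(32, 32, 3))), "uniform")
})

test_that("non-star-convex regions fall back to the max-radius rule with a warning", {
  blob <- rasterDisk(101, c(51, 51), 30)
  blob[20:51, 48:54] <- 0          # carve a deep notch through the top
  blob[20:30, 40:62] <- 1          # re-attach a lobe above the notch
  expect_false(isStarConvex(blob))
  expect_warning(pc <- polarContour(blob), "star-convex")
  expect_true(all(radii(pc) > 0))
})

test_that("grid evaluation aggregates per-image records by type and bin", {
  ds <- smallDataset(2, size = 96L, seed = 30L)
  truth <- file.path(tempdir(), "eval-truth")
  spatheRFR:::writeFixtureDir(ds, truth)
  grid <- file.path(tempdir(), "eval-grid")
  man <- buildTestGrid(ds, grid, seed = 3L)
  man <- man[man$bin_low >= 0.1 & man$bin_low <= 0.2, ]  # 2 bins x 3 types
  pred <- file.path(tempdir(), "eval-pred")
  dir.create(pred, showWarnings = FALSE)
  # "completions": ground truth for image 1 (MSE 0), eroded organ for image 2
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    s <- ds[[match(r$image, c("img_0000", "img_0001"))]]
    img <- s$image
    if (r$image == "img_0001") {
      shrunk <- spatheRFR:::dilateBinary(1 - s$foreground, 2L)
      fg2 <- (1 - shrunk) * s$foreground
      img <- s$image * rep3(fg2, 3) + 0.92 * rep3(1 - fg2, 3)
    }
    writeImagePNG(img, file.path(pred, basename(r$masked_path)))
  }
  res <- evaluateGrid(pred, truth, man, N = 180L)
  expect_identical(nrow(res$records), nrow(man))
  expect_identical(nrow(res$byType), 3L)
  expect_identical(nrow(res$byBin), 2L)
  # group-by oracle
  oracle <- tapply(res$records$mse, res$records$missing_type, mean)
  for (ty in names(oracle))
    expect_equal(res$byType$mse[res$byType$missing_type == ty],
                 unname(oracle[ty]), tolerance = 1e-12)
  perfect <- res$records$mse[res$records$image == "img_0000"]
  eroded <- res$records$mse[res$records$image == "img_0001"]
  expect_true(all(perfect < 1e-12))
  expect_true(all(eroded > 1))
})
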