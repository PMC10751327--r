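# Completion accuracy as a shape metric: the organ contour is expressed in
# polar coordinates about its centroid (theta = 0 horizontal right,
# counterclockwise positive, radii in pixels) and completed vs. real contours
# are compared by the mean squared radial difference
#   MSE = (1/2pi) Integral (r1(theta) - r2(theta))^2 dtheta,
# discretized as the mean over a uniform angular grid.

#' Centroid of a binary region
#'
#' Arithmetic mean of the foreground pixel coordinates (uniform pixel mass).
#'
#' @param region binary H x W matrix.
#' @return numeric `(row, col)`.
#' @export
regionCentroid <- function(region) {
  idx <- which(region >= 0.5, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty region")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Otsu threshold of a numeric vector.
otsuThreshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(min(x), max(x), length.out = nbins + 1L), all.inside = TRUE),
    1L), nbins), nbins)
  mids <- seq(min(x), max(x), length.out = nbins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[nbins]; mtot <- mu[nbins]
  between <- (mtot * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment the organ from a completed image
#'
#' Colour-distance thresholding against the background (estimated from a
#' 2-pixel border frame), Otsu split, largest 4-connected component, hole
#' filling. Fails on images without a dominant foreground object.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param minContrast minimum colour distance a foreground must reach.
#' @return binary H x W matrix.
#' @export
segmentSpathe <- function(image, minContrast = 0.1) {
  d <- dim(image)
  frame <- rbind(
    cbind(rep(1:2, d[2]), rep(seq_len(d[2]), each = 2)),
    cbind(rep(d[1] - 1:0, d[2]), rep(seq_len(d[2]), each = 2)),
    cbind(rep(seq_len(d[1]), each = 2), rep(1:2, d[1])),
    cbind(rep(seq_len(d[1]), each = 2), rep(d[2] - 1:0, d[1])))
  bg <- vapply(1:3, function(ch) median(image[, , ch][frame]), numeric(1))
  dist <- sqrt((image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
               (image[, , 3] - bg[3])^2)
  if (max(dist) < minContrast)
    stop("no foreground object: image is uniform against its border colour")
  fg <- dist > otsuThreshold(c(dist))
  if (sum(fg) < 16) stop("segmentation found no foreground")
  lab <- .cpp_label_components(fg)
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  out <- .cpp_fill_holes(keep)
  matrix(as.numeric(out), d[1], d[2])
}

#' Extract the polar contour of a region
#'
#' Radii are measured from the region centroid along `N` uniformly spaced
#' directions (image-mathematics frame: x right, y up, counterclockwise).
#' Each radius is located to sub-pixel precision by bisecting the bilinear
#' inside/outside indicator around the outermost inside-to-outside crossing,
#' which for a star-convex region is the unique boundary crossing; regions
#' that violate star-convexity trigger a warning and fall back to that
#' max-radius rule.
#'
#' @param region H x W mask; binary, or fractional area-coverage values in
#'   [0, 1] (the 0.5 level is the boundary either way — coverage masks
#'   locate it with sub-pixel fidelity, binary masks to within the
#'   rasterization).
#' @param N number of angular samples.
#' @param step coarse radial marching step in pixels.
#' @return a [PolarContour-class].
#' @examples
#' disk <- outer(1:101, 1:101, function(r, c) ((r-51)^2 + (c-51)^2 <= 50^2) + 0)
#' range(radii(polarContour(disk)))
#' @export
polarContour <- function(region, N = 360L, step = 0.5) {
  if (sum(region) == 0) stop("empty region")
  ctr <- regionCentroid(region)
  star <- isStarConvex(region, nRays = N, step = step)
  if (!star)
    warning("region is not star-convex about its centroid; using the max-radius rule")
  d <- dim(region)
  theta <- 2 * pi * (seq_len(N) - 1) / N
  maxR <- sqrt(sum(d^2))
  rs <- seq(0, maxR, by = step)
  rows <- outer(-sin(theta), rs) + ctr[1]
  cols <- outer(cos(theta), rs) + ctr[2]
  inside <- bilinearSample(region, rows, cols) >= 0.5
  # outermost inside sample per ray (max-radius rule; the unique crossing
  # when star-convex)
  lastIn <- apply(inside, 1, function(z) {
    w <- which(z)
    if (!length(w)) NA_integer_ else max(w)
  })
  if (anyNA(lastIn)) {
    warning("centroid lies outside the region on some rays; radii set to 0")
    lastIn[is.na(lastIn)] <- 1L
  }
  lo <- rs[lastIn]
  hi <- lo + step
  dirR <- -sin(theta); dirC <- cos(theta)
  for (i in 1:22) {
    mid <- (lo + hi) / 2
    ins <- bilinearSample(region, ctr[1] + dirR * mid,
                          ctr[2] + dirC * mid) >= 0.5
    lo <- ifelse(ins, mid, lo)
    hi <- ifelse(ins, hi, mid)
  }
  new("PolarContour", radii = (lo + hi) / 2, pole = ctr, starConvex = star)
}

#' Mean squared contour error
#'
#' `(1/N) sum_k (r1(theta_k) - r2(theta_k))^2`, the uniform-grid
#' discretization of the mean squared radial difference over the full turn.
#' Each contour is taken about its own centroid, so the metric compares
#' shapes, not positions.
#'
#' @param c1,c2 [PolarContour-class] objects with equal `N`.
#' @return non-negative scalar, pixels^2.
#' @export
contourMSE <- function(c1, c2) {
  if (nAngles(c1) != nAngles(c2))
    stop("contours have different angular resolutions")
  mean((radii(c1) - radii(c2))^2)
}

#' Evaluate completed images over a test-grid manifest
#'
#' For every manifest row, segments the completed and ground-truth images,
#' extracts both polar contours (each about its own centroid) and records
#' the mean squared contour error; aggregates mean MSE per missing type and
#' per proportion bin.
#'
#' @param predDir directory of completed images, named like the manifest's
#'   `masked_path` basenames.
#' @param truthDir directory of ground-truth fixtures (`<image>.png`).
#' @param manifest manifest `data.frame` from [buildTestGrid()], or the path
#'   to its CSV.
#' @param N angular samples per contour.
#' @param outDir if given, writes `records.csv`, `by_type.csv`,
#'   `by_bin.csv`.
#' @return list with `records` (per-image), `byType` and `byBin`
#'   data.frames.
#' @export
evaluateGrid <- function(predDir, truthDir, manifest, N = 360L,
                         outDir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  rows <- vector("list", nrow(manifest))
  truthCache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    predFile <- file.path(predDir, basename(r$masked_path))
    truthFile <- file.path(truthDir, paste0(r$image, ".png"))
    if (!file.exists(predFile) || !file.exists(truthFile)) {
      warning("missing file for row ", i, " (", basename(predFile),
              "); skipped")
      next
    }
    mse <- tryCatch({
      key <- r$image
      ct <- truthCache[[key]]
      if (is.null(ct)) {
        ct <- polarContour(segmentSpathe(readImagePNG(truthFile)), N)
        truthCache[[key]] <- ct
      }
      cp <- suppressWarnings(
        polarContour(segmentSpathe(readImagePNG(predFile)), N))
      contourMSE(cp, ct)
    }, error = function(e) {
      warning("row ", i, ": ", conditionMessage(e), "; skipped")
      NA_real_
    })
    if (is.na(mse)) next
    rows[[i]] <- data.frame(image = r$image, missing_type = r$type,
                            bin_low = r$bin_low, bin_high = r$bin_high,
                            mse = mse, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records)) stop("no manifest row could be evaluated")
  byType <- aggregate(mse ~ missing_type, records, mean)
  byBin <- aggregate(mse ~ bin_low + bin_high, records, mean)
  byBin <- byBin[order(byBin$bin_low), ]
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(outDir, "records.csv"), row.names = FALSE)
    write.csv(byType, file.path(outDir, "by_type.csv"), row.names = FALSE)
    write.csv(byBin, file.path(outDir, "by_bin.csv"), row.names = FALSE)
  }
  list(records = records, byType = byType, byBin = byBin)
}
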