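# Occlusion-mask generation: the 3-missing-type x 5-proportion-bin taxonomy.
# Real occlusions come from neighbouring leaves/spathes covering the organ's
# top, side or bottom; masks are grown from the corresponding extremity of the
# foreground so the hole is one connected blob anchored where an occluder
# would sit. The protocol fixes only the taxonomy, not the algorithm:
# here a static-priority region growth (Euclidean distance from the anchor
# plus seeded per-pixel jitter) absorbs pixels until the hole covers an exact
# target fraction of the organ, then enclosed gaps are filled.

# Chebyshev dilation of a binary matrix by `radius` pixels.
dilateBinary <- function(m, radius) {
  d <- .cpp_dilate(m >= 0.5, as.integer(radius))
  matrix(as.numeric(d), nrow(m), ncol(m))
}

# Anchor pixel of the foreground for a missing type: the extremity where the
# occluder sits (median position along the extreme row/column).
maskAnchor <- function(fg, missingType, side) {
  idx <- which(fg == 1, arr.ind = TRUE)
  switch(missingType,
    top = {
      r <- min(idx[, 1])
      c(r, round(median(idx[idx[, 1] == r, 2])))
    },
    bottom = {
      r <- max(idx[, 1])
      c(r, round(median(idx[idx[, 1] == r, 2])))
    },
    side = {
      cl <- if (side == "left") min(idx[, 2]) else max(idx[, 2])
      c(round(median(idx[idx[, 2] == cl, 1])), cl)
    })
}

#' Generate an occlusion mask for one taxonomy cell
#'
#' Grows a single 4-connected hole from the top / lateral / bottom extremity
#' of the foreground until it covers a target fraction (drawn uniformly
#' inside the spec's bin) of the reference area. The hole may spill into
#' background pixels adjacent to the organ -- real occluders cover both --
#' but only the overlap with the reference area counts toward the measured
#' proportion. Identical `(foreground, spec)` give identical masks.
#'
#' @param foreground binary H x W matrix, 1 = organ.
#' @param spec a [MaskSpec-class].
#' @param proportionOf `"foreground"` (default) measures the missing fraction
#'   against the organ area; `"canvas"` against the full image area.
#' @param jitterAmp amplitude (pixels) of the per-pixel priority jitter that
#'   roughens the hole boundary.
#' @param spill Chebyshev radius (pixels) by which the hole may extend into
#'   the background around the organ.
#' @return binary H x W mask, 1 = known pixel, 0 = hole.
#' @examples
#' fg <- generateSpathe(SpatheParams(canvasSize = 64L, scale = 20))$foreground
#' m <- generateMask(fg, MaskSpec("top", 3, seed = 7L))
#' measureProportion(m, fg)
#' @export
generateMask <- function(foreground, spec, proportionOf = "foreground",
                         jitterAmp = 3, spill = 5L) {
  validObject(spec)
  proportionOf <- match.arg(proportionOf, c("foreground", "canvas"))
  if (sum(foreground) == 0) stop("foreground is empty")
  d <- dim(foreground)
  if (spec@binLow == 0 && spec@binHigh == 0)
    return(matrix(1, d[1], d[2]))
  ref <- if (proportionOf == "canvas") matrix(TRUE, d[1], d[2])
         else foreground == 1
  refCount <- sum(ref)
  withSeed(spec@seed, {
    side <- spec@side
    if (spec@missingType == "side" && side == "random")
      side <- sample(c("left", "right"), 1)
    anchor <- maskAnchor(foreground, spec@missingType, side)
    domain <- dilateBinary(foreground, as.integer(spill)) > 0.5
    if (proportionOf == "canvas") domain <- matrix(TRUE, d[1], d[2])
    rr <- matrix(seq_len(d[1]), d[1], d[2])
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    dist <- sqrt((rr - anchor[1])^2 + (cc - anchor[2])^2)
    prio <- dist + matrix(runif(prod(d), 0, jitterAmp), d[1], d[2])
    pad <- 0.015
    frac <- runif(1, spec@binLow + pad, spec@binHigh - pad)
    target <- max(1L, round(frac * refCount))
    for (attempt in 1:10) {
      blob <- .cpp_grow_region(prio, domain, ref,
                               anchor[1] - 1L, anchor[2] - 1L, target)
      blob <- .cpp_fill_holes(blob == 1L)
      got <- sum(blob == 1L & ref)
      measured <- got / refCount
      if (measured >= spec@binLow && measured <= spec@binHigh)
        return(matrix(1 - blob, d[1], d[2]))
      # hole filling added pixels beyond the target: shrink and retry
      target <- target - (got - target)
      if (target < 1L) break
    }
    stop(sprintf(
      "mask generation failed to reach bin [%.2f, %.2f] (degenerate foreground?)",
      spec@binLow, spec@binHigh))
  })
}

#' Measure the missing proportion of a mask
#'
#' Fraction of the foreground covered by the hole:
#' `|(1 - mask) & foreground| / |foreground|`.
#'
#' @param mask binary H x W matrix, 1 = known.
#' @param foreground binary H x W matrix, 1 = organ.
#' @return fraction in [0, 1].
#' @export
measureProportion <- function(mask, foreground) {
  if (!all(dim(mask) == dim(foreground))) stop("shape mismatch")
  nfg <- sum(foreground == 1)
  if (nfg == 0) stop("foreground is empty")
  sum(mask == 0 & foreground == 1) / nfg
}

#' Build the full 15-group occlusion test grid
#'
#' For every fixture and every cell of the taxonomy (3 missing types x 5
#' proportion bins) generates one occlusion mask and the corresponding
#' masked image, writes them as PNG, and records a manifest row. With `n`
#' fixtures the grid holds `15 n` masked images.
#'
#' @param fixtures list as returned by [generateSpatheDataset()], or a
#'   directory containing `img_XXXX.png` / `img_XXXX_fg.png` pairs.
#' @param outDir output directory (created if missing).
#' @param seed integer seed; every mask draw derives from it.
#' @param writeMasked also write the masked (occluded) images, holes white.
#' @param proportionOf passed to [generateMask()].
#' @return invisibly, the manifest `data.frame` with columns
#'   `image, type, bin_low, bin_high, fraction, mask_path, masked_path`;
#'   also written to `outDir/manifest.csv`.
#' @export
buildTestGrid <- function(fixtures, outDir, seed = 1L, writeMasked = TRUE,
                          proportionOf = "foreground") {
  if (is.character(fixtures)) fixtures <- readFixtureDir(fixtures)
  stopifnot(length(fixtures) >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  types <- c("top", "side", "bottom")
  nf <- length(fixtures)
  seeds <- withSeed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nf * 15L), nrow = nf))
  rows <- vector("list", nf * 15L)
  k <- 0L
  for (i in seq_len(nf)) {
    fx <- fixtures[[i]]
    id <- fx$id %||% sprintf("img_%04d", i - 1L)
    cell <- 0L
    for (ty in types) {
      for (b in 1:5) {
        cell <- cell + 1L
        spec <- MaskSpec(ty, b, seed = seeds[i, cell])
        mask <- tryCatch(
          generateMask(fx$foreground, spec, proportionOf = proportionOf),
          error = function(e)
            stop(sprintf("fixture %s, %s bin %d: %s", id, ty, b,
                         conditionMessage(e))))
        fraction <- measureProportion(mask, fx$foreground)
        maskPath <- file.path(outDir, sprintf("%s_%s_b%d_mask.png", id, ty, b))
        writeMaskPNG(mask, maskPath)
        maskedPath <- file.path(outDir,
                                sprintf("%s_%s_b%d_masked.png", id, ty, b))
        if (writeMasked) {
          occ <- fx$image * rep3(mask, 3) + rep3(1 - mask, 3)
          writeImagePNG(occ, maskedPath)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          image = id, type = ty, bin_low = .BINS[[b]][1],
          bin_high = .BINS[[b]][2], fraction = fraction,
          mask_path = maskPath, masked_path = maskedPath,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Read img_XXXX.png / img_XXXX_fg.png pairs written by writeFixtureDir().
readFixtureDir <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^img_[0-9]+\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no img_XXXX.png fixtures found in ", dir)
  lapply(imgs, function(f) {
    id <- sub("\\.png$", "", basename(f))
    fgf <- file.path(dir, paste0(id, "_fg.png"))
    if (!file.exists(fgf)) stop("missing foreground mask ", fgf)
    list(image = readImagePNG(f), foreground = readMaskPNG(fgf), id = id)
  })
}

# Write fixtures as img_XXXX.png + img_XXXX_fg.png pairs.
writeFixtureDir <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fixtures)) {
    id <- sprintf("img_%04d", i - 1L)
    writeImagePNG(fixtures[[i]]$image, file.path(dir, paste0(id, ".png")))
    writeMaskPNG(fixtures[[i]]$foreground,
                 file.path(dir, paste0(id, "_fg.png")))
  }
  invisible(dir)
}
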