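#' Parameters of a synthetic spathe rendering
#'
#' Value object describing one synthetic spathe: a star-convex teardrop
#' outline with a smooth base-to-tip colour gradient on a uniform background.
#' The radial profile is
#' \deqn{r(\phi) = s\,(a + (1-a)\cos^2(\phi/2))\,(1 + t\cos\phi)^{1/2},}
#' where \eqn{s} is \code{scale} (major semi-axis, pixels), \eqn{a} the
#' \code{aspect} ratio squashing the base, and \eqn{t} the
#' \code{tipSharpness} elongating the apex; \eqn{\phi = 0} points along the
#' major axis towards the tip. The profile is single-valued in \eqn{\phi},
#' so the shape is star-convex about its reference point.
#'
#' @slot canvasSize canvas side length in pixels (square canvas).
#' @slot center (row, col) of the shape reference point, pixels.
#' @slot scale major semi-axis, pixels (>= 8).
#' @slot aspect base squashing ratio in (0, 1].
#' @slot tipSharpness apex elongation, >= 0.
#' @slot rotation rotation of the major axis, degrees counterclockwise.
#' @slot baseColor,tipColor,backgroundColor RGB triples in [0, 1].
#' @slot noiseSd per-channel Gaussian noise standard deviation.
#' @slot seed integer seed controlling the noise draw.
#' @seealso [generateSpathe()]
#' @export
setClass("SpatheParams", representation(
  canvasSize = "integer", center = "numeric", scale = "numeric",
  aspect = "numeric", tipSharpness = "numeric", rotation = "numeric",
  baseColor = "numeric", tipColor = "numeric", backgroundColor = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("SpatheParams", function(object) {
  msg <- character()
  if (object@canvasSize < 16L) msg <- c(msg, "canvasSize must be >= 16")
  if (object@scale < 8) msg <- c(msg, "scale must be >= 8 px")
  if (object@aspect <= 0 || object@aspect > 1)
    msg <- c(msg, "aspect must lie in (0, 1]")
  if (object@tipSharpness < 0 || object@tipSharpness >= 1)
    msg <- c(msg, "tipSharpness must lie in [0, 1)")
  for (s in c("baseColor", "tipColor", "backgroundColor")) {
    v <- slot(object, s)
    if (length(v) != 3 || any(v < 0) || any(v > 1))
      msg <- c(msg, paste(s, "must be an RGB triple in [0, 1]"))
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  # worst-case radius of the profile: s * (1 + t)^0.5 at phi = 0
  rmax <- object@scale * sqrt(1 + object@tipSharpness)
  lo <- min(object@center) - rmax
  hi <- max(object@center) + rmax
  if (lo < 5 || hi > object@canvasSize - 4)
    msg <- c(msg, "shape (after rotation) would violate the 4 px canvas margin")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpatheParams-class Constructor with study-condition defaults.
#' @param canvasSize,center,scale,aspect,tipSharpness,rotation,baseColor,tipColor,backgroundColor,noiseSd,seed see slots.
#' @export
SpatheParams <- function(canvasSize = 256L, center = NULL, scale = 70,
                         aspect = 0.75, tipSharpness = 0.3, rotation = 0,
                         baseColor = c(0.85, 0.15, 0.20),
                         tipColor = c(0.95, 0.55, 0.55),
                         backgroundColor = c(0.92, 0.92, 0.90),
                         noiseSd = 0.01, seed = 1L) {
  if (is.null(center)) center <- rep((canvasSize + 1) / 2, 2)
  new("SpatheParams", canvasSize = as.integer(canvasSize), center = center,
      scale = scale, aspect = aspect, tipSharpness = tipSharpness,
      rotation = rotation, baseColor = baseColor, tipColor = tipColor,
      backgroundColor = backgroundColor, noiseSd = noiseSd,
      seed = as.integer(seed))
}

setMethod("show", "SpatheParams", function(object) {
  cat(sprintf(
    "SpatheParams: %dpx canvas, scale %.1f, aspect %.2f, tip %.2f, rot %.0f deg, seed %d\n",
    object@canvasSize, object@scale, object@aspect, object@tipSharpness,
    object@rotation, object@seed))
})

# ---------------------------------------------------------------------------

.BINS <- list(c(0, .1), c(.1, .2), c(.2, .3), c(.3, .4), c(.4, .5))

#' Occlusion mask specification
#'
#' One cell of the occlusion taxonomy: a missing type (where on the organ the
#' occluder sits) and a missing-proportion bin (fraction of the organ's area
#' covered). Five bins of width 10% span 0--50%.
#'
#' @slot missingType one of \code{"top"}, \code{"side"}, \code{"bottom"}.
#' @slot binLow,binHigh bin bounds; \code{(binLow, binHigh)} must be one of
#'   (0,.1), (.1,.2), (.2,.3), (.3,.4), (.4,.5); the degenerate (0,0) is
#'   allowed and means "no hole".
#' @slot side for \code{missingType="side"}: \code{"left"}, \code{"right"} or
#'   \code{"random"}.
#' @slot seed integer seed for the mask draw.
#' @seealso [generateMask()], [buildTestGrid()]
#' @export
setClass("MaskSpec", representation(
  missingType = "character", binLow = "numeric", binHigh = "numeric",
  side = "character", seed = "integer"))

setValidity("MaskSpec", function(object) {
  msg <- character()
  if (!object@missingType %in% c("top", "side", "bottom"))
    msg <- c(msg, "missingType must be top, side or bottom")
  okBin <- (object@binLow == 0 && object@binHigh == 0) ||
    any(vapply(.BINS, function(b)
      isTRUE(all.equal(b, c(object@binLow, object@binHigh))), logical(1)))
  if (!okBin) msg <- c(msg, "bin must be one of (0,.1),(.1,.2),...,(.4,.5) or (0,0)")
  if (!object@side %in% c("left", "right", "random"))
    msg <- c(msg, "side must be left, right or random")
  if (length(msg)) msg else TRUE
})

#' @describeIn MaskSpec-class Constructor. `bin` may be a bin index (1..5) or
#'   a `c(low, high)` pair.
#' @param missingType,side,seed see slots.
#' @param bin bin index in 1..5, or numeric `c(low, high)`.
#' @export
MaskSpec <- function(missingType, bin, side = "random", seed = 1L) {
  if (length(bin) == 1) bin <- .BINS[[bin]]
  new("MaskSpec", missingType = missingType, binLow = bin[1], binHigh = bin[2],
      side = side, seed = as.integer(seed))
}

#' @describeIn MaskSpec-class Missing-type accessor.
#' @param x a `MaskSpec`.
#' @export
missingType <- function(x) x@missingType

#' @describeIn MaskSpec-class Bin accessor, returns `c(low, high)`.
#' @export
binRange <- function(x) c(x@binLow, x@binHigh)

setMethod("show", "MaskSpec", function(object) {
  cat(sprintf("MaskSpec: %s missing, %.0f-%.0f%%, side=%s, seed %d\n",
              object@missingType, 100 * object@binLow, 100 * object@binHigh,
              object@side, object@seed))
})

# ---------------------------------------------------------------------------

#' Joint-loss weights
#'
#' Coefficients of the joint training objective
#' \deqn{L_{sum} = \lambda_{hole} L_{hole} + \lambda_{valid} L_{valid} +
#'   \lambda_{perc} L_{perc} + \lambda_{style} L_{style}.}
#' Defaults are the published operating point:
#' \eqn{\lambda_{hole}=1,\ \lambda_{valid}=6,\ \lambda_{perc}=0.05,\
#' \lambda_{style}=120}.
#'
#' @slot hole,valid,perceptual,style non-negative reals.
#' @seealso [jointLoss()]
#' @export
setClass("LossWeights", representation(
  hole = "numeric", valid = "numeric", perceptual = "numeric",
  style = "numeric"))

setValidity("LossWeights", function(object) {
  v <- c(object@hole, object@valid, object@perceptual, object@style)
  if (any(v < 0)) "all loss weights must be >= 0" else TRUE
})

#' @describeIn LossWeights-class Constructor with the published defaults.
#' @param hole,valid,perceptual,style see slots.
#' @export
LossWeights <- function(hole = 1, valid = 6, perceptual = 0.05, style = 120) {
  new("LossWeights", hole = hole, valid = valid, perceptual = perceptual,
      style = style)
}

#' @describeIn LossWeights-class Weights as a named numeric vector.
#' @param x a `LossWeights`.
#' @export
lossWeightVector <- function(x)
  c(hole = x@hole, valid = x@valid, perceptual = x@perceptual, style = x@style)

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights: hole=%g valid=%g perceptual=%g style=%g\n",
              object@hole, object@valid, object@perceptual, object@style))
})

# ---------------------------------------------------------------------------

#' Polar contour of a star-convex region
#'
#' Radii \eqn{r(\theta_k)} sampled on a uniform angular grid
#' \eqn{\theta_k = 2\pi k/N}, \eqn{k = 0..N-1}, about the region centroid.
#' Angles follow the image-mathematics frame: \eqn{\theta = 0} points
#' horizontally right, positive angles run counterclockwise (y up).
#'
#' @slot radii numeric vector of N radii, pixels.
#' @slot pole centroid `(row, col)` used as the pole.
#' @slot starConvex logical; FALSE if the region violated star-convexity and
#'   the max-radius rule was applied.
#' @seealso [polarContour()], [contourMSE()]
#' @export
setClass("PolarContour", representation(
  radii = "numeric", pole = "numeric", starConvex = "logical"))

setValidity("PolarContour", function(object) {
  if (length(object@radii) < 3) return("need at least 3 angular samples")
  if (any(!is.finite(object@radii)) || any(object@radii < 0))
    return("radii must be finite and non-negative")
  TRUE
})

#' @describeIn PolarContour-class Radii accessor.
#' @param x a `PolarContour`.
#' @export
radii <- function(x) x@radii

#' @describeIn PolarContour-class Pole (centroid) accessor.
#' @export
pole <- function(x) x@pole

#' @describeIn PolarContour-class Number of angular samples.
#' @export
nAngles <- function(x) length(x@radii)

setMethod("show", "PolarContour", function(object) {
  cat(sprintf(
    "PolarContour: N=%d, pole=(%.1f, %.1f), r in [%.1f, %.1f] px%s\n",
    length(object@radii), object@pole[1], object@pole[2],
    min(object@radii), max(object@radii),
    if (object@starConvex) "" else " [non-star-convex, max-radius rule]"))
})

# ---------------------------------------------------------------------------

#' Network architecture configuration
#'
#' @slot imageSize input side length, pixels; must be divisible by
#'   `4 * 2^encoderDepth` (two strided front-end convolutions put the
#'   reasoning module at 1/4 resolution, and each reasoning encoder level
#'   halves once more).
#' @slot baseChannels width of the first front-end convolution; the reasoning
#'   module works at `2 * baseChannels` channels.
#' @slot recurrenceCount number of identify-then-reason rounds.
#' @slot encoderDepth number of downsampling levels inside the reasoning
#'   encoder-decoder.
#' @slot leakySlope negative slope of the LeakyReLU activations.
#' @slot useAttention reserved extension point; must be FALSE.
#' @seealso [createModel()]
#' @export
setClass("ModelConfig", representation(
  imageSize = "integer", baseChannels = "integer", recurrenceCount = "integer",
  encoderDepth = "integer", leakySlope = "numeric", useAttention = "logical"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  need <- 4L * 2L^object@encoderDepth
  if (object@imageSize %% need != 0)
    msg <- c(msg, sprintf("imageSize must be divisible by %d", need))
  if (object@baseChannels < 4) msg <- c(msg, "baseChannels must be >= 4")
  if (object@recurrenceCount < 1) msg <- c(msg, "recurrenceCount must be >= 1")
  if (object@encoderDepth < 1) msg <- c(msg, "encoderDepth must be >= 1")
  if (object@useAttention) msg <- c(msg, "attention extension not implemented")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelConfig-class Constructor; defaults target 256 px inputs.
#' @param imageSize,baseChannels,recurrenceCount,encoderDepth,leakySlope,useAttention see slots.
#' @export
ModelConfig <- function(imageSize = 256L, baseChannels = 32L,
                        recurrenceCount = 6L, encoderDepth = 3L,
                        leakySlope = 0.01, useAttention = FALSE) {
  new("ModelConfig", imageSize = as.integer(imageSize),
      baseChannels = as.integer(baseChannels),
      recurrenceCount = as.integer(recurrenceCount),
      encoderDepth = as.integer(encoderDepth), leakySlope = leakySlope,
      useAttention = useAttention)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %dpx, base %d ch, %d recurrences, encoder depth %d\n",
    object@imageSize, object@baseChannels, object@recurrenceCount,
    object@encoderDepth))
})

# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @slot learningRate Adam learning rate (default 2e-4, the published value).
#' @slot batchSize images per step (published value 4).
#' @slot iterations number of optimizer steps (published run: 120000).
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot seed integer seed controlling batching, masking and augmentation.
#' @slot augScale,augRotate,augTranslate augmentation ranges: scale factor
#'   interval, max |rotation| in degrees, max |translation| in pixels.
#' @slot checkpointEvery write a checkpoint every this many steps (0 = only
#'   at the end).
#' @seealso [fitModel()]
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", batchSize = "integer", iterations = "integer",
  beta1 = "numeric", beta2 = "numeric", seed = "integer",
  augScale = "numeric", augRotate = "numeric", augTranslate = "numeric",
  checkpointEvery = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@iterations < 0) msg <- c(msg, "iterations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig-class Constructor with the published defaults.
#' @param learningRate,batchSize,iterations,beta1,beta2,seed,augScale,augRotate,augTranslate,checkpointEvery see slots.
#' @export
TrainConfig <- function(learningRate = 2e-4, batchSize = 4L,
                        iterations = 120000L, beta1 = 0.9, beta2 = 0.999,
                        seed = 1L, augScale = c(0.9, 1.1), augRotate = 20,
                        augTranslate = 8, checkpointEvery = 0L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), iterations = as.integer(iterations),
      beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
      augScale = augScale, augRotate = augRotate, augTranslate = augTranslate,
      checkpointEvery = as.integer(checkpointEvery))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: lr=%g, batch %d, %d iterations, seed %d\n",
              object@learningRate, object@batchSize, object@iterations,
              object@seed))
})
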