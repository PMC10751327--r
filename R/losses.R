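# Joint training objective: L1 content losses on the hole and valid regions
# plus perceptual and style (Gram) losses on the composited prediction,
# weighted by the published coefficients (hole 1, valid 6, perceptual 0.05,
# style 120).

#' Mean absolute error over a pixel region
#'
#' `sum(|pred - gt| . region) / (|region| * channels)`; 0 for an empty
#' region.
#'
#' @param pred,gt H x W x C arrays.
#' @param region binary H x W matrix (or H x W x C array) selecting pixels.
#' @return non-negative scalar.
#' @export
regionL1 <- function(pred, gt, region) {
  stopifnot(all(dim(pred) == dim(gt)))
  C <- if (length(dim(pred)) == 3) dim(pred)[3] else 1L
  if (is.matrix(region)) region <- rep3(region, C)
  den <- sum(region)
  if (den == 0) return(0)
  sum(abs(pred - gt) * region) / den
}

#' Gram matrix of a feature map
#'
#' `G = F F^T / (C H W)` with `F` the C x (HW) unfolding of the map:
#' channel co-activation statistics, the carrier of the style loss.
#'
#' @param feature H x W x C array.
#' @return symmetric positive semi-definite C x C matrix.
#' @export
gramMatrix <- function(feature) {
  stopifnot(length(dim(feature)) == 3)
  adValue(adGram(adConst(feature)))
}

#' Deterministic random-convolution feature extractor
#'
#' A fixed, seeded bank of strided 3x3 convolutions (3 -> 8 -> 16 -> 32
#' channels, LeakyReLU 0.1) used as the perceptual/style feature space.
#' Random convolutional features are a standard self-contained perceptual
#' basis; a pretrained VGG-style extractor can be substituted by passing any
#' function mapping an image node to a list of feature nodes.
#'
#' @param seed integer seed fixing the bank.
#' @param channels channel widths of the stages.
#' @return extractor closure: `function(node) -> list of feature nodes`.
#' @export
randomFeatureExtractor <- function(seed = 20231213L, channels = c(8L, 16L, 32L)) {
  cin <- 3L
  ws <- withSeed(seed, lapply(channels, function(co) {
    w <- convInit(3, cin, co)
    cin <<- co
    w
  }))
  ws <- lapply(ws, function(p) list(w = adConst(p$w), b = adConst(p$b)))
  function(x) {
    outs <- vector("list", length(ws))
    h <- x
    for (i in seq_along(ws)) {
      h <- adLeakyRelu(adConv(h, ws[[i]]$w, ws[[i]]$b, 2L, 1L), 0.1)
      outs[[i]] <- h
    }
    outs
  }
}

#' Identity feature extractor
#'
#' Returns the image itself as the single feature map; under it the
#' perceptual loss reduces to whole-image L1. Useful for testing.
#'
#' @return extractor closure.
#' @export
identityExtractor <- function() function(x) list(x)

# Node-level perceptual + style losses; gt is a plain array.
psLossNodes <- function(predNode, gt, extractor) {
  fp <- extractor(predNode)
  fg <- extractor(adConst(gt))
  percs <- list(); styles <- list()
  for (i in seq_along(fp)) {
    tgt <- adValue(fg[[i]])
    percs[[i]] <- adL1(fp[[i]], tgt, 1, length(tgt))
    gp <- adGram(fp[[i]])
    gt_g <- adValue(adGram(fg[[i]]))
    styles[[i]] <- adL1(gp, gt_g, 1, length(gt_g))
  }
  list(perceptual = adScalarSum(percs, rep(1, length(percs))),
       style = adScalarSum(styles, rep(1, length(styles))))
}

#' Perceptual and style losses
#'
#' `L_perceptual = sum_layers mean|phi(pred) - phi(gt)|`;
#' `L_style = sum_layers mean|G(phi(pred)) - G(phi(gt))|` with `G` the
#' normalized Gram matrix.
#'
#' @param pred,gt H x W x 3 arrays.
#' @param extractor feature extractor closure, e.g.
#'   [randomFeatureExtractor()].
#' @return named numeric `c(perceptual=, style=)`.
#' @export
perceptualStyleLosses <- function(pred, gt,
                                  extractor = randomFeatureExtractor()) {
  r <- psLossNodes(adConst(pred), gt, extractor)
  c(perceptual = adValue(r$perceptual), style = adValue(r$style))
}

#' Loss breakdown
#'
#' Components and weighted sum of the joint objective.
#'
#' @slot hole,valid,perceptual,style,sum non-negative reals;
#'   `sum` is the weighted combination of the four components.
#' @export
setClass("LossBreakdown", representation(
  hole = "numeric", valid = "numeric", perceptual = "numeric",
  style = "numeric", sum = "numeric"))

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf(
    "LossBreakdown: sum=%.5g (hole=%.5g valid=%.5g perc=%.5g style=%.5g)\n",
    object@sum, object@hole, object@valid, object@perceptual, object@style))
})

#' @describeIn LossBreakdown-class Components as a named numeric vector.
#' @param x a `LossBreakdown`.
#' @export
lossComponents <- function(x)
  c(hole = x@hole, valid = x@valid, perceptual = x@perceptual,
    style = x@style, sum = x@sum)

# Node-level joint loss; pred is a node, everything else plain data.
jointLossNodes <- function(predNode, gt, mask, weights, extractor,
                           validRegion = "known", foreground = NULL) {
  hole <- 1 - mask
  holeDen <- sum(hole) * 3
  holeN <- if (holeDen > 0) adL1(predNode, gt, rep3(hole, 3), holeDen)
           else adConst(0)
  vmask <- switch(validRegion,
                  known = mask,
                  image = matrix(1, nrow(mask), ncol(mask)),
                  foreground = {
                    if (is.null(foreground))
                      stop("validRegion='foreground' needs a foreground mask")
                    foreground
                  })
  vDen <- sum(vmask) * 3
  validN <- if (vDen > 0) adL1(predNode, gt, rep3(vmask, 3), vDen)
            else adConst(0)
  comp <- adAdd(adMulConst(predNode, rep3(hole, 3)),
                adConst(gt * rep3(mask, 3)))
  ps <- psLossNodes(comp, gt, extractor)
  coefs <- c(weights@hole, weights@valid, weights@perceptual, weights@style)
  total <- adScalarSum(list(holeN, validN, ps$perceptual, ps$style), coefs)
  list(hole = holeN, valid = validN, perceptual = ps$perceptual,
       style = ps$style, sum = total)
}

#' Joint completion loss
#'
#' Weighted sum of the hole-region L1, valid-region L1, perceptual and style
#' losses. The perceptual/style terms are evaluated on the composited
#' prediction (ground truth on known pixels, prediction in the hole).
#'
#' @param pred,gt H x W x 3 arrays.
#' @param mask binary H x W matrix, 1 = known.
#' @param weights a [LossWeights-class].
#' @param extractor feature extractor closure.
#' @param validRegion what the "valid" content loss covers: the known region
#'   (`"known"`, default), the whole image, or the organ foreground.
#' @param foreground binary matrix, required for
#'   `validRegion = "foreground"`.
#' @return a [LossBreakdown-class].
#' @export
jointLoss <- function(pred, gt, mask, weights = LossWeights(),
                      extractor = randomFeatureExtractor(),
                      validRegion = c("known", "image", "foreground"),
                      foreground = NULL) {
  validRegion <- match.arg(validRegion)
  r <- jointLossNodes(adConst(pred), gt, mask, weights, extractor,
                      validRegion, foreground)
  new("LossBreakdown", hole = adValue(r$hole), valid = adValue(r$valid),
      perceptual = adValue(r$perceptual), style = adValue(r$style),
      sum = adValue(r$sum))
}
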