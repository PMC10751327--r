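# Multi-scale recurrent feature reasoning network.
#
# Structure: two strided partial convolutions encode the masked image to 1/4
# resolution; then, for each recurrence, an area-identification step (two
# stride-1 partial convolutions) dilates the validity mask and names the thin
# ring to fill, and a reasoning step (an encoder-decoder whose every layer is
# an Inception block: parallel 1x1/3x3/5x5 convolutions plus 3x3 max pooling,
# concatenated and fused by a 3x3 convolution) predicts features inside the
# ring. Per-round feature maps are merged by validity-weighted averaging and
# decoded back to RGB. Reasoning weights are shared across recurrences --
# the parameter reuse that keeps the recurrent formulation compact.

heInit <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

convInit <- function(k, cin, cout) list(w = heInit(k, cin, cout),
                                        b = numeric(cout))

inceptionInit <- function(cin, bc, cout) {
  list(w1 = heInit(1, cin, bc), b1 = numeric(bc),
       w3 = heInit(3, cin, bc), b3 = numeric(bc),
       w5 = heInit(5, cin, bc), b5 = numeric(bc),
       wf = heInit(3, 3 * bc + cin, cout))
}

flattenParams <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) out <- c(out, flattenParams(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

#' Create a multi-scale recurrent feature reasoning model
#'
#' Initializes all network weights (He-normal, zero biases) for the
#' architecture described by a [ModelConfig-class]. The reasoning module
#' works at `F = 2 * baseChannels` channels and 1/4 input resolution; every
#' Inception block uses `max(4, F/4)` channels per branch.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for weight initialization.
#' @return an object of class `rfrModel`: a list with `config` and a flat
#'   named list `params` of weight arrays.
#' @examples
#' m <- createModel(ModelConfig(imageSize = 32L, baseChannels = 8L,
#'                              encoderDepth = 1L, recurrenceCount = 2L))
#' m
#' @export
createModel <- function(config = ModelConfig(), seed = 1L) {
  validObject(config)
  C <- config@baseChannels
  Fc <- 2L * C
  bc <- max(4L, Fc %/% 4L)
  C2 <- max(4L, C %/% 2L)
  d <- config@encoderDepth
  p <- withSeed(seed, {
    p <- list(front1 = convInit(5, 3, C), front2 = convInit(5, C, Fc),
              ai1 = convInit(3, Fc, Fc), ai2 = convInit(3, Fc, Fc))
    for (l in seq_len(d)) {
      p[[paste0("enc", l)]] <- inceptionInit(Fc, bc, Fc)
      p[[paste0("dec", l)]] <- inceptionInit(2L * Fc, bc, Fc)
    }
    p$bottleneck <- inceptionInit(Fc, bc, Fc)
    p$rout <- convInit(3, Fc, Fc)
    # decode head mirrors the front end: skip-concat of the half-resolution
    # front-end activation, then of the masked input image
    p$head1 <- convInit(3, Fc + C, C)
    p$head2 <- convInit(3, C + 3, C2)
    p$out <- convInit(1, C2, 3)
    p
  })
  structure(list(config = config, params = flattenParams(p)),
            class = "rfrModel")
}

#' @export
print.rfrModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("rfrModel: %d parameters\n", np))
  print(x$config)
  invisible(x)
}

# Wrap a flat param list as autodiff leaves (trainable) or constants.
paramNodes <- function(params, trainable = TRUE) {
  f <- if (trainable) adLeaf else adConst
  lapply(params, f)
}

zeroBias <- function(cout) adConst(numeric(cout))

# ---- partial convolution --------------------------------------------------

# Node-level partial convolution. Mask arithmetic is pure bookkeeping (not
# differentiated): output = (W (x . m)) * (k^2 / valid_count) + b wherever the
# window saw at least one valid pixel, 0 elsewhere; the updated mask marks
# those locations valid.
pconvNode <- function(x, mask, w, b, stride = 1L, pad = 1L) {
  k <- dim(w$v)[1]
  cin <- dim(w$v)[3]; cout <- dim(w$v)[4]
  ones <- array(1, c(k, k, 1, 1))
  mc <- convRaw(array(mask, c(dim(mask), 1)), ones, 0, stride, pad)[, , 1]
  # normalize by the in-bounds window size, not k^2: zero padding is not
  # missing data, so a fully valid border window needs no boost
  wc <- convRaw(array(1, c(dim(mask), 1)), ones, 0, stride, pad)[, , 1]
  valid <- (mc > 0.5) + 0
  ratio <- valid * wc / pmax(mc, 1)
  y <- adConv(adMulConst(x, rep3(mask, cin)), w, zeroBias(cout), stride, pad)
  y <- adMulConst(y, rep3(ratio, cout))
  y <- adBias(y, b)
  y <- adMulConst(y, rep3(valid, cout))
  list(node = y, mask = valid)
}

#' Partial convolution over a masked feature map
#'
#' Convolution computed over valid (mask = 1) inputs only, renormalized at
#' each location by `in-bounds window size / valid count` (so a fully valid
#' window — including clipped border windows — is not rescaled); locations
#' whose window holds no valid pixel output 0. Also returns the updated
#' (dilated) validity mask.
#'
#' @param feature H x W x C array.
#' @param mask binary H x W matrix, 1 = valid.
#' @param kernel k x k x C x Cout array.
#' @param bias length-Cout numeric.
#' @param stride,pad convolution stride and zero padding.
#' @return list with `feature` (H' x W' x Cout) and `mask` (H' x W').
#' @export
partialConv <- function(feature, mask, kernel, bias = NULL,
                        stride = 1L, pad = (dim(kernel)[1] - 1L) %/% 2L) {
  if (is.matrix(feature)) feature <- array(feature, c(dim(feature), 1))
  if (any(mask != 0 & mask != 1)) stop("mask must be binary")
  if (is.null(bias)) bias <- numeric(dim(kernel)[4])
  r <- pconvNode(adConst(feature), mask, adConst(kernel), adConst(bias),
                 as.integer(stride), as.integer(pad))
  list(feature = adValue(r$node), mask = r$mask)
}

# ---- inception layer ------------------------------------------------------

inceptionNode <- function(x, p, slope) {
  h1 <- adRelu(adConv(x, p$w1, p$b1, 1L, 0L))
  h2 <- adRelu(adConv(x, p$w3, p$b3, 1L, 1L))
  h3 <- adRelu(adConv(x, p$w5, p$b5, 1L, 2L))
  h4 <- adMaxPool(x, 3L, 1L, 1L)
  fused <- adConv(adConcat(list(h1, h2, h3, h4)), p$wf,
                  zeroBias(dim(p$wf$v)[4]), 1L, 1L)
  adLeakyRelu(fused, slope)
}

#' Initialize a standalone Inception layer
#'
#' @param inChannels,branchChannels,outChannels channel counts: each of the
#'   three convolution branches produces `branchChannels` maps, the pooling
#'   branch preserves `inChannels`, and the 3x3 fusion maps the
#'   `3 * branchChannels + inChannels` concatenation to `outChannels`.
#' @param seed integer seed for weight initialization.
#' @return named list of weight arrays.
#' @export
initInceptionLayer <- function(inChannels, branchChannels, outChannels,
                               seed = 1L) {
  p <- withSeed(seed, inceptionInit(inChannels, branchChannels, outChannels))
  c(p, list(inChannels = inChannels, branchChannels = branchChannels,
            outChannels = outChannels))
}

#' Apply an Inception layer to a feature map
#'
#' Four parallel branches -- ReLU-activated 1x1, 3x3 and 5x5 convolutions and
#' a 3x3 stride-1 max pooling -- are concatenated channel-wise and fused by a
#' 3x3 convolution under a LeakyReLU. Spatial dimensions are preserved.
#'
#' @param feature H x W x C array with `C == layer$inChannels`.
#' @param layer as returned by [initInceptionLayer()].
#' @param leakySlope negative slope of the fusion activation.
#' @return H x W x outChannels array.
#' @export
inceptionLayer <- function(feature, layer, leakySlope = 0.01) {
  if (dim(feature)[3] != layer$inChannels)
    stop(sprintf("channel mismatch: feature has %d, layer expects %d",
                 dim(feature)[3], layer$inChannels))
  p <- lapply(layer[c("w1", "b1", "w3", "b3", "w5", "b5", "wf")], adConst)
  adValue(inceptionNode(adConst(feature), p, leakySlope))
}

# ---- recurrent structure --------------------------------------------------

# Pull the sub-list of P whose names start with "<nm>." into branch names.
subParams <- function(P, nm) {
  pre <- paste0(nm, ".")
  keep <- startsWith(names(P), pre)
  stats::setNames(P[keep], substring(names(P)[keep], nchar(pre) + 1L))
}

areaIdentifyNode <- function(f, mask, P, slope, record = NULL, tag = "") {
  a1 <- pconvNode(f, mask, P[["ai1.w"]], P[["ai1.b"]], 1L, 1L)
  h <- adLeakyRelu(a1$node, slope)
  a2 <- pconvNode(h, a1$mask, P[["ai2.w"]], P[["ai2.b"]], 1L, 1L)
  h2 <- adLeakyRelu(a2$node, slope)
  if (!is.null(record)) record[[paste0(tag, "ai")]] <- h2$v
  list(feature = h2, mask = a2$mask, infer = a2$mask - mask)
}

reasoningNode <- function(f, P, cfg, record = NULL, tag = "") {
  slope <- cfg@leakySlope
  d <- cfg@encoderDepth
  skips <- vector("list", d)
  h <- f
  for (l in seq_len(d)) {
    h <- inceptionNode(h, subParams(P, paste0("enc", l)), slope)
    if (!is.null(record)) record[[paste0(tag, "enc", l)]] <- h$v
    skips[[l]] <- h
    h <- adMaxPool(h, 2L, 2L, 0L)
  }
  h <- inceptionNode(h, subParams(P, "bottleneck"), slope)
  if (!is.null(record)) record[[paste0(tag, "bottleneck")]] <- h$v
  for (l in rev(seq_len(d))) {
    h <- adUpsample2(h)
    h <- adConcat(list(h, skips[[l]]))
    h <- inceptionNode(h, subParams(P, paste0("dec", l)), slope)
    if (!is.null(record)) record[[paste0(tag, "dec", l)]] <- h$v
  }
  h <- adConv(h, P[["rout.w"]], P[["rout.b"]], 1L, 1L)
  if (!is.null(record)) record[[paste0(tag, "out")]] <- h$v
  h
}

# One identify-then-reason round. Known-region features pass through; the
# reasoning output replaces features outside the incoming validity mask, and
# the mask absorbs the identified ring.
reasoningRoundNode <- function(f, mask, P, cfg, record = NULL, tag = "") {
  ai <- areaIdentifyNode(f, mask, P, cfg@leakySlope, record, tag)
  r <- reasoningNode(ai$feature, P, cfg, record, tag)
  C <- dim(f$v)[3]
  fnew <- adAdd(adMulConst(f, rep3(mask, C)),
                adMulConst(r, rep3(1 - mask, C)))
  list(feature = fnew, mask = ai$mask, infer = ai$infer)
}

featureMergeNode <- function(features, masks) {
  C <- dim(features[[1]]$v)[3]
  denom <- Reduce(`+`, masks)
  acc <- NULL
  for (i in seq_along(features)) {
    term <- adMulConst(features[[i]], rep3(masks[[i]], C))
    acc <- if (is.null(acc)) term else adAdd(acc, term)
  }
  inv <- ifelse(denom > 0, 1 / pmax(denom, 1), 0)
  merged <- adMulConst(acc, rep3(inv, C))
  never <- (denom == 0) + 0
  if (any(never > 0)) {
    merged <- adAdd(merged,
                    adMulConst(features[[length(features)]], rep3(never, C)))
  }
  merged
}

decodeNode <- function(merged, skipHalf, input, P, cfg, record = NULL) {
  slope <- cfg@leakySlope
  h <- adConcat(list(adUpsample2(merged), skipHalf))
  h <- adLeakyRelu(adConv(h, P[["head1.w"]], P[["head1.b"]], 1L, 1L), slope)
  if (!is.null(record)) record[["head1"]] <- h$v
  h <- adConcat(list(adUpsample2(h), input))
  h <- adLeakyRelu(adConv(h, P[["head2.w"]], P[["head2.b"]], 1L, 1L), slope)
  if (!is.null(record)) record[["head2"]] <- h$v
  adSigmoid(adConv(h, P[["out.w"]], P[["out.b"]], 1L, 0L))
}

# Full forward pass on the tape. Returns prediction and composite nodes plus
# per-round feature states.
forwardNode <- function(P, image, mask, cfg, record = NULL) {
  x <- adConst(image * rep3(mask, 3))
  f1 <- pconvNode(x, mask, P[["front1.w"]], P[["front1.b"]], 2L, 2L)
  hHalf <- adLeakyRelu(f1$node, cfg@leakySlope)
  if (!is.null(record)) record[["front1"]] <- hHalf$v
  f2 <- pconvNode(hHalf, f1$mask, P[["front2.w"]], P[["front2.b"]], 2L, 2L)
  h <- adLeakyRelu(f2$node, cfg@leakySlope)
  if (!is.null(record)) record[["front2"]] <- h$v
  fmask <- f2$mask
  feats <- list(); masks <- list()
  for (t in seq_len(cfg@recurrenceCount)) {
    rd <- reasoningRoundNode(h, fmask, P, cfg, record, sprintf("r%d.", t))
    h <- rd$feature
    fmask <- rd$mask
    feats[[t]] <- h
    masks[[t]] <- fmask
  }
  merged <- featureMergeNode(feats, masks)
  if (!is.null(record)) record[["merge"]] <- merged$v
  pred <- decodeNode(merged, hHalf, x, P, cfg, record)
  if (!is.null(record)) record[["pred"]] <- pred$v
  completed <- adAdd(adMulConst(pred, rep3(1 - mask, 3)),
                     adConst(image * rep3(mask, 3)))
  list(pred = pred, completed = completed, features = feats,
       featureMasks = masks)
}

#' Area identification step
#'
#' Applies the model's fixed stack of two stride-1 partial convolutions to a
#' feature state. The updated validity mask is a dilation of the input mask;
#' their difference is the ring of feature locations to fill this round.
#'
#' @param model an `rfrModel`.
#' @param feature H' x W' x F array at the reasoning resolution.
#' @param mask binary H' x W' validity mask.
#' @return list with `feature`, `mask` (updated) and `inferRegion`
#'   (`mask_updated - mask`).
#' @export
areaIdentify <- function(model, feature, mask) {
  P <- paramNodes(model$params, trainable = FALSE)
  r <- areaIdentifyNode(adConst(feature), mask, P, model$config@leakySlope)
  list(feature = adValue(r$feature), mask = r$mask, inferRegion = r$infer)
}

#' Reasoning pass
#'
#' One identify-then-reason round on a feature state: the Inception
#' encoder-decoder predicts features inside the identified ring; known
#' features pass through unchanged; the mask absorbs the ring.
#'
#' @inheritParams areaIdentify
#' @return list with `feature` and `mask`.
#' @export
reasoningPass <- function(model, feature, mask) {
  P <- paramNodes(model$params, trainable = FALSE)
  r <- reasoningRoundNode(adConst(feature), mask, P, model$config)
  list(feature = adValue(r$feature), mask = r$mask)
}

#' Merge per-round feature states
#'
#' Validity-weighted average: each location averages the feature values of
#' the rounds in which it was valid; locations never valid take the last
#' round's value.
#'
#' @param features list of H x W x C arrays.
#' @param masks list of binary H x W matrices, one per round.
#' @return H x W x C array.
#' @export
featureMerge <- function(features, masks) {
  if (!length(features)) stop("empty feature list")
  stopifnot(length(features) == length(masks))
  nodes <- lapply(features, adConst)
  adValue(featureMergeNode(nodes, masks))
}

#' Complete an occluded image
#'
#' Runs the full recurrent inference: front-end partial-convolution encoding,
#' `recurrenceCount` identify-then-reason rounds, validity-weighted feature
#' merging and decoding. The output composites the network prediction into
#' the hole only: known pixels are returned bit-for-bit.
#'
#' @param model an `rfrModel`.
#' @param image H x W x 3 array in [0, 1], `H = W = imageSize`.
#' @param mask binary H x W matrix, 1 = known pixel.
#' @return list with `completed` and `pred` (H x W x 3 arrays), and
#'   `states`: per-round `featureMasks` (validity masks at reasoning
#'   resolution) and `features`.
#' @export
recurrentInference <- function(model, image, mask) {
  cfg <- model$config
  stopifnot(all(dim(image)[1:2] == cfg@imageSize),
            all(dim(mask) == cfg@imageSize))
  if (any(mask != 0 & mask != 1)) stop("mask must be binary")
  P <- paramNodes(model$params, trainable = FALSE)
  out <- forwardNode(P, image, mask, cfg)
  list(completed = adValue(out$completed), pred = adValue(out$pred),
       states = list(features = lapply(out$features, adValue),
                     featureMasks = out$featureMasks))
}
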