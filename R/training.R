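# Training: Adam on the joint objective with on-the-fly random occlusion
# masks, geometric augmentation, periodic checkpoints and a reproducible
# loss log.

#' Geometric augmentation of an image/foreground pair
#'
#' Applies one random scale-rotate-translate transform (drawn from the
#' current RNG stream) identically to the image (bilinear) and foreground
#' mask (thresholded bilinear). Draws are retried until the foreground stays
#' fully inside the canvas; identity ranges return the input unchanged.
#'
#' @param image H x W x 3 array.
#' @param foreground binary H x W matrix.
#' @param scale length-2 scale-factor range.
#' @param rotate maximum |rotation| in degrees.
#' @param translate maximum |translation| in pixels per axis.
#' @param maxTries bounded number of redraws before an error.
#' @return list with `image` and `foreground`.
#' @export
augmentSample <- function(image, foreground, scale = c(0.9, 1.1),
                          rotate = 20, translate = 8, maxTries = 20L) {
  if (scale[1] == 1 && scale[2] == 1 && rotate == 0 && translate == 0)
    return(list(image = image, foreground = foreground))
  d <- dim(foreground)
  for (try in seq_len(maxTries)) {
    s <- runif(1, scale[1], scale[2])
    ang <- runif(1, -rotate, rotate)
    tr <- runif(2, -translate, translate)
    out <- affineTransform(image, foreground, scale = s, angle = ang,
                           translate = tr)
    fg <- out$foreground
    if (sum(fg) < 16) next
    border <- c(fg[1:2, ], fg[d[1] - 1:0, ], fg[, 1:2], fg[, d[2] - 1:0])
    if (any(border == 1)) next
    return(out)
  }
  stop("augmentation failed to keep the foreground inside the canvas")
}

#' Deterministic scale-rotate-translate warp about the canvas centre
#'
#' The geometric core of [augmentSample()]: bilinear resampling for the
#' image (out-of-canvas reads fall back to the median background colour),
#' thresholded bilinear for the foreground mask. The same transform is
#' applied to both.
#'
#' @inheritParams augmentSample
#' @param scale scale factor.
#' @param angle rotation in degrees, counterclockwise.
#' @param translate `(row, col)` shift in pixels.
#' @return list with `image` and `foreground`.
#' @export
affineTransform <- function(image, foreground, scale = 1, angle = 0,
                            translate = c(0, 0)) {
  d <- dim(foreground)
  ctr <- (d + 1) / 2
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  ang <- angle * pi / 180
  # inverse map: output pixel -> source location
  dr <- rows - ctr[1] - translate[1]
  dc <- cols - ctr[2] - translate[2]
  sr <- (cos(ang) * dr - sin(ang) * dc) / scale + ctr[1]
  sc <- (sin(ang) * dr + cos(ang) * dc) / scale + ctr[2]
  fg <- (bilinearSample(foreground, sr, sc) >= 0.5) + 0
  img <- array(0, dim(image))
  for (ch in 1:3) {
    bgfill <- median(image[, , ch][foreground == 0])
    v <- bilinearSample(image[, , ch], sr, sc)
    oob <- sr < 1 | sr > d[1] | sc < 1 | sc > d[2]
    v[oob] <- bgfill
    img[, , ch] <- v
  }
  list(image = img, foreground = fg)
}

# Random taxonomy cell for training-time masking, drawn from the current RNG
# stream. Type frequencies mirror where occluders actually sit: mostly the
# side and the bottom (root), a few on the top.
randomMaskSpec <- function() {
  ty <- sample(c("side", "bottom", "top"), 1, prob = c(0.5, 0.3, 0.2))
  MaskSpec(ty, sample.int(5L, 1),
           seed = sample.int(.Machine$integer.max - 1L, 1))
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' One optimizer step
#'
#' Forward (full recurrent inference), joint-loss backward and one Adam
#' update, averaged over the batch.
#'
#' @param model an `rfrModel`.
#' @param batch list of samples, each a list with `image` (ground truth),
#'   `mask` (binary, 1 = known); an optional `foreground` is passed to the
#'   loss when `validRegion = "foreground"`.
#' @param weights a [LossWeights-class].
#' @param opt optimizer state from [adamInit()] (created if `NULL`).
#' @param lr,beta1,beta2 Adam hyper-parameters.
#' @param extractor perceptual/style feature extractor.
#' @param validRegion see [jointLoss()].
#' @return list with updated `model`, `opt` and the batch-mean `loss`
#'   ([LossBreakdown-class]).
#' @export
trainStep <- function(model, batch, weights = LossWeights(), opt = NULL,
                      lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                      extractor = randomFeatureExtractor(),
                      validRegion = "known") {
  if (is.null(opt)) opt <- adamInit(model$params)
  nb <- length(batch)
  gacc <- NULL
  comp <- c(hole = 0, valid = 0, perceptual = 0, style = 0, sum = 0)
  for (s in batch) {
    P <- paramNodes(model$params, trainable = TRUE)
    out <- forwardNode(P, s$image, s$mask, model$config)
    ln <- jointLossNodes(out$pred, s$image, s$mask, weights, extractor,
                         validRegion, s$foreground)
    vals <- vapply(ln, adValue, numeric(1))
    if (any(!is.finite(vals)))
      stop(sprintf(
        "non-finite loss (hole=%g valid=%g perc=%g style=%g) at step %d",
        vals[1], vals[2], vals[3], vals[4], opt$t + 1L))
    comp <- comp + vals / nb
    adBackward(ln$sum)
    g <- lapply(P, function(p) p$g)
    if (is.null(gacc)) {
      gacc <- lapply(g, function(x) if (is.null(x)) 0 else x)
    } else {
      for (nm in names(g)) if (!is.null(g[[nm]]))
        gacc[[nm]] <- gacc[[nm]] + g[[nm]]
    }
  }
  gacc <- lapply(gacc, function(x) x / nb)
  upd <- adamStep(model$params, gacc, opt, lr, beta1, beta2)
  model$params <- upd$params
  list(model = model,
       opt = upd$opt,
       loss = new("LossBreakdown", hole = comp[["hole"]],
                  valid = comp[["valid"]], perceptual = comp[["perceptual"]],
                  style = comp[["style"]], sum = comp[["sum"]]))
}

#' Fit the model on a dataset
#'
#' Runs `config@iterations` optimizer steps. Each step samples a batch,
#' augments each image/foreground pair, draws a random occlusion mask
#' (type frequencies side 0.5 / bottom 0.3 / top 0.2, bins uniform) and
#' calls [trainStep()]. The loss log is fully reproducible under the
#' config seed; a run can be resumed bit-identically from a checkpoint
#' because the checkpoint captures the optimizer state and RNG stream.
#'
#' @param model an `rfrModel` (ignored when `resume` is given).
#' @param dataset list of samples with `image` and `foreground`, e.g. from
#'   [generateSpatheDataset()].
#' @param config a [TrainConfig-class].
#' @param weights a [LossWeights-class].
#' @param extractor perceptual/style feature extractor.
#' @param outDir directory for checkpoints and the loss-log CSV (`NULL`:
#'   keep everything in memory).
#' @param resume path to a checkpoint to resume from.
#' @param verbose print the loss every 50 steps.
#' @return list with the trained `model`, the loss `log` data.frame
#'   (`step, L_hole, L_valid, L_perceptual, L_style, L_sum`) and
#'   `checkpoint` (final checkpoint path or `NULL`).
#' @export
fitModel <- function(model, dataset, config = TrainConfig(),
                     weights = LossWeights(),
                     extractor = randomFeatureExtractor(), outDir = NULL,
                     resume = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  logRows <- list()
  opt <- NULL
  step0 <- 0L
  if (!is.null(resume)) {
    ck <- loadCheckpoint(resume)
    model <- ck$model
    opt <- ck$opt
    step0 <- ck$step
    if (!is.null(ck$rngState))
      assign(".Random.seed", ck$rngState, envir = globalenv())
    if (!is.null(ck$log)) logRows <- split(ck$log, seq_len(nrow(ck$log)))
  } else {
    set.seed(config@seed)
  }
  if (is.null(opt)) opt <- adamInit(model$params)
  writeCk <- function(step) {
    if (is.null(outDir)) return(NULL)
    path <- file.path(outDir, sprintf("checkpoint_%06d.rds", step))
    log <- if (length(logRows)) do.call(rbind, logRows) else NULL
    saveCheckpoint(model, path, opt = opt, step = step, log = log)
    if (!is.null(log))
      write.csv(log, file.path(outDir, "loss_log.csv"), row.names = FALSE)
    path
  }
  ckPath <- if (config@iterations == step0) writeCk(step0) else NULL
  for (step in seq_len(config@iterations - step0) + step0) {
    idx <- sample.int(length(dataset), config@batchSize,
                      replace = length(dataset) < config@batchSize)
    batch <- lapply(idx, function(i) {
      s <- dataset[[i]]
      a <- augmentSample(s$image, s$foreground, config@augScale,
                         config@augRotate, config@augTranslate)
      spec <- randomMaskSpec()
      mask <- generateMask(a$foreground, spec)
      list(image = a$image, mask = mask, foreground = a$foreground)
    })
    st <- trainStep(model, batch, weights, opt, lr = config@learningRate,
                    beta1 = config@beta1, beta2 = config@beta2,
                    extractor = extractor)
    model <- st$model
    opt <- st$opt
    lb <- st$loss
    logRows[[length(logRows) + 1L]] <- data.frame(
      step = step, L_hole = lb@hole, L_valid = lb@valid,
      L_perceptual = lb@perceptual, L_style = lb@style, L_sum = lb@sum)
    if (verbose && step %% 50 == 0)
      message(sprintf("step %d: L_sum=%.4f", step, lb@sum))
    if (config@checkpointEvery > 0 && step %% config@checkpointEvery == 0)
      ckPath <- writeCk(step)
  }
  if (!is.null(outDir)) ckPath <- writeCk(config@iterations)
  list(model = model,
       log = if (length(logRows)) do.call(rbind, c(logRows,
                                                   make.row.names = FALSE))
             else data.frame(),
       checkpoint = ckPath)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights, the architecture
#' configuration, and (when written during training) the optimizer state,
#' step counter, RNG stream and loss log, so training resumes
#' bit-identically.
#'
#' @param model an `rfrModel`.
#' @param path file path.
#' @param opt,step,log optional optimizer state, step count and loss log.
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: a list
#'   with `model`, `opt`, `step`, `rngState`, `log`.
#' @export
saveCheckpoint <- function(model, path, opt = NULL, step = 0L, log = NULL) {
  cfg <- model$config
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(
    params = model$params,
    config = list(imageSize = cfg@imageSize, baseChannels = cfg@baseChannels,
                  recurrenceCount = cfg@recurrenceCount,
                  encoderDepth = cfg@encoderDepth,
                  leakySlope = cfg@leakySlope),
    opt = opt, step = step, rngState = rng, log = log), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(ModelConfig, x$config)
  model <- structure(list(config = cfg, params = x$params),
                     class = "rfrModel")
  list(model = model, opt = x$opt, step = x$step %||% 0L,
       rngState = x$rngState, log = x$log)
}
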