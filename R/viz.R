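# Channel-wise feature-map diagnostics: separate every channel of a chosen
# reasoning-module layer and render normalized heatmap tiles. Comparing tiles
# between small- and large-hole inputs makes visible how much semantic
# content the encoder still extracts when most of the organ is missing
# (many near-inactive "cold" channels = little usable information).

#' Channel grid of a hooked layer
#'
#' @slot tiles list of H' x W' matrices normalized to [0, 1], one per
#'   channel.
#' @slot layer name of the hooked layer.
#' @slot layout `(rows, cols)` of the near-square tiling.
#' @export
setClass("ChannelGrid", representation(
  tiles = "list", layer = "character", layout = "integer"))

setValidity("ChannelGrid", function(object) {
  if (length(object@tiles) > prod(object@layout))
    return("layout too small for tile count")
  TRUE
})

setMethod("show", "ChannelGrid", function(object) {
  cat(sprintf("ChannelGrid: %d tiles of layer '%s' in a %dx%d layout\n",
              length(object@tiles), object@layer, object@layout[1],
              object@layout[2]))
})

#' Capture named layer activations during a forward pass
#'
#' Runs the full recurrent inference with read-only recording hooks and
#' returns the requested layers' outputs. Available names: `front1`,
#' `front2`, per-round `r<t>.ai`, `r<t>.enc<l>`, `r<t>.bottleneck`,
#' `r<t>.dec<l>`, `r<t>.out`, then `merge`, `head1`, `head2`, `pred`.
#' Recording never alters the forward computation.
#'
#' @param model an `rfrModel`.
#' @param image H x W x 3 array.
#' @param mask binary H x W matrix, 1 = known.
#' @param layers character vector of layer names; `NULL` captures all.
#' @return named list of activation arrays (plus the model output under
#'   attribute `"completed"`).
#' @export
captureActivations <- function(model, image, mask, layers = NULL) {
  record <- new.env(parent = emptyenv())
  P <- paramNodes(model$params, trainable = FALSE)
  out <- forwardNode(P, image, mask, model$config, record = record)
  acts <- as.list(record)
  if (!is.null(layers)) {
    unknown <- setdiff(layers, names(acts))
    if (length(unknown))
      stop("unknown layer(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(sort(names(acts)), collapse = ", "))
    acts <- acts[layers]
  } else {
    acts <- acts[sort(names(acts))]
  }
  attr(acts, "completed") <- adValue(out$completed)
  acts
}

# Map [0,1] values through a cold-to-hot colour ramp.
vizColormap <- function(x) {
  ramp <- colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#FFFF00",
                      "#FF0000", "#7F0000"))
  rgb <- ramp(c(x)) / 255
  out <- array(0, c(dim(x), 3))
  out[, , 1] <- rgb[, 1]; out[, , 2] <- rgb[, 2]; out[, , 3] <- rgb[, 3]
  out
}

#' Render a per-channel heatmap grid
#'
#' Min-max normalizes every channel (per channel by default, or against the
#' global range), tiles the channels row-major into a near-square layout and
#' optionally writes a colormapped PNG. Constant channels render as uniform
#' mid-value tiles.
#'
#' @param features H x W x C activation array.
#' @param perChannelNormalize normalize each channel by its own range.
#' @param file optional PNG output path.
#' @param layer layer name stored in the result.
#' @param sep separator width in pixels between tiles.
#' @return a [ChannelGrid-class], invisibly if `file` is given.
#' @export
renderChannelGrid <- function(features, perChannelNormalize = TRUE,
                              file = NULL, layer = "layer", sep = 1L) {
  stopifnot(length(dim(features)) == 3)
  C <- dim(features)[3]
  glo <- range(features)
  tiles <- lapply(seq_len(C), function(ch) {
    m <- features[, , ch]
    rg <- if (perChannelNormalize) range(m) else glo
    if (rg[2] - rg[1] < 1e-12) matrix(0.5, nrow(m), ncol(m))
    else (m - rg[1]) / (rg[2] - rg[1])
  })
  rows <- as.integer(ceiling(sqrt(C)))
  cols <- as.integer(ceiling(C / rows))
  grid <- new("ChannelGrid", tiles = tiles, layer = layer,
              layout = c(rows, cols))
  if (!is.null(file)) {
    th <- dim(features)[1]; tw <- dim(features)[2]
    H <- rows * th + (rows - 1L) * sep
    W <- cols * tw + (cols - 1L) * sep
    canvas <- matrix(0, H, W)
    for (ch in seq_len(C)) {
      r0 <- ((ch - 1L) %/% cols) * (th + sep)
      c0 <- ((ch - 1L) %% cols) * (tw + sep)
      canvas[r0 + seq_len(th), c0 + seq_len(tw)] <- tiles[[ch]]
    }
    writeImagePNG(vizColormap(canvas), file)
    return(invisible(grid))
  }
  grid
}

#' Per-channel activity summary
#'
#' Mean absolute activation per channel and the fraction of channels whose
#' activity falls below `thresholdFrac` times the global mean absolute
#' activation -- the quantitative counterpart of counting "cold" tiles in
#' the channel grid. A zero feature map has low-activity fraction 1.
#'
#' @param features H x W x C activation array.
#' @param thresholdFrac low-activity threshold as a fraction of the global
#'   mean absolute activation.
#' @return list with `meanAbs` (length-C numeric) and
#'   `lowActivityFraction`.
#' @export
channelActivitySummary <- function(features, thresholdFrac = 0.05) {
  stopifnot(length(dim(features)) == 3)
  scores <- apply(abs(features), 3, mean)
  glob <- mean(abs(features))
  low <- if (glob == 0) rep(TRUE, length(scores))
         else scores < thresholdFrac * glob
  list(meanAbs = scores, lowActivityFraction = mean(low))
}
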