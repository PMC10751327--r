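# PNG and YAML I/O. Images are H x W x 3 arrays in [0,1]; masks are H x W
# matrices in {0,1} serialized as 8-bit grayscale PNG with 0 = hole (black)
# and 255 = known (white).

#' Read / write RGB images and binary masks as PNG
#'
#' `readImagePNG` returns an H x W x 3 array in [0, 1] (grayscale images are
#' replicated across channels, alpha is dropped). `readMaskPNG` thresholds a
#' grayscale PNG at 0.5 into a 0/1 matrix (white = known). Writers are the
#' inverse operations, 8-bit.
#'
#' @param path PNG file path.
#' @param image H x W x 3 array in [0, 1].
#' @param mask binary H x W matrix.
#' @return the array/matrix, or (writers) the path invisibly.
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x
}

#' @rdname readImagePNG
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' @rdname readImagePNG
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x >= 0.5) + 0
}

#' @rdname readImagePNG
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Recognized sections: `model` ([ModelConfig-class] fields), `train`
#' ([TrainConfig-class] fields) and `loss` (`hole`, `valid`, `perceptual`,
#' `style`). Missing sections/fields fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with `model`, `train`, `loss` objects.
#' @export
loadConfigYAML <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  takeArgs <- function(section, fun) {
    args <- y[[section]] %||% list()
    ok <- intersect(names(args), names(formals(fun)))
    do.call(fun, args[ok])
  }
  list(model = takeArgs("model", ModelConfig),
       train = takeArgs("train", TrainConfig),
       loss = takeArgs("loss", LossWeights))
}
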