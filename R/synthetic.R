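# Synthetic spathe-image generator. Real capture data are not redistributable,
# so every downstream module is exercised on seeded renderings of a
# star-convex teardrop outline with a smooth base-to-tip colour gradient --
# the two properties the pipeline actually relies on: a single complete organ
# per image, and a contour that is single-valued in polar angle.

# Radial profile of the spathe outline; phi measured from the major axis.
spatheProfile <- function(phi, scale, aspect, tipSharpness) {
  r <- scale * (aspect + (1 - aspect) * cos(phi / 2)^2) *
    sqrt(pmax(1 + tipSharpness * cos(phi), 0))
  pmax(r, 1e-6)
}

#' Render one synthetic spathe image
#'
#' Rasterizes the star-convex teardrop outline described by a
#' [SpatheParams-class] onto a uniform background, paints the interior with a
#' linear base-to-tip colour gradient along the major axis, and adds seeded
#' Gaussian pixel noise. The foreground mask is a hard threshold (no
#' anti-aliasing), so its pixel count is exact.
#'
#' @param params a [SpatheParams-class].
#' @return list with `image` (H x W x 3 array in [0,1]), `foreground`
#'   (H x W matrix in \{0,1\}) and `params`.
#' @examples
#' s <- generateSpathe(SpatheParams(canvasSize = 64L, scale = 20))
#' mean(s$foreground)
#' @export
generateSpathe <- function(params) {
  validObject(params)
  n <- params@canvasSize
  cr <- params@center[1]; cc <- params@center[2]
  # math frame: x right, y up
  x <- matrix(rep(seq_len(n) - cc, each = n), n, n)
  y <- matrix(rep(cr - seq_len(n), times = n), n, n)
  alpha <- params@rotation * pi / 180
  # coordinates in the shape frame (major axis along +u)
  u <- x * cos(alpha) + y * sin(alpha)
  v <- -x * sin(alpha) + y * cos(alpha)
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  rmax <- spatheProfile(phi, params@scale, params@aspect, params@tipSharpness)
  fg <- (rho <= rmax) + 0
  if (sum(fg) < 16)
    stop("degenerate parameters: foreground nearly empty")
  # base-to-tip gradient along the major axis
  ufg <- u[fg == 1]
  tpos <- (u - min(ufg)) / max(max(ufg) - min(ufg), 1e-9)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    grad <- params@baseColor[ch] +
      clamp01(tpos) * (params@tipColor[ch] - params@baseColor[ch])
    img[, , ch] <- ifelse(fg == 1, grad, params@backgroundColor[ch])
  }
  if (params@noiseSd > 0) {
    img <- img + withSeed(params@seed,
                          array(rnorm(n * n * 3, sd = params@noiseSd),
                                c(n, n, 3)))
    img <- clamp01(img)
  }
  list(image = img, foreground = fg, params = params)
}

#' Check star-convexity of a binary region about its centroid
#'
#' Casts `nRays` rays from the region centroid and verifies that the
#' (bilinearly interpolated) inside indicator crosses from inside to outside
#' exactly once along every ray, i.e. the polar radius is single-valued.
#'
#' @param region binary H x W matrix.
#' @param nRays number of ray directions.
#' @param step radial sampling step in pixels.
#' @return logical.
#' @export
isStarConvex <- function(region, nRays = 360L, step = 0.5) {
  ctr <- regionCentroid(region)
  d <- dim(region)
  maxR <- sqrt(sum(d^2))
  theta <- 2 * pi * (seq_len(nRays) - 1) / nRays
  rs <- seq(0, maxR, by = step)
  # rows of the sample matrix: angles; cols: radii
  rows <- outer(-sin(theta), rs) + ctr[1]
  cols <- outer(cos(theta), rs) + ctr[2]
  inside <- bilinearSample(region, rows, cols) >= 0.5
  if (!all(inside[, 1])) return(FALSE)
  exits <- inside[, -ncol(inside), drop = FALSE] &
    !inside[, -1, drop = FALSE]
  all(rowSums(exits) == 1L)
}

# Bilinear interpolation of a matrix at fractional (row, col) positions;
# out-of-range positions read as 0.
bilinearSample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  dm <- dim(rows)
  v <- get(c(r0), c(c0)) * (1 - c(fr)) * (1 - c(fc)) +
    get(c(r0 + 1), c(c0)) * c(fr) * (1 - c(fc)) +
    get(c(r0), c(c0 + 1)) * (1 - c(fr)) * c(fc) +
    get(c(r0 + 1), c(c0 + 1)) * c(fr) * c(fc)
  if (!is.null(dm)) dim(v) <- dm
  v
}

#' Default per-sample jitter ranges for dataset generation
#'
#' The ranges define the synthetic study conditions: organ major semi-axis
#' 60--88 px on a 256 px canvas (foreground 10--30% of the canvas), free
#' rotation, moderate shape variation, +/- 10 px centre jitter and mild
#' colour jitter. For other canvas sizes the ranges are scaled
#' proportionally and then capped so the worst-case draw still respects the
#' 4 px canvas margin (small canvases also get a gentler apex range).
#'
#' @param canvasSize canvas side length the ranges must fit, pixels.
#' @return named list of ranges consumed by [generateSpatheDataset()].
#' @export
spatheJitter <- function(canvasSize = 256L) {
  sc <- canvasSize / 256
  j <- list(scale = c(60, 88) * sc, aspect = c(0.55, 0.95),
            tipSharpness = if (canvasSize < 96) c(0.1, 0.2) else c(0.1, 0.5),
            rotation = c(0, 360), centerJitter = 10 * sc,
            colorJitter = 0.08)
  cap <- (canvasSize / 2 - j$centerJitter - 5) / sqrt(1 + j$tipSharpness[2])
  j$scale[2] <- min(j$scale[2], cap)
  j$scale[1] <- max(8, min(j$scale[1], 0.75 * j$scale[2]))
  j$scale[2] <- max(j$scale[2], j$scale[1] + 0.5)
  j
}

#' Generate a dataset of synthetic spathe images
#'
#' Draws `n` independent parameter jitters around `base` and renders each.
#' Identical `(n, base, jitter, seed)` give bit-identical output.
#'
#' @param n number of images (>= 1).
#' @param base a [SpatheParams-class] supplying non-jittered fields.
#' @param jitter named ranges as returned by [spatheJitter()]; defaults to
#'   the ranges fitting the base canvas.
#' @param seed integer seed.
#' @return list of `n` elements, each as returned by [generateSpathe()].
#' @export
generateSpatheDataset <- function(n, base = SpatheParams(), jitter = NULL,
                                  seed = 1L) {
  stopifnot(n >= 1)
  if (is.null(jitter)) jitter <- spatheJitter(base@canvasSize)
  draws <- withSeed(seed, lapply(seq_len(n), function(i) {
    list(scale = runif(1, jitter$scale[1], jitter$scale[2]),
         aspect = runif(1, jitter$aspect[1], jitter$aspect[2]),
         tip = runif(1, jitter$tipSharpness[1], jitter$tipSharpness[2]),
         rot = runif(1, jitter$rotation[1], jitter$rotation[2]),
         dc = runif(2, -jitter$centerJitter, jitter$centerJitter),
         colb = runif(3, -jitter$colorJitter, jitter$colorJitter),
         colt = runif(3, -jitter$colorJitter, jitter$colorJitter),
         seed = sample.int(.Machine$integer.max - 1L, 1))
  }))
  lapply(draws, function(d) {
    p <- SpatheParams(
      canvasSize = base@canvasSize, center = base@center + d$dc,
      scale = d$scale, aspect = d$aspect, tipSharpness = d$tip,
      rotation = d$rot, baseColor = clamp01(base@baseColor + d$colb),
      tipColor = clamp01(base@tipColor + d$colt),
      backgroundColor = base@backgroundColor, noiseSd = base@noiseSd,
      seed = d$seed)
    generateSpathe(p)
  })
}
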