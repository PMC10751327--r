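# Reverse-mode autodiff tape.
#
# Nodes are environments carrying a value (`v`, an H x W x C array, matrix or
# scalar), an accumulated gradient (`g`), parent nodes and a backward closure
# that maps the node's output gradient to per-parent gradients. Ops are coarse
# (whole feature maps), so tape overhead is negligible next to the GEMMs.
# Nothing here is exported; the network modules build on these primitives.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

adNode <- function(value, parents = list(), backward = NULL, req = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  .ad$counter <- .ad$counter + 1L
  n$id <- .ad$counter
  n$par <- parents
  n$bw <- backward
  n$req <- if (is.null(req)) any(vapply(parents, function(p) p$req, logical(1))) else req
  class(n) <- "adNode"
  n
}

adConst <- function(value) adNode(value, req = FALSE)
adLeaf  <- function(value) adNode(value, req = TRUE)

adValue <- function(n) n$v

# Accumulate dL/droot into every requires-grad ancestor of `root`.
adBackward <- function(root, seed = 1) {
  stopifnot(length(root$v) == 1L)
  nodes <- list()
  stack <- list(root)
  # visited marker: a unique sentinel per call, stamped on the node itself
  # (string keys would intern one immortal CHARSXP per node id)
  tag <- new.env(parent = emptyenv())
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(n$vis, tag)) next
    n$vis <- tag
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$par) if (p$req) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$g <- seed
  for (i in ord) {
    n <- nodes[[i]]
    if (is.null(n$g) || is.null(n$bw)) next
    grads <- n$bw(n$g)
    for (j in seq_along(n$par)) {
      p <- n$par[[j]]
      if (!p$req || is.null(grads[[j]])) next
      p$g <- if (is.null(p$g)) grads[[j]] else p$g + grads[[j]]
    }
    if (length(n$par)) n$g <- NULL  # free intermediate gradients
  }
  invisible(root)
}

# ---- tensor ops -----------------------------------------------------------

# Raw (non-tape) convolution, for mask bookkeeping and morphology.
convRaw <- function(x, w, b, stride = 1L, pad = 0L)
  .cpp_conv2d_fw(x, w, b, stride, pad, FALSE)$y

adConv <- function(x, w, b, stride = 1L, pad = 0L) {
  need <- x$req || w$req
  r <- .cpp_conv2d_fw(x$v, w$v, b$v, stride, pad, need)
  adNode(r$y, list(x, w, b), function(g) {
    bw <- .cpp_conv2d_bw(x$v, w$v, g, stride, pad, x$req, r$cols)
    list(if (x$req) bw$gx else NULL, if (w$req) bw$gw else NULL,
         as.numeric(bw$gb))
  })
}

adRelu <- function(x) {
  v <- pmax(x$v, 0)
  adNode(v, list(x), function(g) list(g * (x$v > 0)))
}

adLeakyRelu <- function(x, slope = 0.01) {
  fac <- slope + (1 - slope) * (x$v > 0)
  adNode(x$v * fac, list(x), function(g) list(g * fac))
}

adSigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$v))
  adNode(v, list(x), function(g) list(g * v * (1 - v)))
}

adMaxPool <- function(x, k = 3L, stride = 1L, pad = 1L) {
  r <- .cpp_maxpool_fw(x$v, k, stride, pad)
  d <- dim(x$v)
  adNode(r$y, list(x), function(g)
    list(.cpp_maxpool_bw(d[1], d[2], d[3], r$idx, g)))
}

# Nearest-neighbour x2 upsampling.
adUpsample2 <- function(x) {
  d <- dim(x$v)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  v <- x$v[ri, ci, , drop = FALSE]
  adNode(v, list(x), function(g) {
    o <- seq(1L, 2L * d[1], by = 2L)
    e <- seq(1L, 2L * d[2], by = 2L)
    gr <- g[o, , , drop = FALSE] + g[o + 1L, , , drop = FALSE]
    list(gr[, e, , drop = FALSE] + gr[, e + 1L, , drop = FALSE])
  })
}

adConcat <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cc <- vapply(dims, `[`, numeric(1), 3)
  d1 <- dims[[1]]
  v <- array(0, c(d1[1], d1[2], sum(cc)))
  at <- 0L
  for (i in seq_along(xs)) {
    v[, , at + seq_len(cc[i])] <- xs[[i]]$v
    at <- at + cc[i]
  }
  adNode(v, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , at + seq_len(cc[i]), drop = FALSE]
      at <- at + cc[i]
    }
    out
  })
}

adAdd <- function(x, y) adNode(x$v + y$v, list(x, y), function(g) list(g, g))

# Elementwise product with a constant array of the same shape.
adMulConst <- function(x, k) adNode(x$v * k, list(x), function(g) list(g * k))

adAddConst <- function(x, k) adNode(x$v + k, list(x), function(g) list(g))

# Per-output-channel bias add.
adBias <- function(x, b) {
  d <- dim(x$v)
  v <- x$v + rep(b$v, each = d[1] * d[2])
  adNode(v, list(x, b), function(g)
    list(g, as.numeric(apply(g, 3, sum))))
}

# Weighted L1: sum(|x - target| * weight) / den  (target, weight constant).
adL1 <- function(x, target, weight, den) {
  diff <- x$v - target
  v <- sum(abs(diff) * weight) / den
  adNode(v, list(x), function(g) list(g * sign(diff) * weight / den))
}

# Gram matrix of an H x W x C map: G = F F^T / (C*H*W), F the C x (HW) unfold.
adGram <- function(x) {
  d <- dim(x$v)
  n <- prod(d)
  Fm <- t(matrix(x$v, d[1] * d[2], d[3]))     # C x HW
  G <- tcrossprod(Fm) / n
  adNode(G, list(x), function(g) {
    gF <- (g + t(g)) %*% Fm / n               # C x HW
    list(array(t(gF), d))
  })
}

# Weighted sum of scalar nodes.
adScalarSum <- function(xs, coefs) {
  v <- sum(vapply(seq_along(xs), function(i) coefs[i] * xs[[i]]$v, numeric(1)))
  adNode(v, xs, function(g) as.list(g * coefs))
}
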