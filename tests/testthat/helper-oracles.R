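# Brute-force per-pixel oracles, shared across test files. Deliberately
# written as plain loops, independent of the package's vectorized /
# GEMM-based implementations.

# Sliding-window partial convolution (stride 1, zero padding).
pconvOracle <- function(x, mask, w, b, pad) {
  k <- dim(w)[1]; H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  mp <- matrix(0, H + 2 * pad, W + 2 * pad)
  op <- matrix(0, H + 2 * pad, W + 2 * pad)
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  mp[pad + seq_len(H), pad + seq_len(W)] <- mask
  op[pad + seq_len(H), pad + seq_len(W)] <- 1
  Ho <- H + 2 * pad - k + 1; Wo <- W + 2 * pad - k + 1
  y <- array(0, c(Ho, Wo, cout)); nm <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    mwin <- mp[i + 0:(k - 1), j + 0:(k - 1)]
    cnt <- sum(mwin)
    wsz <- sum(op[i + 0:(k - 1), j + 0:(k - 1)])  # in-bounds window size
    nm[i, j] <- (cnt > 0) + 0
    if (cnt > 0) {
      for (co in seq_len(cout)) {
        acc <- 0
        for (ci in seq_len(cin))
          acc <- acc + sum(xp[i + 0:(k - 1), j + 0:(k - 1), ci] *
                             mwin * w[, , ci, co])
        y[i, j, co] <- acc * (wsz / cnt) + b[co]
      }
    }
  }
  list(feature = y, mask = nm)
}

# Per-pixel validity-weighted feature merge.
mergeOracle <- function(fs, ms) {
  d <- dim(fs[[1]])
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    vals <- vapply(seq_along(fs), function(t) fs[[t]][i, j, c], numeric(1))
    valid <- vapply(seq_along(ms), function(t) ms[[t]][i, j], numeric(1))
    out[i, j, c] <- if (sum(valid) > 0) sum(vals * valid) / sum(valid)
                    else vals[length(vals)]
  }
  out
}

# Region-restricted mean absolute difference.
regionL1Oracle <- function(p, g, r) {
  d <- dim(p)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3]))
    acc <- acc + abs(p[i, j, c] - g[i, j, c]) * r[i, j]
  if (sum(r) == 0) 0 else acc / (sum(r) * d[3])
}

# Channel co-activation Gram matrix.
gramOracle <- function(x) {
  d <- dim(x)
  C <- d[3]
  G <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C))
    G[a, b] <- sum(x[, , a] * x[, , b]) / prod(d)
  G
}
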