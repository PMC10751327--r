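// Low-level numerical kernels: convolution via im2col + GEMM, windowed max
// pooling with argmax bookkeeping, priority-queue region growing for occlusion
// masks, connected-component labelling and hole filling for binary masks.
//
// Array conventions match R: feature maps are H x W x C cubes (column-major,
// row index fastest), kernels are k x k x Cin x Cout, masks are H x W matrices.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Transposed im2col: row j = (ho + Ho*wo) holds the receptive field of
// output (ho,wo); column r = kh + k*(kw + k*c) matches the linear order of
// the first three dims of a k x k x Cin x Cout kernel array. The transposed
// layout makes the inner ho-run contiguous in both source and destination
// for stride 1, so the fill is done with memcpy runs instead of per-element
// loops.
static void im2colT(const arma::cube& x, int k, int stride, int pad,
                    int Ho, int Wo, arma::mat& colsT) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  colsT.zeros((size_t)Ho * Wo, (size_t)k * k * C);
  const double* xp = x.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* dst = colsT.colptr(kh + k * (kw + k * c));
        // valid output rows: 0 <= ho*stride - pad + kh < H
        int lo = 0;
        while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
        int hiEnd = Ho;
        while (hiEnd > lo && (hiEnd - 1) * stride - pad + kh >= H) --hiEnd;
        if (hiEnd <= lo) continue;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double* src = xp + (size_t)H * (wi + (size_t)W * c)
                              + (lo * stride - pad + kh);
          double* d = dst + lo + (size_t)Ho * wo;
          if (stride == 1) {
            std::memcpy(d, src, sizeof(double) * (hiEnd - lo));
          } else {
            for (int ho = 0; ho < hiEnd - lo; ++ho)
              d[ho] = src[(size_t)ho * stride];
          }
        }
      }
    }
  }
}

static void col2imT_add(arma::cube& gx, const arma::mat& gcolsT, int k,
                        int stride, int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  double* xp = gx.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* src0 = gcolsT.colptr(kh + k * (kw + k * c));
        int lo = 0;
        while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
        int hiEnd = Ho;
        while (hiEnd > lo && (hiEnd - 1) * stride - pad + kh >= H) --hiEnd;
        if (hiEnd <= lo) continue;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* dst = xp + (size_t)H * (wi + (size_t)W * c)
                        + (lo * stride - pad + kh);
          const double* s = src0 + lo + (size_t)Ho * wo;
          if (stride == 1) {
            for (int ho = 0; ho < hiEnd - lo; ++ho) dst[ho] += s[ho];
          } else {
            for (int ho = 0; ho < hiEnd - lo; ++ho)
              dst[(size_t)ho * stride] += s[ho];
          }
        }
      }
    }
  }
}

static inline bool is_pointwise(int k, int stride, int pad) {
  return k == 1 && stride == 1 && pad == 0;
}

// Forward convolution. When want_cols, the im2col matrix is returned as an
// external pointer so the backward pass can reuse it instead of rebuilding.
// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
List cpp_conv2d_fw_full(const arma::cube& x, const NumericVector& w,
                        const arma::vec& b, int stride, int pad,
                        bool want_cols) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if ((int)x.n_slices != Cin) stop("input channel mismatch");
  if (k > (int)x.n_rows + 2 * pad || k > (int)x.n_cols + 2 * pad)
    stop("kernel larger than (padded) feature map");
  const int Ho = out_dim(x.n_rows, k, stride, pad);
  const int Wo = out_dim(x.n_cols, k, stride, pad);
  const arma::mat A(const_cast<double*>(w.begin()), (size_t)k * k * Cin,
                    Cout, false, true);
  arma::mat Yt;                              // (Ho*Wo) x Cout
  SEXP colsTag = R_NilValue;
  if (is_pointwise(k, stride, pad)) {
    const arma::mat Xm(const_cast<double*>(x.memptr()),
                       (size_t)Ho * Wo, Cin, false, true);
    Yt = Xm * A;
  } else {
    arma::mat* colsT = new arma::mat();
    im2colT(x, k, stride, pad, Ho, Wo, *colsT);
    Yt = (*colsT) * A;
    if (want_cols) {
      colsTag = XPtr<arma::mat>(colsT, true);
    } else {
      delete colsT;
    }
  }
  Yt.each_row() += b.t();
  arma::cube out(Yt.memptr(), Ho, Wo, Cout);
  return List::create(_["y"] = out, _["cols"] = colsTag);
}

// Backward convolution; `cols` may carry the forward's im2col XPtr.
// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::cube& x, const NumericVector& w,
                   const arma::cube& gy, int stride, int pad, bool need_gx,
                   SEXP cols) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const arma::mat A(const_cast<double*>(w.begin()), (size_t)k * k * Cin,
                    Cout, false, true);
  const arma::mat gYt(const_cast<double*>(gy.memptr()), (size_t)Ho * Wo,
                      Cout, false, true);
  NumericVector gw(w.size());
  List out = List::create(_["gw"] = gw, _["gb"] = R_NilValue);
  if (is_pointwise(k, stride, pad)) {
    const arma::mat Xm(const_cast<double*>(x.memptr()), (size_t)Ho * Wo,
                       Cin, false, true);
    arma::mat gA = Xm.t() * gYt;
    std::copy(gA.begin(), gA.end(), gw.begin());
    if (need_gx) {
      arma::mat gXm = gYt * A.t();
      out["gx"] = arma::cube(gXm.memptr(), x.n_rows, x.n_cols, Cin);
    }
  } else {
    arma::mat localColsT;
    const arma::mat* colsT;
    if (cols != R_NilValue) {
      colsT = XPtr<arma::mat>(cols).get();
    } else {
      im2colT(x, k, stride, pad, Ho, Wo, localColsT);
      colsT = &localColsT;
    }
    arma::mat gA = colsT->t() * gYt;
    std::copy(gA.begin(), gA.end(), gw.begin());
    if (need_gx) {
      arma::mat gcolsT = gYt * A.t();
      arma::cube gx(x.n_rows, x.n_cols, Cin, arma::fill::zeros);
      col2imT_add(gx, gcolsT, k, stride, pad, Ho, Wo);
      out["gx"] = gx;
    }
  }
  gw.attr("dim") = wd;
  out["gb"] = arma::sum(gYt, 0).t();
  return out;
}

// Windowed max pooling; padded positions behave as -Inf. idx holds 0-based
// linear indices into x of each selected maximum.
// [[Rcpp::export(name = ".cpp_maxpool_fw")]]
List cpp_maxpool_fw(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::cube y(Ho, Wo, C);
  IntegerVector idx((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        double best = -std::numeric_limits<double>::infinity();
        long bi = -1;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const double v = x(hi, wi, c);
            if (v > best) { best = v; bi = hi + (long)H * wi + (long)H * W * c; }
          }
        }
        y(ho, wo, c) = bi >= 0 ? best : 0.0;
        idx[(size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * c] = (int)bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bw")]]
arma::cube cpp_maxpool_bw(int H, int W, int C, const IntegerVector& idx,
                          const arma::cube& gy) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gy.memptr();
  double* out = gx.memptr();
  for (size_t j = 0; j < (size_t)idx.size(); ++j)
    if (idx[j] >= 0) out[idx[j]] += g[j];
  return gx;
}

// Seeded region growing over a domain: starting from the anchor pixel, pixels
// are absorbed in increasing order of a static per-pixel priority (frontier
// pixels only), which keeps the grown blob 4-connected. Growth stops once
// `target` foreground pixels are absorbed. Returns the grown blob (0/1).
// [[Rcpp::export(name = ".cpp_grow_region")]]
IntegerMatrix cpp_grow_region(const NumericMatrix& priority,
                              const LogicalMatrix& domain,
                              const LogicalMatrix& fg,
                              int anchor_row, int anchor_col, int target) {
  const int H = priority.nrow(), W = priority.ncol();
  IntegerMatrix region(H, W);
  if (target <= 0) return region;
  std::vector<char> seen((size_t)H * W, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  const int a = anchor_row + H * anchor_col;
  q.push(QE(priority[a], a));
  seen[a] = 1;
  int got = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty() && got < target) {
    const int p = q.top().second;
    q.pop();
    region[p] = 1;
    if (fg[p]) ++got;
    const int r = p % H, c = p / H;
    for (int d = 0; d < 4; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const int pp = rr + H * cc;
      if (seen[pp] || !domain[pp]) continue;
      seen[pp] = 1;
      q.push(QE(priority[pp], pp));
    }
  }
  return region;
}

// Chebyshev (square structuring element) binary dilation by `radius`,
// separable: a running 1D max over rows, then over columns.
// [[Rcpp::export(name = ".cpp_dilate")]]
IntegerMatrix cpp_dilate(const LogicalMatrix& mask, int radius) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int v = 0;
      const int lo = std::max(0, r - radius), hi = std::min(H - 1, r + radius);
      for (int k = lo; k <= hi && !v; ++k) v = mask(k, c) ? 1 : 0;
      tmp(r, c) = v;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int v = 0;
      const int lo = std::max(0, c - radius), hi = std::min(W - 1, c + radius);
      for (int k = lo; k <= hi && !v; ++k) v = tmp(r, k) ? 1 : 0;
      out(r, c) = v;
    }
  return out;
}

// 4-connected component labelling (labels 1..n, 0 = background).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int p = 0; p < H * W; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    stack.push_back(p);
    lab[p] = next;
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      const int r = q % H, c = q / H;
      for (int d = 0; d < 4; ++d) {
        const int rr = r + dr[d], cc = c + dc[d];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        const int pp = rr + H * cc;
        if (mask[pp] && !lab[pp]) { lab[pp] = next; stack.push_back(pp); }
      }
    }
  }
  return lab;
}

// Fill enclosed background holes: background reachable from the border stays
// background, everything else becomes foreground.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
IntegerMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> outside((size_t)H * W, 0);
  std::vector<int> stack;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; r += (H > 1 ? H - 1 : 1)) {
      const int p = r + H * c;
      if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      if (H == 1) break;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; c += (W > 1 ? W - 1 : 1)) {
      const int p = r + H * c;
      if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      if (W == 1) break;
    }
  while (!stack.empty()) {
    const int q = stack.back();
    stack.pop_back();
    const int r = q % H, c = q / H;
    for (int d = 0; d < 4; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const int pp = rr + H * cc;
      if (!mask[pp] && !outside[pp]) { outside[pp] = 1; stack.push_back(pp); }
    }
  }
  IntegerMatrix out(H, W);
  for (int p = 0; p < H * W; ++p) out[p] = (mask[p] || !outside[p]) ? 1 : 0;
  return out;
}
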