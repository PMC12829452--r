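#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as (H*W*N) x C matrices with row index ordered
// h fastest, then w, then sample n. Convolutions are "valid" (no padding).

// [[Rcpp::export]]
NumericMatrix im2col_hwn(const NumericMatrix& A, int H, int W, int N,
                         int kh, int kw) {
  const int C = A.ncol();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than input");
  NumericMatrix out((R_xlen_t)Ho * Wo * N, (R_xlen_t)kh * kw * C);
  const double* a = A.begin();
  double* o = out.begin();
  const R_xlen_t rowsA = (R_xlen_t)H * W * N;
  const R_xlen_t rowsO = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    const double* ac = a + (R_xlen_t)c * rowsA;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        // output column index: dh + kh*dw + kh*kw*c
        double* oc = o + ((R_xlen_t)dh + (R_xlen_t)kh * dw +
                          (R_xlen_t)kh * kw * c) * rowsO;
        for (int n = 0; n < N; ++n) {
          const double* an = ac + (R_xlen_t)n * H * W;
          double* on = oc + (R_xlen_t)n * Ho * Wo;
          for (int w = 0; w < Wo; ++w) {
            const double* src = an + (R_xlen_t)(w + dw) * H + dh;
            double* dst = on + (R_xlen_t)w * Ho;
            memcpy(dst, src, sizeof(double) * Ho);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_hwn(const NumericMatrix& dcol, int H, int W, int N,
                         int kh, int kw, int C) {
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericMatrix out((R_xlen_t)H * W * N, C);
  const double* d = dcol.begin();
  double* o = out.begin();
  const R_xlen_t rowsA = (R_xlen_t)H * W * N;
  const R_xlen_t rowsO = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    double* oc = o + (R_xlen_t)c * rowsA;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const double* dc = d + ((R_xlen_t)dh + (R_xlen_t)kh * dw +
                                (R_xlen_t)kh * kw * c) * rowsO;
        for (int n = 0; n < N; ++n) {
          double* on = oc + (R_xlen_t)n * H * W;
          const double* dn = dc + (R_xlen_t)n * Ho * Wo;
          for (int w = 0; w < Wo; ++w) {
            double* dst = on + (R_xlen_t)(w + dw) * H + dh;
            const double* src = dn + (R_xlen_t)w * Ho;
            for (int h = 0; h < Ho; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling with stride 2; trailing odd row/col dropped.
// Returns pooled values and 1-based linear argmax indices into the input.
// [[Rcpp::export]]
List maxpool2_hwn(const NumericMatrix& A, int H, int W, int N) {
  const int C = A.ncol();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix P((R_xlen_t)Ho * Wo * N, C);
  IntegerMatrix idx((R_xlen_t)Ho * Wo * N, C);
  const double* a = A.begin();
  double* p = P.begin();
  int* ix = idx.begin();
  const R_xlen_t rowsA = (R_xlen_t)H * W * N;
  const R_xlen_t rowsP = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    const double* ac = a + (R_xlen_t)c * rowsA;
    double* pc = p + (R_xlen_t)c * rowsP;
    int* ic = ix + (R_xlen_t)c * rowsP;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t offA = (R_xlen_t)n * H * W;
      const R_xlen_t offP = (R_xlen_t)n * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t base = offA + (R_xlen_t)(2 * w) * H + 2 * h;
          R_xlen_t cand[4] = {base, base + 1, base + H, base + H + 1};
          R_xlen_t best = cand[0];
          double bv = ac[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (ac[cand[k]] > bv) { bv = ac[cand[k]]; best = cand[k]; }
          pc[offP + (R_xlen_t)w * Ho + h] = bv;
          ic[offP + (R_xlen_t)w * Ho + h] = (int)(best + 1);  // within column
        }
      }
    }
  }
  return List::create(_["values"] = P, _["argmax"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_backward_hwn(const NumericMatrix& dP,
                                    const IntegerMatrix& idx,
                                    int H, int W, int N) {
  const int C = dP.ncol();
  NumericMatrix out((R_xlen_t)H * W * N, C);
  const double* d = dP.begin();
  const int* ix = idx.begin();
  double* o = out.begin();
  const R_xlen_t rowsP = dP.nrow();
  const R_xlen_t rowsA = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    const double* dc = d + (R_xlen_t)c * rowsP;
    const int* ic = ix + (R_xlen_t)c * rowsP;
    double* oc = o + (R_xlen_t)c * rowsA;
    for (R_xlen_t r = 0; r < rowsP; ++r) oc[ic[r] - 1] += dc[r];
  }
  return out;
}

// Sliding windows for wavelet convolution at decimated centers.
// Xpad: (Spad x C) zero-padded signals; centers: 1-based index of the first
// tap of each window in Xpad; taps: window length.
// Returns (length(centers)*C) x taps, rows ordered time-point fastest then channel.
// [[Rcpp::export]]
NumericMatrix window_gather(const NumericMatrix& Xpad, const IntegerVector& centers,
                            int taps) {
  const int C = Xpad.ncol();
  const int nT = centers.size();
  const R_xlen_t Spad = Xpad.nrow();
  NumericMatrix out((R_xlen_t)nT * C, taps);
  const double* x = Xpad.begin();
  double* o = out.begin();
  for (int k = 0; k < taps; ++k) {
    double* ok = o + (R_xlen_t)k * nT * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (R_xlen_t)c * Spad;
      double* oc = ok + (R_xlen_t)c * nT;
      for (int t = 0; t < nT; ++t) oc[t] = xc[centers[t] - 1 + k];
    }
  }
  return out;
}

// im2col gathering only the samples in idx (1-based) from a full
// (H*W*Nall) x C layout; output rows ordered h, w, then idx position.
// [[Rcpp::export]]
NumericMatrix im2col_sel(const NumericMatrix& A, int H, int W, int Nall,
                         const IntegerVector& idx, int kh, int kw) {
  const int C = A.ncol();
  const int N = idx.size();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than input");
  NumericMatrix out((R_xlen_t)Ho * Wo * N, (R_xlen_t)kh * kw * C);
  const double* a = A.begin();
  double* o = out.begin();
  const R_xlen_t rowsA = (R_xlen_t)H * W * Nall;
  const R_xlen_t rowsO = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    const double* ac = a + (R_xlen_t)c * rowsA;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        double* oc = o + ((R_xlen_t)dh + (R_xlen_t)kh * dw +
                          (R_xlen_t)kh * kw * c) * rowsO;
        for (int n = 0; n < N; ++n) {
          const double* an = ac + (R_xlen_t)(idx[n] - 1) * H * W;
          double* on = oc + (R_xlen_t)n * Ho * Wo;
          for (int w = 0; w < Wo; ++w) {
            memcpy(on + (R_xlen_t)w * Ho, an + (R_xlen_t)(w + dw) * H + dh,
                   sizeof(double) * Ho);
          }
        }
      }
    }
  }
  return out;
}

// out[i,j] = X[i,j] * scale[j] + shift[j]
// [[Rcpp::export]]
NumericMatrix col_affine(const NumericMatrix& X, const NumericVector& scale,
                         const NumericVector& shift) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t m = X.nrow();
  for (int j = 0; j < X.ncol(); ++j) {
    const double s = scale[j], b = shift[j];
    const double* x = X.begin() + (R_xlen_t)j * m;
    double* o = out.begin() + (R_xlen_t)j * m;
    for (R_xlen_t i = 0; i < m; ++i) o[i] = x[i] * s + b;
  }
  return out;
}

// out[i,j] = max(X[i,j] + b[j], 0)
// [[Rcpp::export]]
NumericMatrix bias_relu(const NumericMatrix& X, const NumericVector& b) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t m = X.nrow();
  for (int j = 0; j < X.ncol(); ++j) {
    const double bj = b[j];
    const double* x = X.begin() + (R_xlen_t)j * m;
    double* o = out.begin() + (R_xlen_t)j * m;
    for (R_xlen_t i = 0; i < m; ++i) {
      double v = x[i] + bj;
      o[i] = v > 0 ? v : 0;
    }
  }
  return out;
}

// batch-norm input gradient:
// dx[i,j] = (dxhat[i,j] - s1m[j] - xhat[i,j] * s2m[j]) * invstd[j]
// [[Rcpp::export]]
NumericMatrix bn_backward_core(const NumericMatrix& dxhat,
                               const NumericMatrix& xhat,
                               const NumericVector& s1m,
                               const NumericVector& s2m,
                               const NumericVector& invstd) {
  NumericMatrix out(dxhat.nrow(), dxhat.ncol());
  const R_xlen_t m = dxhat.nrow();
  for (int j = 0; j < dxhat.ncol(); ++j) {
    const double a = s1m[j], b = s2m[j], s = invstd[j];
    const double* d = dxhat.begin() + (R_xlen_t)j * m;
    const double* xh = xhat.begin() + (R_xlen_t)j * m;
    double* o = out.begin() + (R_xlen_t)j * m;
    for (R_xlen_t i = 0; i < m; ++i) o[i] = (d[i] - a - xh[i] * b) * s;
  }
  return out;
}

// column means of X and of X^2 in one pass
// [[Rcpp::export]]
List col_moments(const NumericMatrix& X) {
  const R_xlen_t m = X.nrow();
  NumericVector mu(X.ncol()), musq(X.ncol());
  for (int j = 0; j < X.ncol(); ++j) {
    const double* x = X.begin() + (R_xlen_t)j * m;
    double s = 0, sq = 0;
    for (R_xlen_t i = 0; i < m; ++i) { s += x[i]; sq += x[i] * x[i]; }
    mu[j] = s / m; musq[j] = sq / m;
  }
  return List::create(_["mean"] = mu, _["meansq"] = musq);
}
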