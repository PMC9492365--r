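// Convolution / pooling kernels for the segmentation network.
// Tensor layout follows the R arrays: dim = c(N, C, H, W), column-major,
// so element (n, c, h, w) sits at n + N*(c + C*(h + H*w)) (0-based).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-D array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Gather x (N,C,H,W) into columns: row (c,i,j) x col (n,h,w), zero padding.
static arma::mat im2col(const double* x, int N, int C, int H, int W,
                        int kh, int kw, int ph, int pw) {
  arma::mat cols(C * kh * kw, (size_t)N * H * W, arma::fill::zeros);
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) {
        const size_t r = c + (size_t)C * (i + kh * j);
        for (int w = 0; w < W; ++w) {
          const int wi = w + j - pw;
          if (wi < 0 || wi >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hi = h + i - ph;
            if (hi < 0 || hi >= H) continue;
            const size_t col0 = (size_t)N * (h + (size_t)H * w);
            const double* src = x + (size_t)N * ((size_t)c + (size_t)C * (hi + (size_t)H * wi));
            for (int n = 0; n < N; ++n)
              cols(r, col0 + n) = src[n];
          }
        }
      }
    }
  }
  return cols;
}

// y = conv2d(x, w) + b, "same"-style padding given explicitly.
// x: (N,C,H,W); w: (K,C,kh,kw); b: length K. Returns (N,K,H,W).
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int ph, int pw) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int K = dw[0], kh = dw[2], kw = dw[3];
  if (dw[1] != C) stop("weight/input channel mismatch");
  arma::mat cols = im2col(REAL(x), N, C, H, W, kh, kw, ph, pw);
  arma::mat Wm(const_cast<double*>(REAL(w)), K, (size_t)C * kh * kw, false, true);
  arma::mat Y = Wm * cols;                       // K x (N*H*W)
  NumericVector out((size_t)N * K * H * W);
  out.attr("dim") = IntegerVector::create(N, K, H, W);
  double* o = REAL(out);
  const double* bp = REAL(b);
  for (size_t col = 0; col < (size_t)N * H * W; ++col) {
    const size_t n = col % N, hw = col / N;
    for (int k = 0; k < K; ++k)
      o[n + (size_t)N * (k + (size_t)K * hw)] = Y(k, col) + bp[k];
  }
  return out;
}

// Gradients of conv2d. gy: (N,K,H,W). Returns list(gx, gw, gb).
// [[Rcpp::export]]
List cpp_conv2d_grad(NumericVector x, NumericVector w, NumericVector gy,
                     int ph, int pw) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int K = dw[0], kh = dw[2], kw = dw[3];

  // reshape gy into K x (N*H*W)
  arma::mat Gy(K, (size_t)N * H * W);
  const double* g = REAL(gy);
  for (size_t col = 0; col < (size_t)N * H * W; ++col) {
    const size_t n = col % N, hw = col / N;
    for (int k = 0; k < K; ++k)
      Gy(k, col) = g[n + (size_t)N * (k + (size_t)K * hw)];
  }

  arma::mat cols = im2col(REAL(x), N, C, H, W, kh, kw, ph, pw);
  arma::mat Gw = Gy * cols.t();                  // K x (C*kh*kw)
  arma::mat Wm(const_cast<double*>(REAL(w)), K, (size_t)C * kh * kw, false, true);
  arma::mat Gcols = Wm.t() * Gy;                 // (C*kh*kw) x (N*H*W)

  NumericVector gx((size_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  double* gxp = REAL(gx);
  // col2im scatter-add
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) {
        const size_t r = c + (size_t)C * (i + kh * j);
        for (int w2 = 0; w2 < W; ++w2) {
          const int wi = w2 + j - pw;
          if (wi < 0 || wi >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hi = h + i - ph;
            if (hi < 0 || hi >= H) continue;
            const size_t col0 = (size_t)N * (h + (size_t)H * w2);
            double* dst = gxp + (size_t)N * ((size_t)c + (size_t)C * (hi + (size_t)H * wi));
            for (int n = 0; n < N; ++n)
              dst[n] += Gcols(r, col0 + n);
          }
        }
      }
    }
  }

  NumericVector gwv(Gw.n_elem);
  std::copy(Gw.memptr(), Gw.memptr() + Gw.n_elem, REAL(gwv));
  gwv.attr("dim") = IntegerVector::create(K, C, kh, kw);
  NumericVector gb(K);
  arma::vec rs = arma::sum(Gy, 1);
  std::copy(rs.memptr(), rs.memptr() + K, REAL(gb));
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// Transposed 2x2 stride-2 convolution (deconvolution).
// x: (N,C,H,W); w: (C,K,2,2); b: length K. Returns (N,K,2H,2W).
// [[Rcpp::export]]
NumericVector cpp_convt2x2(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int K = dw[1];
  if (dw[0] != C || dw[2] != 2 || dw[3] != 2) stop("bad deconv weight shape");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)N * K * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, K, Ho, Wo);
  double* o = REAL(out);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  for (size_t i = 0; i < (size_t)N * K * Ho * Wo; ++i) o[i] = 0.0;
  for (int wo = 0; wo < Wo; ++wo) {
    const int w2 = wo / 2, j = wo % 2;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h = ho / 2, i = ho % 2;
      for (int k = 0; k < K; ++k) {
        double* dst = o + (size_t)N * (k + (size_t)K * (ho + (size_t)Ho * wo));
        for (int c = 0; c < C; ++c) {
          const double wv = wp[c + (size_t)C * (k + (size_t)K * (i + 2 * j))];
          const double* src = xp + (size_t)N * (c + (size_t)C * (h + (size_t)H * w2));
          for (int n = 0; n < N; ++n) dst[n] += wv * src[n];
        }
        for (int n = 0; n < N; ++n) dst[n] += bp[k];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt2x2_grad(NumericVector x, NumericVector w, NumericVector gy) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int K = dw[1];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)N * C * H * W), gw((size_t)C * K * 4), gb(K);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  gw.attr("dim") = IntegerVector::create(C, K, 2, 2);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gy);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w2 = wo / 2, j = wo % 2;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h = ho / 2, i = ho % 2;
      for (int k = 0; k < K; ++k) {
        const double* gsrc = gp + (size_t)N * (k + (size_t)K * (ho + (size_t)Ho * wo));
        for (int n = 0; n < N; ++n) gbp[k] += gsrc[n];
        for (int c = 0; c < C; ++c) {
          const size_t wi = c + (size_t)C * (k + (size_t)K * (i + 2 * j));
          const double wv = wp[wi];
          const double* src = xp + (size_t)N * (c + (size_t)C * (h + (size_t)H * w2));
          double* gdst = gxp + (size_t)N * (c + (size_t)C * (h + (size_t)H * w2));
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            gdst[n] += wv * gsrc[n];
            acc += src[n] * gsrc[n];
          }
          gwp[wi] += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; H, W must be even.
// Returns list(y = (N,C,H/2,W/2), idx = winner offset 0..3 as (dh + 2*dw)).
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  int dx[4];
  get_dims4(x, dx);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)N * C * Ho * Wo);
  IntegerVector idx((size_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  idx.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -1e300; int bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              const double v = xp[n + (size_t)N * (c + (size_t)C *
                ((2 * ho + dh) + (size_t)H * (2 * wo + dw2)))];
              if (v > best) { best = v; bi = dh + 2 * dw2; }
            }
          const size_t o = n + (size_t)N * (c + (size_t)C * (ho + (size_t)Ho * wo));
          yp[o] = best; ip[o] = bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_grad(NumericVector gy, IntegerVector idx, int H, int W) {
  int dg[4];
  get_dims4(gy, dg);
  const int N = dg[0], C = dg[1], Ho = dg[2], Wo = dg[3];
  NumericVector gx((size_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  double* gxp = REAL(gx);
  const double* gp = REAL(gy);
  const int* ip = INTEGER(idx);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const size_t o = n + (size_t)N * (c + (size_t)C * (ho + (size_t)Ho * wo));
          const int dh = ip[o] % 2, dw2 = ip[o] / 2;
          gxp[n + (size_t)N * (c + (size_t)C *
            ((2 * ho + dh) + (size_t)H * (2 * wo + dw2)))] += gp[o];
        }
  return gx;
}
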