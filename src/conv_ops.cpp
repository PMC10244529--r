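// Single-precision convolution and pooling kernels.
// Tensor layout everywhere: column-major R arrays (H, W, C, N).
// Weight layout: (kh, kw, Cin, Cout); the flattened weight matrix is
// K x Cout with K = kh*kw*Cin and row index r = dh + kh*(dw + kw*c).
// im2col builds the transposed patch matrix colT (L x K, L = Ho*Wo) so
// that both the reads from the image and the writes to the matrix are
// contiguous; the convolution is then one sgemm per image.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2colT_f(const float* x, int H, int W, int C,
                      int kh, int kw, int sh, int sw, int ph, int pw,
                      int Ho, int Wo, arma::fmat& colT) {
  const size_t L = (size_t)Ho * Wo;
  colT.zeros(L, (size_t)kh * kw * C);
  float* cm = colT.memptr();
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        float* dst0 = cm + (size_t)r * L;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          const float* xcol = xc + (size_t)wi * H;
          float* dst = dst0 + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * sh - ph + dh;
            if (hi >= 0 && hi < H) dst[oh] = xcol[hi];
          }
        }
      }
    }
  }
}

static void col2imT_f(const arma::fmat& colT, int H, int W, int C,
                      int kh, int kw, int sh, int sw, int ph, int pw,
                      int Ho, int Wo, float* dx) {
  const size_t L = (size_t)Ho * Wo;
  const float* cm = colT.memptr();
  for (int c = 0; c < C; ++c) {
    float* xc = dx + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const float* src0 = cm + (size_t)r * L;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          float* xcol = xc + (size_t)wi * H;
          const float* src = src0 + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * sh - ph + dh;
            if (hi >= 0 && hi < H) xcol[hi] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int sh, int sw, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = kh * kw * C;
  const size_t L = (size_t)Ho * Wo;

  arma::fmat Wm(K, Cout);
  { const double* wp = w.begin(); float* d = Wm.memptr();
    for (size_t i = 0; i < (size_t)K * Cout; ++i) d[i] = (float)wp[i]; }
  arma::frowvec bv;
  const bool has_bias = bias.size() == Cout;
  if (has_bias) { bv.set_size(Cout);
    for (int i = 0; i < Cout; ++i) bv[i] = (float)bias[i]; }

  NumericVector y(L * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  std::vector<float> xf((size_t)H * W * C);
  arma::fmat colT;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    for (size_t i = 0; i < xf.size(); ++i) xf[i] = (float)xp[i];
    im2colT_f(xf.data(), H, W, C, kh, kw, sh, sw, ph, pw, Ho, Wo, colT);
    arma::fmat Y = colT * Wm;             // L x Cout
    if (has_bias) Y.each_row() += bv;
    double* yp = y.begin() + (size_t)n * L * Cout;
    const float* yf = Y.memptr();
    for (size_t i = 0; i < L * (size_t)Cout; ++i) yp[i] = (double)yf[i];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy,
                         int sh, int sw, int ph, int pw,
                         bool has_bias, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  const int K = kh * kw * C;
  const size_t L = (size_t)Ho * Wo;

  arma::fmat Wm(K, Cout);
  { const double* wp = w.begin(); float* d = Wm.memptr();
    for (size_t i = 0; i < (size_t)K * Cout; ++i) d[i] = (float)wp[i]; }

  arma::fmat dWm(K, Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = xdim;
  }

  std::vector<float> xf((size_t)H * W * C), dxf;
  if (need_dx) dxf.resize(xf.size());
  arma::fmat colT, dY(L, Cout);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    for (size_t i = 0; i < xf.size(); ++i) xf[i] = (float)xp[i];
    im2colT_f(xf.data(), H, W, C, kh, kw, sh, sw, ph, pw, Ho, Wo, colT);
    const double* dyp = dy.begin() + (size_t)n * L * Cout;
    float* dYf = dY.memptr();
    for (size_t i = 0; i < L * (size_t)Cout; ++i) dYf[i] = (float)dyp[i];
    dWm += colT.t() * dY;                 // K x Cout
    if (has_bias) db += arma::sum(dY, 0).t();
    if (need_dx) {
      arma::fmat dcolT = dY * Wm.t();     // L x K
      std::fill(dxf.begin(), dxf.end(), 0.0f);
      col2imT_f(dcolT, H, W, C, kh, kw, sh, sw, ph, pw, Ho, Wo, dxf.data());
      double* dxp = dx.begin() + (size_t)n * H * W * C;
      for (size_t i = 0; i < dxf.size(); ++i) dxp[i] = (double)dxf[i];
    }
  }

  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wdim;
  { const float* s = dWm.memptr(); double* d = dw.begin();
    for (size_t i = 0; i < (size_t)K * Cout; ++i) d[i] = (double)s[i]; }
  NumericVector dbv(has_bias ? Cout : 0);
  if (has_bias) for (int i = 0; i < Cout; ++i) dbv[i] = (double)db[i];

  return List::create(_["dw"] = dw, _["db"] = dbv,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);   // 0-based index into x

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          long long bidx = -1;
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = ow * sw - pw + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = oh * sh - ph + dh;
              if (hi < 0 || hi >= H) continue;
              const size_t xi = base + (size_t)wi * H + hi;
              if (xp[xi] > best) { best = xp[xi]; bidx = (long long)xi; }
            }
          }
          const size_t oi = ((size_t)n * C + c) * Ho * Wo + (size_t)ow * Ho + oh;
          yp[oi] = best; ip[oi] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) dxp[(size_t)ip[i]] += dyp[i];
  return dx;
}
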