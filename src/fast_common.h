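// Shared single-precision tensor and layer helpers for the C++ fast paths
// (ResNet-18 backbone and the feature-fusion front end). Tensor layout is
// the same column-major (H, W, C, N) used on the R side; convolution is
// im2col (transposed, L x K) plus one sgemm per image.

#ifndef HMHN_FAST_COMMON_H
#define HMHN_FAST_COMMON_H

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

namespace hmhn_fast {

struct Ten {
  int H = 0, W = 0, C = 0, N = 0;
  arma::fvec d;
  void resize(int h, int w, int c, int n) {
    H = h; W = w; C = c; N = n;
    d.set_size((size_t)h * w * c * n);
  }
  size_t per_img() const { return (size_t)H * W * C; }
};

struct ConvSpec { int kh, kw, cin, cout, s, ph, pw; bool bias; };

struct Conv {
  ConvSpec sp;
  arma::fmat W, gW, mW, vW;   // K x Cout
  arma::fvec b, gb, mb, vb;
  void init(const ConvSpec& s) {
    sp = s;
    const int K = s.kh * s.kw * s.cin;
    W.set_size(K, s.cout);
    gW.zeros(K, s.cout); mW.zeros(K, s.cout); vW.zeros(K, s.cout);
    if (s.bias) {
      b.zeros(s.cout); gb.zeros(s.cout);
      mb.zeros(s.cout); vb.zeros(s.cout);
    }
  }
  size_t n_params() const { return W.n_elem + b.n_elem; }
};

struct BN {
  int C = 0;
  arma::fvec gamma, beta, rmean, rvar;
  arma::fvec ggamma, gbeta, mg, vg, mb, vb;
  arma::fvec mu, invstd;      // batch cache
  void init(int c) {
    C = c;
    gamma.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
    ggamma.zeros(c); gbeta.zeros(c);
    mg.zeros(c); vg.zeros(c); mb.zeros(c); vb.zeros(c);
  }
};

inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

inline void im2colT(const float* x, int H, int W, int C,
                    int kh, int kw, int s, int ph, int pw,
                    int Ho, int Wo, arma::fmat& colT) {
  const size_t L = (size_t)Ho * Wo;
  colT.zeros(L, (size_t)kh * kw * C);
  float* cm = colT.memptr();
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        float* dst0 = cm + (size_t)r * L;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * s - pw + dw;
          if (wi < 0 || wi >= W) continue;
          const float* xcol = xc + (size_t)wi * H;
          float* dst = dst0 + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * s - ph + dh;
            if (hi >= 0 && hi < H) dst[oh] = xcol[hi];
          }
        }
      }
  }
}

inline void col2imT(const arma::fmat& colT, int H, int W, int C,
                    int kh, int kw, int s, int ph, int pw,
                    int Ho, int Wo, float* dx) {
  const size_t L = (size_t)Ho * Wo;
  const float* cm = colT.memptr();
  for (int c = 0; c < C; ++c) {
    float* xc = dx + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const float* src0 = cm + (size_t)r * L;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * s - pw + dw;
          if (wi < 0 || wi >= W) continue;
          float* xcol = xc + (size_t)wi * H;
          const float* src = src0 + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hi = oh * s - ph + dh;
            if (hi >= 0 && hi < H) xcol[hi] += src[oh];
          }
        }
      }
  }
}

inline void conv_forward(Conv& c, const Ten& x, Ten& y, arma::fmat& scratch) {
  const ConvSpec& s = c.sp;
  const int Ho = out_size(x.H, s.kh, s.s, s.ph);
  const int Wo = out_size(x.W, s.kw, s.s, s.pw);
  y.resize(Ho, Wo, s.cout, x.N);
  const size_t L = (size_t)Ho * Wo;
  for (int n = 0; n < x.N; ++n) {
    im2colT(x.d.memptr() + (size_t)n * x.per_img(), x.H, x.W, x.C,
            s.kh, s.kw, s.s, s.ph, s.pw, Ho, Wo, scratch);
    arma::fmat Y(y.d.memptr() + (size_t)n * y.per_img(), L, s.cout,
                 false, true);
    Y = scratch * c.W;
    if (s.bias) Y.each_row() += c.b.t();
  }
}

inline void conv_backward(Conv& c, const Ten& x, const Ten& dy, Ten* dx,
                          arma::fmat& scratch) {
  const ConvSpec& s = c.sp;
  const int Ho = dy.H, Wo = dy.W;
  const size_t L = (size_t)Ho * Wo;
  if (dx) { dx->resize(x.H, x.W, x.C, x.N); dx->d.zeros(); }
  for (int n = 0; n < x.N; ++n) {
    im2colT(x.d.memptr() + (size_t)n * x.per_img(), x.H, x.W, x.C,
            s.kh, s.kw, s.s, s.ph, s.pw, Ho, Wo, scratch);
    const arma::fmat dY(const_cast<float*>(dy.d.memptr()) +
                        (size_t)n * dy.per_img(), L, s.cout, false, true);
    c.gW += scratch.t() * dY;
    if (s.bias) c.gb += arma::sum(dY, 0).t();
    if (dx) {
      arma::fmat dcolT = dY * c.W.t();
      col2imT(dcolT, x.H, x.W, x.C, s.kh, s.kw, s.s, s.ph, s.pw,
              Ho, Wo, dx->d.memptr() + (size_t)n * dx->per_img());
    }
  }
}

inline void bn_forward(BN& b, const Ten& x, Ten& y, bool train,
                       float momentum, float eps) {
  y.resize(x.H, x.W, x.C, x.N);
  const size_t HW = (size_t)x.H * x.W;
  const float m = (float)(HW * x.N);
  if (train) {
    arma::fvec mu(b.C, arma::fill::zeros), s2(b.C, arma::fill::zeros);
    for (int n = 0; n < x.N; ++n)
      for (int c = 0; c < b.C; ++c) {
        const float* xs = x.d.memptr() + ((size_t)n * b.C + c) * HW;
        float a = 0, q = 0;
        for (size_t i = 0; i < HW; ++i) { a += xs[i]; q += xs[i] * xs[i]; }
        mu[c] += a; s2[c] += q;
      }
    b.mu = mu / m;
    arma::fvec var = arma::max(s2 / m - arma::square(b.mu),
                               arma::fvec(b.C, arma::fill::zeros));
    b.invstd = 1.0f / arma::sqrt(var + eps);
    b.rmean = (1.0f - momentum) * b.rmean + momentum * b.mu;
    const float ub = m > 1 ? m / (m - 1) : 1.0f;
    b.rvar = (1.0f - momentum) * b.rvar + momentum * var * ub;
    for (int n = 0; n < x.N; ++n)
      for (int c = 0; c < b.C; ++c) {
        const float a = b.gamma[c] * b.invstd[c];
        const float sh = b.beta[c] - b.mu[c] * a;
        const size_t off = ((size_t)n * b.C + c) * HW;
        const float* xs = x.d.memptr() + off;
        float* ys = y.d.memptr() + off;
        for (size_t i = 0; i < HW; ++i) ys[i] = xs[i] * a + sh;
      }
  } else {
    for (int n = 0; n < x.N; ++n)
      for (int c = 0; c < b.C; ++c) {
        const float a = b.gamma[c] / std::sqrt(b.rvar[c] + eps);
        const float sh = b.beta[c] - b.rmean[c] * a;
        const size_t off = ((size_t)n * b.C + c) * HW;
        const float* xs = x.d.memptr() + off;
        float* ys = y.d.memptr() + off;
        for (size_t i = 0; i < HW; ++i) ys[i] = xs[i] * a + sh;
      }
  }
}

inline void bn_backward(BN& b, const Ten& x, const Ten& dy, Ten& dx) {
  dx.resize(x.H, x.W, x.C, x.N);
  const size_t HW = (size_t)x.H * x.W;
  const float m = (float)(HW * x.N);
  arma::fvec sdy(b.C, arma::fill::zeros), sdx(b.C, arma::fill::zeros);
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < b.C; ++c) {
      const size_t off = ((size_t)n * b.C + c) * HW;
      const float* xs = x.d.memptr() + off;
      const float* ds = dy.d.memptr() + off;
      const float muc = b.mu[c], isc = b.invstd[c];
      float a = 0, q = 0;
      for (size_t i = 0; i < HW; ++i) {
        a += ds[i];
        q += ds[i] * (xs[i] - muc) * isc;
      }
      sdy[c] += a; sdx[c] += q;
    }
  b.gbeta += sdy; b.ggamma += sdx;
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < b.C; ++c) {
      const size_t off = ((size_t)n * b.C + c) * HW;
      const float* xs = x.d.memptr() + off;
      const float* ds = dy.d.memptr() + off;
      float* o = dx.d.memptr() + off;
      const float muc = b.mu[c], isc = b.invstd[c];
      const float coef = b.gamma[c] * isc;
      const float t1 = sdy[c] / m, t2 = sdx[c] / m;
      for (size_t i = 0; i < HW; ++i) {
        const float xhat = (xs[i] - muc) * isc;
        o[i] = coef * (ds[i] - t1 - xhat * t2);
      }
    }
}

// slope 0 gives plain relu, 0.01 the leaky variant
inline void srelu_forward(const Ten& x, Ten& y, float slope) {
  y.resize(x.H, x.W, x.C, x.N);
  const size_t n = x.d.n_elem;
  const float* xs = x.d.memptr();
  float* ys = y.d.memptr();
  for (size_t i = 0; i < n; ++i) ys[i] = xs[i] > 0 ? xs[i] : slope * xs[i];
}

// masks with the OUTPUT's sign (sign is preserved for slope >= 0)
inline void srelu_backward(const Ten& y, const Ten& dy, Ten& dx,
                           float slope) {
  dx.resize(y.H, y.W, y.C, y.N);
  const size_t n = y.d.n_elem;
  const float* ys = y.d.memptr();
  const float* ds = dy.d.memptr();
  float* o = dx.d.memptr();
  for (size_t i = 0; i < n; ++i) o[i] = ys[i] > 0 ? ds[i] : slope * ds[i];
}

inline void maxpool_forward(const Ten& x, Ten& y, std::vector<int>& idx,
                            int k, int s, int p) {
  const int Ho = out_size(x.H, k, s, p), Wo = out_size(x.W, k, s, p);
  y.resize(Ho, Wo, x.C, x.N);
  idx.assign(y.d.n_elem, -1);
  const float* xp = x.d.memptr();
  float* yp = y.d.memptr();
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < x.C; ++c) {
      const size_t base = ((size_t)n * x.C + c) * x.H * x.W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          float best = -std::numeric_limits<float>::infinity();
          long long bi = -1;
          for (int dw = 0; dw < k; ++dw) {
            const int wi = ow * s - p + dw;
            if (wi < 0 || wi >= x.W) continue;
            for (int dh = 0; dh < k; ++dh) {
              const int hi = oh * s - p + dh;
              if (hi < 0 || hi >= x.H) continue;
              const size_t xi = base + (size_t)wi * x.H + hi;
              if (xp[xi] > best) { best = xp[xi]; bi = (long long)xi; }
            }
          }
          const size_t oi = ((size_t)n * x.C + c) * Ho * Wo +
                            (size_t)ow * Ho + oh;
          yp[oi] = best; idx[oi] = (int)bi;
        }
    }
}

inline void maxpool_backward(const Ten& x, const Ten& dy,
                             const std::vector<int>& idx, Ten& dx) {
  dx.resize(x.H, x.W, x.C, x.N);
  dx.d.zeros();
  float* o = dx.d.memptr();
  const float* ds = dy.d.memptr();
  for (size_t i = 0; i < dy.d.n_elem; ++i) o[idx[i]] += ds[i];
}

// AdamW with decoupled weight decay and bias correction; zeroes the grad.
inline void adamw(arma::fmat& w, arma::fmat& g, arma::fmat& m, arma::fmat& v,
                  float lr, float b1, float b2, float eps, float wd, int t) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * arma::square(g);
  const float bc1 = 1.0f - std::pow(b1, (float)t);
  const float bc2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + eps) + wd * w);
  g.zeros();
}

inline void adamw(arma::fvec& w, arma::fvec& g, arma::fvec& m, arma::fvec& v,
                  float lr, float b1, float b2, float eps, float wd, int t) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * arma::square(g);
  const float bc1 = 1.0f - std::pow(b1, (float)t);
  const float bc2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + eps) + wd * w);
  g.zeros();
}

inline void conv_step(Conv& c, float lr, float b1, float b2, float eps,
                      float wd, int t) {
  adamw(c.W, c.gW, c.mW, c.vW, lr, b1, b2, eps, wd, t);
  if (c.sp.bias)   // no decay on biases
    adamw(c.b, c.gb, c.mb, c.vb, lr, b1, b2, eps, 0.0f, t);
}

inline void bn_step(BN& b, float lr, float b1, float b2, float eps, int t) {
  // no weight decay on batch-norm scale/shift
  adamw(b.gamma, b.ggamma, b.mg, b.vg, lr, b1, b2, eps, 0.0f, t);
  adamw(b.beta, b.gbeta, b.mb, b.vb, lr, b1, b2, eps, 0.0f, t);
}

inline void fill_fmat(arma::fmat& dst, const Rcpp::NumericVector& src) {
  if ((size_t)src.size() != dst.n_elem)
    Rcpp::stop("weight size mismatch");
  const double* s = src.begin();
  float* d = dst.memptr();
  for (size_t i = 0; i < dst.n_elem; ++i) d[i] = (float)s[i];
}

inline void fill_fvec(arma::fvec& dst, const Rcpp::NumericVector& src) {
  if ((size_t)src.size() != dst.n_elem)
    Rcpp::stop("parameter size mismatch");
  const double* s = src.begin();
  float* d = dst.memptr();
  for (size_t i = 0; i < dst.n_elem; ++i) d[i] = (float)s[i];
}

inline Rcpp::NumericVector to_R(const arma::fmat& m) {
  Rcpp::NumericVector out(m.n_elem);
  const float* s = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) out[i] = (double)s[i];
  return out;
}

inline Rcpp::NumericVector to_R(const arma::fvec& m) {
  Rcpp::NumericVector out(m.n_elem);
  const float* s = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) out[i] = (double)s[i];
  return out;
}

inline void ten_from_R(Ten& t, const Rcpp::NumericVector& x,
                       const Rcpp::IntegerVector& dim) {
  t.resize(dim[0], dim[1], dim[2], dim[3]);
  if ((size_t)x.size() != t.d.n_elem) Rcpp::stop("tensor size mismatch");
  const double* s = x.begin();
  float* d = t.d.memptr();
  for (size_t i = 0; i < t.d.n_elem; ++i) d[i] = (float)s[i];
}

inline Rcpp::NumericVector ten_to_R(const Ten& t) {
  Rcpp::NumericVector out(t.d.n_elem);
  out.attr("dim") = Rcpp::IntegerVector::create(t.H, t.W, t.C, t.N);
  const float* s = t.d.memptr();
  double* d = out.begin();
  for (size_t i = 0; i < t.d.n_elem; ++i) d[i] = (double)s[i];
  return out;
}

// conv weight list element: (kh, kw, cin, cout) double array (+ optional
// bias attached separately); bn element: list(gamma, beta[, run_mean,
// run_var]).
inline void set_conv(Conv& c, const Rcpp::List& el) {
  fill_fmat(c.W, el["w"]);
  if (c.sp.bias) fill_fvec(c.b, el["b"]);
}

inline void set_bn(BN& b, const Rcpp::List& el) {
  fill_fvec(b.gamma, el["gamma"]);
  fill_fvec(b.beta, el["beta"]);
  if (el.containsElementNamed("run_mean")) {
    fill_fvec(b.rmean, el["run_mean"]);
    fill_fvec(b.rvar, el["run_var"]);
  }
}

inline Rcpp::List get_conv(const Conv& c) {
  using namespace Rcpp;
  if (c.sp.bias)
    return List::create(_["w"] = to_R(c.W), _["b"] = to_R(c.b));
  return List::create(_["w"] = to_R(c.W));
}

inline Rcpp::List get_bn(const BN& b) {
  using namespace Rcpp;
  return List::create(_["gamma"] = to_R(b.gamma), _["beta"] = to_R(b.beta),
                      _["run_mean"] = to_R(b.rmean),
                      _["run_var"] = to_R(b.rvar));
}

inline Rcpp::List grad_conv(const Conv& c) {
  using namespace Rcpp;
  if (c.sp.bias)
    return List::create(_["dw"] = to_R(c.gW), _["db"] = to_R(c.gb));
  return List::create(_["dw"] = to_R(c.gW));
}

inline Rcpp::List grad_bn(const BN& b) {
  using namespace Rcpp;
  return List::create(_["dgamma"] = to_R(b.ggamma),
                      _["dbeta"] = to_R(b.gbeta));
}

} // namespace hmhn_fast

#endif
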