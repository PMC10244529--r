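// Batch normalisation and element-wise activation kernels: single-pass
// loops over (H, W, C, N) arrays, avoiding the intermediate copies that
// vectorised R would allocate on feature maps of tens of megabytes.

#include <Rcpp.h>
using namespace Rcpp;

// Training-mode batch norm. Returns y plus the per-channel batch mean and
// inverse standard deviation needed for the backward pass (the normalised
// activations are recomputed there from x, so nothing else is cached).
// [[Rcpp::export]]
List cpp_bn_forward_train(NumericVector x, IntegerVector xdim,
                          NumericVector gamma, NumericVector beta,
                          double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      mu[c] += s; var[c] += s2;
    }
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = std::max(var[c] / m - mu[c] * mu[c], 0.0);
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - mu[c] * a;
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xs = xp + off;
      double* ys = yp + off;
      for (size_t i = 0; i < HW; ++i) ys[i] = xs[i] * a + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector cpp_bn_forward_eval(NumericVector x, IntegerVector xdim,
                                  NumericVector scale, NumericVector shift) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double a = scale[c], b = shift[c];
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * a + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, IntegerVector xdim,
                     NumericVector mu, NumericVector invstd,
                     NumericVector gamma, NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double muc = mu[c], isc = invstd[c];
      double sdy = 0, sdx = 0;
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xp[off + i] - muc) * isc;
        sdy += dyp[off + i];
        sdx += dyp[off + i] * xhat;
      }
      dbeta[c] += sdy; dgamma[c] += sdx;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double muc = mu[c], isc = invstd[c];
      const double coef = gamma[c] * isc;
      const double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xp[off + i] - muc) * isc;
        dxp[off + i] = coef * (dyp[off + i] - t1 - xhat * t2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_slope_relu_forward(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_slope_relu_backward(NumericVector x, NumericVector dy,
                                      double slope) {
  NumericVector dx(x.size());
  dx.attr("dim") = dy.attr("dim");
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) dxp[i] = xp[i] > 0 ? dyp[i] : slope * dyp[i];
  return dx;
}
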