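// Single-precision C++ implementation of the deep-feature-fusion front
// end: two feature-transformation nets (conv3x3 C->hidden, BN, leaky ReLU,
// conv3x3 hidden->C, BN, leaky ReLU) whose outputs are summed and passed
// through a 1x1 fusion net. These run on full-resolution images, so the
// float fast path matters as much as for the backbone. The R layer
// implementation in dff.R is the reference.

#include "fast_common.h"
using namespace Rcpp;
using namespace hmhn_fast;

namespace {

constexpr float kSlope = 0.01f;

struct FT {
  Conv conv1, conv2;
  BN bn1, bn2;
  // caches
  Ten x_in, c1, r1, c2, y;
  void init(int C, int hidden) {
    conv1.init({3, 3, C, hidden, 1, 1, 1, true});
    bn1.init(hidden);
    conv2.init({3, 3, hidden, C, 1, 1, 1, true});
    bn2.init(C);
  }
};

struct DffState {
  float momentum = 0.1f, eps = 1e-5f;
  int C, hidden;
  FT ft1, ft2;
  Conv f_conv;
  BN f_bn;
  // caches
  Ten s_in, fc, y_out;
  arma::fmat scratch;
  bool train_cached = false;

  DffState(int C_, int hidden_) : C(C_), hidden(hidden_) {
    ft1.init(C, hidden);
    ft2.init(C, hidden);
    f_conv.init({1, 1, C, C, 1, 0, 0, true});
    f_bn.init(C);
  }
};

void ft_forward(DffState& st, FT& f, const Ten& x, bool train) {
  f.x_in = x;
  Ten t;
  conv_forward(f.conv1, x, f.c1, st.scratch);
  bn_forward(f.bn1, f.c1, t, train, st.momentum, st.eps);
  srelu_forward(t, f.r1, kSlope);
  conv_forward(f.conv2, f.r1, f.c2, st.scratch);
  bn_forward(f.bn2, f.c2, t, train, st.momentum, st.eps);
  srelu_forward(t, f.y, kSlope);
}

// returns dx in *dx when requested
void ft_backward(DffState& st, FT& f, const Ten& dy, Ten* dx) {
  Ten d, t1, t2;
  srelu_backward(f.y, dy, d, kSlope);
  bn_backward(f.bn2, f.c2, d, t1);
  conv_backward(f.conv2, f.r1, t1, &t2, st.scratch);
  srelu_backward(f.r1, t2, t1, kSlope);
  bn_backward(f.bn1, f.c1, t1, t2);
  conv_backward(f.conv1, f.x_in, t2, dx, st.scratch);
}

// weight order: ft1 conv1, ft1 bn1, ft1 conv2, ft1 bn2, same for ft2,
// fusion conv, fusion bn
void dff_set(DffState& st, List w) {
  int i = 0;
  for (FT* f : {&st.ft1, &st.ft2}) {
    set_conv(f->conv1, w[i++]); set_bn(f->bn1, w[i++]);
    set_conv(f->conv2, w[i++]); set_bn(f->bn2, w[i++]);
  }
  set_conv(st.f_conv, w[i++]);
  set_bn(st.f_bn, w[i++]);
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_dff_create(List weights, int C, int hidden) {
  XPtr<DffState> p(new DffState(C, hidden), true);
  dff_set(*p, weights);
  return p;
}

// [[Rcpp::export]]
void cpp_dff_set_weights(SEXP ptr, List weights) {
  XPtr<DffState> p(ptr);
  dff_set(*p, weights);
}

// [[Rcpp::export]]
List cpp_dff_get_weights(SEXP ptr) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  List out;
  for (FT* f : {&st.ft1, &st.ft2}) {
    out.push_back(get_conv(f->conv1)); out.push_back(get_bn(f->bn1));
    out.push_back(get_conv(f->conv2)); out.push_back(get_bn(f->bn2));
  }
  out.push_back(get_conv(st.f_conv));
  out.push_back(get_bn(st.f_bn));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dff_forward(SEXP ptr, NumericVector g, NumericVector gt,
                              IntegerVector xdim, bool train) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  Ten tg, tgt;
  ten_from_R(tg, g, xdim);
  ten_from_R(tgt, gt, xdim);
  ft_forward(st, st.ft1, tg, train);
  ft_forward(st, st.ft2, tgt, train);
  st.s_in = st.ft1.y;
  st.s_in.d += st.ft2.y.d;
  Ten t;
  conv_forward(st.f_conv, st.s_in, st.fc, st.scratch);
  bn_forward(st.f_bn, st.fc, t, train, st.momentum, st.eps);
  srelu_forward(t, st.y_out, kSlope);
  st.train_cached = train;
  return ten_to_R(st.y_out);
}

// Backpropagates into both branches' parameters; returns the gradient on
// g_tilde (the raw-image branch has no trainable modules upstream).
// [[Rcpp::export]]
NumericVector cpp_dff_backward(SEXP ptr, NumericVector dyR) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  if (!st.train_cached)
    stop("dff backward requires a training-mode forward");
  Ten dy;
  ten_from_R(dy, dyR, IntegerVector::create(st.y_out.H, st.y_out.W,
                                            st.y_out.C, st.y_out.N));
  Ten d, ds, t;
  srelu_backward(st.y_out, dy, d, kSlope);
  bn_backward(st.f_bn, st.fc, d, t);
  conv_backward(st.f_conv, st.s_in, t, &ds, st.scratch);
  ft_backward(st, st.ft1, ds, nullptr);
  Ten dgt;
  ft_backward(st, st.ft2, ds, &dgt);
  return ten_to_R(dgt);
}

// [[Rcpp::export]]
void cpp_dff_step(SEXP ptr, double lr, double beta1, double beta2,
                  double eps, double wd, int t) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  const float flr = lr, b1 = beta1, b2 = beta2, fe = eps, fwd = wd;
  for (FT* f : {&st.ft1, &st.ft2}) {
    conv_step(f->conv1, flr, b1, b2, fe, fwd, t);
    bn_step(f->bn1, flr, b1, b2, fe, t);
    conv_step(f->conv2, flr, b1, b2, fe, fwd, t);
    bn_step(f->bn2, flr, b1, b2, fe, t);
  }
  conv_step(st.f_conv, flr, b1, b2, fe, fwd, t);
  bn_step(st.f_bn, flr, b1, b2, fe, t);
}

// [[Rcpp::export]]
void cpp_dff_zero_grads(SEXP ptr) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  auto zc = [](Conv& c) { c.gW.zeros(); if (c.sp.bias) c.gb.zeros(); };
  auto zb = [](BN& b) { b.ggamma.zeros(); b.gbeta.zeros(); };
  for (FT* f : {&st.ft1, &st.ft2}) {
    zc(f->conv1); zb(f->bn1); zc(f->conv2); zb(f->bn2);
  }
  zc(st.f_conv); zb(st.f_bn);
}

// [[Rcpp::export]]
List cpp_dff_get_grads(SEXP ptr) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  List out;
  for (FT* f : {&st.ft1, &st.ft2}) {
    out.push_back(grad_conv(f->conv1)); out.push_back(grad_bn(f->bn1));
    out.push_back(grad_conv(f->conv2)); out.push_back(grad_bn(f->bn2));
  }
  out.push_back(grad_conv(st.f_conv));
  out.push_back(grad_bn(st.f_bn));
  return out;
}

// [[Rcpp::export]]
double cpp_dff_count_params(SEXP ptr) {
  XPtr<DffState> p(ptr);
  DffState& st = *p;
  size_t n = 0;
  for (FT* f : {&st.ft1, &st.ft2}) {
    n += f->conv1.n_params() + 2 * f->bn1.C;
    n += f->conv2.n_params() + 2 * f->bn2.C;
  }
  n += st.f_conv.n_params() + 2 * st.f_bn.C;
  return (double)n;
}
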