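// Generic single-precision convolution stack with per-layer activations,
// used for the spatial attention unit of each cross-attention head (a 1x1
// reduction followed by the configured kernel sequence and a sigmoid
// gate). Holding weights, activations and the AdamW state in C++ avoids
// converting the multi-megabyte head weights between double and float on
// every pass. The R layer implementation remains the reference.

#include "fast_common.h"
using namespace Rcpp;
using namespace hmhn_fast;

namespace {

// activation codes applied after conv i
enum Act { ACT_NONE = 0, ACT_RELU = 1, ACT_LEAKY = 2, ACT_SIGMOID = 3 };

struct CSState {
  std::vector<Conv> convs;
  std::vector<int> act;
  // caches: input of each conv, output of each (conv+activation)
  std::vector<Ten> x_in, y_out;
  arma::fmat scratch;
  bool train_cached = false;
};

void sigmoid_forward(const Ten& x, Ten& y) {
  y.resize(x.H, x.W, x.C, x.N);
  const size_t n = x.d.n_elem;
  const float* xs = x.d.memptr();
  float* ys = y.d.memptr();
  for (size_t i = 0; i < n; ++i) ys[i] = 1.0f / (1.0f + std::exp(-xs[i]));
}

void sigmoid_backward(const Ten& y, const Ten& dy, Ten& dx) {
  dx.resize(y.H, y.W, y.C, y.N);
  const size_t n = y.d.n_elem;
  const float* ys = y.d.memptr();
  const float* ds = dy.d.memptr();
  float* o = dx.d.memptr();
  for (size_t i = 0; i < n; ++i) o[i] = ds[i] * ys[i] * (1.0f - ys[i]);
}

void cs_set(CSState& st, List weights) {
  if ((size_t)weights.size() != st.convs.size())
    stop("conv stack expects %d weight entries", (int)st.convs.size());
  for (size_t i = 0; i < st.convs.size(); ++i)
    set_conv(st.convs[i], weights[i]);
}

} // namespace

// spec: integer matrix with one row per conv:
// (kh, kw, cin, cout, stride, ph, pw, bias); act: activation code per conv.
// [[Rcpp::export]]
SEXP cpp_cs_create(IntegerMatrix spec, IntegerVector act, List weights) {
  if (spec.nrow() != act.size())
    stop("spec and act length mismatch");
  XPtr<CSState> p(new CSState(), true);
  CSState& st = *p;
  st.convs.resize(spec.nrow());
  st.act.resize(spec.nrow());
  st.x_in.resize(spec.nrow());
  st.y_out.resize(spec.nrow());
  for (int i = 0; i < spec.nrow(); ++i) {
    st.convs[i].init({spec(i, 0), spec(i, 1), spec(i, 2), spec(i, 3),
                      spec(i, 4), spec(i, 5), spec(i, 6),
                      spec(i, 7) != 0});
    st.act[i] = act[i];
  }
  cs_set(st, weights);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_cs_forward(SEXP ptr, NumericVector x, IntegerVector xdim,
                             bool train) {
  XPtr<CSState> p(ptr);
  CSState& st = *p;
  Ten t;
  ten_from_R(t, x, xdim);
  for (size_t i = 0; i < st.convs.size(); ++i) {
    st.x_in[i] = t;
    Ten c;
    conv_forward(st.convs[i], st.x_in[i], c, st.scratch);
    switch (st.act[i]) {
      case ACT_NONE:    st.y_out[i] = c; break;
      case ACT_RELU:    srelu_forward(c, st.y_out[i], 0.0f); break;
      case ACT_LEAKY:   srelu_forward(c, st.y_out[i], 0.01f); break;
      case ACT_SIGMOID: sigmoid_forward(c, st.y_out[i]); break;
      default: stop("unknown activation code");
    }
    t = st.y_out[i];
  }
  st.train_cached = train;
  return ten_to_R(t);
}

// For ACT_NONE the backward needs the conv output's gradient directly; for
// relu/leaky the output's sign masks; for sigmoid y*(1-y). y_out suffices
// in every case (relu/leaky preserve sign).
// [[Rcpp::export]]
SEXP cpp_cs_backward(SEXP ptr, NumericVector dyR, bool need_dx) {
  XPtr<CSState> p(ptr);
  CSState& st = *p;
  if (!st.train_cached)
    stop("conv stack backward requires a training-mode forward");
  const int n = (int)st.convs.size();
  const Ten& last = st.y_out[n - 1];
  Ten dy;
  ten_from_R(dy, dyR, IntegerVector::create(last.H, last.W, last.C, last.N));
  Ten d, dx;
  for (int i = n - 1; i >= 0; --i) {
    switch (st.act[i]) {
      case ACT_NONE:    d = dy; break;
      case ACT_RELU:    srelu_backward(st.y_out[i], dy, d, 0.0f); break;
      case ACT_LEAKY:   srelu_backward(st.y_out[i], dy, d, 0.01f); break;
      case ACT_SIGMOID: sigmoid_backward(st.y_out[i], dy, d); break;
    }
    const bool want = need_dx || i > 0;
    conv_backward(st.convs[i], st.x_in[i], d, want ? &dx : nullptr,
                  st.scratch);
    if (want) dy = dx;
  }
  if (!need_dx) return R_NilValue;
  return ten_to_R(dy);
}

// [[Rcpp::export]]
void cpp_cs_step(SEXP ptr, double lr, double beta1, double beta2,
                 double eps, double wd, int t) {
  XPtr<CSState> p(ptr);
  for (auto& c : p->convs)
    conv_step(c, (float)lr, (float)beta1, (float)beta2, (float)eps,
              (float)wd, t);
}

// [[Rcpp::export]]
void cpp_cs_zero_grads(SEXP ptr) {
  XPtr<CSState> p(ptr);
  for (auto& c : p->convs) {
    c.gW.zeros();
    if (c.sp.bias) c.gb.zeros();
  }
}

// [[Rcpp::export]]
List cpp_cs_get_weights(SEXP ptr) {
  XPtr<CSState> p(ptr);
  List out;
  for (auto& c : p->convs) out.push_back(get_conv(c));
  return out;
}

// [[Rcpp::export]]
void cpp_cs_set_weights(SEXP ptr, List weights) {
  XPtr<CSState> p(ptr);
  cs_set(*p, weights);
}

// [[Rcpp::export]]
List cpp_cs_get_grads(SEXP ptr) {
  XPtr<CSState> p(ptr);
  List out;
  for (auto& c : p->convs) out.push_back(grad_conv(c));
  return out;
}

// [[Rcpp::export]]
double cpp_cs_count_params(SEXP ptr) {
  XPtr<CSState> p(ptr);
  size_t n = 0;
  for (auto& c : p->convs) n += c.n_params();
  return (double)n;
}
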