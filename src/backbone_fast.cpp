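// Single-precision ResNet-18 feature extractor (no classification head),
// held as persistent C++ state. Activations stay in float between the
// forward and backward pass, avoiding per-layer round trips through R
// double arrays; an AdamW step for the backbone parameters is also done
// here. The R-level layer implementation of the same network serves as the
// reference in the test suite.

#include "fast_common.h"
using namespace Rcpp;
using namespace hmhn_fast;

namespace {

struct BlockSpec { int cin, cout, stride; bool ds; };

struct Block {
  BlockSpec sp;
  Conv conv1, conv2, ds_conv;
  BN bn1, bn2, ds_bn;
  // caches
  Ten x_in, c1, r1, c2, dsc, y_out;
};

struct BBState {
  float momentum = 0.1f, eps = 1e-5f;
  Conv stem_conv;
  BN stem_bn;
  std::vector<Block> blocks;
  // caches
  Ten x_in, s_c1, s_r1, s_pool;
  std::vector<int> pool_idx;
  arma::fmat scratch;
  bool train_cached = false;

  explicit BBState(int cin) {
    stem_conv.init({7, 7, cin, 64, 2, 3, 3, false});
    stem_bn.init(64);
    const BlockSpec bs[8] = {
      {64, 64, 1, false},  {64, 64, 1, false},
      {64, 128, 2, true},  {128, 128, 1, false},
      {128, 256, 2, true}, {256, 256, 1, false},
      {256, 512, 2, true}, {512, 512, 1, false}};
    blocks.resize(8);
    for (int i = 0; i < 8; ++i) {
      Block& b = blocks[i];
      b.sp = bs[i];
      b.conv1.init({3, 3, bs[i].cin, bs[i].cout, bs[i].stride, 1, 1, false});
      b.bn1.init(bs[i].cout);
      b.conv2.init({3, 3, bs[i].cout, bs[i].cout, 1, 1, 1, false});
      b.bn2.init(bs[i].cout);
      if (bs[i].ds) {
        b.ds_conv.init({1, 1, bs[i].cin, bs[i].cout, bs[i].stride, 0, 0,
                        false});
        b.ds_bn.init(bs[i].cout);
      }
    }
  }
};

void block_forward(BBState& st, Block& b, const Ten& x, bool train) {
  b.x_in = x;  // needed by the conv backward
  Ten t;
  conv_forward(b.conv1, x, b.c1, st.scratch);
  bn_forward(b.bn1, b.c1, t, train, st.momentum, st.eps);
  srelu_forward(t, b.r1, 0.0f);
  conv_forward(b.conv2, b.r1, b.c2, st.scratch);
  Ten main_out;
  bn_forward(b.bn2, b.c2, main_out, train, st.momentum, st.eps);
  if (b.sp.ds) {
    Ten sc;
    conv_forward(b.ds_conv, x, b.dsc, st.scratch);
    bn_forward(b.ds_bn, b.dsc, sc, train, st.momentum, st.eps);
    main_out.d += sc.d;
  } else {
    main_out.d += x.d;
  }
  srelu_forward(main_out, b.y_out, 0.0f);
}

void block_backward(BBState& st, Block& b, const Ten& dy, Ten& dx) {
  Ten d, t1, t2;
  srelu_backward(b.y_out, dy, d, 0.0f);
  // main branch
  bn_backward(b.bn2, b.c2, d, t1);
  conv_backward(b.conv2, b.r1, t1, &t2, st.scratch);
  srelu_backward(b.r1, t2, t1, 0.0f);
  bn_backward(b.bn1, b.c1, t1, t2);
  conv_backward(b.conv1, b.x_in, t2, &dx, st.scratch);
  // shortcut
  if (b.sp.ds) {
    bn_backward(b.ds_bn, b.dsc, d, t1);
    conv_backward(b.ds_conv, b.x_in, t1, &t2, st.scratch);
    dx.d += t2.d;
  } else {
    dx.d += d.d;
  }
}

// weights: list in fixed order: stem conv, stem bn, then per block
// conv1, bn1, conv2, bn2[, ds_conv, ds_bn]. Conv entries are
// list(w[, b]); bn entries list(gamma, beta[, run_mean, run_var]).
void bb_set(BBState& st, List weights) {
  int i = 0;
  set_conv(st.stem_conv, weights[i++]);
  set_bn(st.stem_bn, weights[i++]);
  for (auto& blk : st.blocks) {
    set_conv(blk.conv1, weights[i++]);
    set_bn(blk.bn1, weights[i++]);
    set_conv(blk.conv2, weights[i++]);
    set_bn(blk.bn2, weights[i++]);
    if (blk.sp.ds) {
      set_conv(blk.ds_conv, weights[i++]);
      set_bn(blk.ds_bn, weights[i++]);
    }
  }
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_bb_create(List weights, int cin) {
  XPtr<BBState> p(new BBState(cin), true);
  bb_set(*p, weights);
  return p;
}

// [[Rcpp::export]]
void cpp_bb_set_weights(SEXP ptr, List weights) {
  XPtr<BBState> p(ptr);
  bb_set(*p, weights);
}

// [[Rcpp::export]]
List cpp_bb_get_weights(SEXP ptr) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  List out;
  out.push_back(get_conv(st.stem_conv));
  out.push_back(get_bn(st.stem_bn));
  for (auto& blk : st.blocks) {
    out.push_back(get_conv(blk.conv1));
    out.push_back(get_bn(blk.bn1));
    out.push_back(get_conv(blk.conv2));
    out.push_back(get_bn(blk.bn2));
    if (blk.sp.ds) {
      out.push_back(get_conv(blk.ds_conv));
      out.push_back(get_bn(blk.ds_bn));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bb_forward(SEXP ptr, NumericVector x, IntegerVector xdim,
                             bool train) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  ten_from_R(st.x_in, x, xdim);
  Ten t;
  conv_forward(st.stem_conv, st.x_in, st.s_c1, st.scratch);
  bn_forward(st.stem_bn, st.s_c1, t, train, st.momentum, st.eps);
  srelu_forward(t, st.s_r1, 0.0f);
  maxpool_forward(st.s_r1, st.s_pool, st.pool_idx, 3, 2, 1);
  const Ten* cur = &st.s_pool;
  for (auto& blk : st.blocks) {
    block_forward(st, blk, *cur, train);
    cur = &blk.y_out;
  }
  st.train_cached = train;
  return ten_to_R(*cur);
}

// [[Rcpp::export]]
SEXP cpp_bb_backward(SEXP ptr, NumericVector dyR, bool need_dx) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  if (!st.train_cached)
    stop("backbone backward requires a training-mode forward");
  const Ten& last = st.blocks.back().y_out;
  Ten dy;
  ten_from_R(dy, dyR, IntegerVector::create(last.H, last.W, last.C, last.N));
  Ten dx;
  for (int i = (int)st.blocks.size() - 1; i >= 0; --i) {
    block_backward(st, st.blocks[i], dy, dx);
    dy = dx;
  }
  Ten t1, t2;
  maxpool_backward(st.s_r1, dy, st.pool_idx, t1);
  srelu_backward(st.s_r1, t1, t2, 0.0f);
  bn_backward(st.stem_bn, st.s_c1, t2, t1);
  if (!need_dx) {
    conv_backward(st.stem_conv, st.x_in, t1, nullptr, st.scratch);
    return R_NilValue;
  }
  conv_backward(st.stem_conv, st.x_in, t1, &t2, st.scratch);
  return ten_to_R(t2);
}

// [[Rcpp::export]]
void cpp_bb_step(SEXP ptr, double lr, double beta1, double beta2,
                 double eps, double wd, int t) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  const float flr = lr, b1 = beta1, b2 = beta2, fe = eps, fwd = wd;
  conv_step(st.stem_conv, flr, b1, b2, fe, fwd, t);
  bn_step(st.stem_bn, flr, b1, b2, fe, t);
  for (auto& blk : st.blocks) {
    conv_step(blk.conv1, flr, b1, b2, fe, fwd, t);
    bn_step(blk.bn1, flr, b1, b2, fe, t);
    conv_step(blk.conv2, flr, b1, b2, fe, fwd, t);
    bn_step(blk.bn2, flr, b1, b2, fe, t);
    if (blk.sp.ds) {
      conv_step(blk.ds_conv, flr, b1, b2, fe, fwd, t);
      bn_step(blk.ds_bn, flr, b1, b2, fe, t);
    }
  }
}

// [[Rcpp::export]]
void cpp_bb_zero_grads(SEXP ptr) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  auto zc = [](Conv& c) { c.gW.zeros(); if (c.sp.bias) c.gb.zeros(); };
  auto zb = [](BN& b) { b.ggamma.zeros(); b.gbeta.zeros(); };
  zc(st.stem_conv); zb(st.stem_bn);
  for (auto& blk : st.blocks) {
    zc(blk.conv1); zb(blk.bn1); zc(blk.conv2); zb(blk.bn2);
    if (blk.sp.ds) { zc(blk.ds_conv); zb(blk.ds_bn); }
  }
}

// [[Rcpp::export]]
List cpp_bb_get_grads(SEXP ptr) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  List out;
  out.push_back(grad_conv(st.stem_conv));
  out.push_back(grad_bn(st.stem_bn));
  for (auto& blk : st.blocks) {
    out.push_back(grad_conv(blk.conv1));
    out.push_back(grad_bn(blk.bn1));
    out.push_back(grad_conv(blk.conv2));
    out.push_back(grad_bn(blk.bn2));
    if (blk.sp.ds) {
      out.push_back(grad_conv(blk.ds_conv));
      out.push_back(grad_bn(blk.ds_bn));
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_bb_count_params(SEXP ptr) {
  XPtr<BBState> p(ptr);
  BBState& st = *p;
  size_t n = st.stem_conv.n_params() + 2 * st.stem_bn.C;
  for (auto& blk : st.blocks) {
    n += blk.conv1.n_params() + 2 * blk.bn1.C;
    n += blk.conv2.n_params() + 2 * blk.bn2.C;
    if (blk.sp.ds) n += blk.ds_conv.n_params() + 2 * blk.ds_bn.C;
  }
  return (double)n;
}
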