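# Single-precision C++ implementation of the ResNet-18 feature extractor.
#
# The backbone dominates the network's compute, so its forward, backward
# and optimiser step run entirely in C++ with activations kept in float
# between passes (see src/backbone_fast.cpp). The R-level layer
# implementation in backbone.R computes the same function and serves as
# the reference in the test suite. Weight initialisation happens here in R
# with the session RNG, and in the same draw order as the reference
# implementation, so both produce identical parameters under one seed.

bn_par_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

fast_backbone <- function(cin = 3L) {
  blocks <- list(c(64L, 64L, 1L), c(64L, 64L, 1L),
                 c(64L, 128L, 2L), c(128L, 128L, 1L),
                 c(128L, 256L, 2L), c(256L, 256L, 1L),
                 c(256L, 512L, 2L), c(512L, 512L, 1L))
  w <- list(list(w = he_init(c(7, 7, cin, 64), fan_in = 7 * 7 * cin)),
            bn_par_init(64))
  for (b in blocks) {
    ci <- b[1]; co <- b[2]; s <- b[3]
    conv1 <- list(w = he_init(c(3, 3, ci, co), fan_in = 9 * ci))
    conv2 <- list(w = he_init(c(3, 3, co, co), fan_in = 9 * co))
    ds <- s != 1L || ci != co
    w <- c(w, list(conv1, bn_par_init(co), conv2, bn_par_init(co)))
    if (ds)
      w <- c(w, list(list(w = he_init(c(1, 1, ci, co), fan_in = ci)),
                     bn_par_init(co)))
  }
  fb <- new.env(parent = emptyenv())
  fb$cin <- as.integer(cin)
  fb$ptr <- cpp_bb_create(w, fb$cin)
  class(fb) <- "hmhn_fast_backbone"
  fb
}

fb_step <- function(fb, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    weight_decay = 0.01, t = 1L) {
  cpp_bb_step(fb$ptr, lr, beta1, beta2, eps, weight_decay, as.integer(t))
  invisible(fb)
}

# Pull the weights (and batch-norm running statistics) as plain R doubles,
# e.g. for a checkpoint; `fb_set_weights()` pushes them back.
fb_weights <- function(fb) cpp_bb_get_weights(fb$ptr)

fb_set_weights <- function(fb, weights) {
  cpp_bb_set_weights(fb$ptr, weights)
  invisible(fb)
}

fb_grads <- function(fb) cpp_bb_get_grads(fb$ptr)

# ---- fast deep-feature-fusion front end -------------------------------------

fast_dff <- function(C = 3L, ft_hidden = 16L) {
  conv_par <- function(kh, kw, ci, co)
    list(w = he_init(c(kh, kw, ci, co), fan_in = kh * kw * ci),
         b = numeric(co))
  ft_par <- function() {
    c1 <- conv_par(3, 3, C, ft_hidden)
    c2 <- conv_par(3, 3, ft_hidden, C)
    list(c1, bn_par_init(ft_hidden), c2, bn_par_init(C))
  }
  w <- c(ft_par(), ft_par(),
         list(conv_par(1, 1, C, C), bn_par_init(C)))
  df <- new.env(parent = emptyenv())
  df$C <- as.integer(C)
  df$hidden <- as.integer(ft_hidden)
  df$ptr <- cpp_dff_create(w, df$C, df$hidden)
  class(df) <- "hmhn_fast_dff"
  df
}

dff_step <- function(df, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0.01, t = 1L) {
  cpp_dff_step(df$ptr, lr, beta1, beta2, eps, weight_decay, as.integer(t))
  invisible(df)
}

dff_weights <- function(df) cpp_dff_get_weights(df$ptr)

dff_set_weights <- function(df, weights) {
  cpp_dff_set_weights(df$ptr, weights)
  invisible(df)
}

dff_grads <- function(df) cpp_dff_get_grads(df$ptr)

# ---- fast spatial attention stacks -------------------------------------------

# Mirrors make_spatial_unit() (mab.R): a 1x1 reduction, the configured
# kernel sequence, and a sigmoid on the final single-channel gate. Weight
# draws happen here in R, in the same order as the reference, so equal
# seeds give equal parameters.
fast_spatial_unit <- function(cin, cfg) {
  kernels <- kernel_configs[[cfg$kernel_config]]
  widths <- c(cfg$reduce_channels, cfg$head_widths)
  widths <- widths[seq_len(length(kernels))]
  chans <- c(cin, widths, 1L)
  nconv <- length(kernels) + 1L
  spec <- matrix(0L, nrow = nconv, ncol = 8L)
  spec[1, ] <- c(1L, 1L, cin, chans[2], 1L, 0L, 0L, 1L)
  w <- list(list(w = he_init(c(1, 1, cin, chans[2]), fan_in = cin),
                 b = numeric(chans[2])))
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    p <- same_pad(k)
    spec[i + 1L, ] <- c(k[1], k[2], chans[i + 1], chans[i + 2], 1L,
                        p[1], p[2], 1L)
    w <- c(w, list(list(
      w = he_init(c(k[1], k[2], chans[i + 1], chans[i + 2]),
                  fan_in = k[1] * k[2] * chans[i + 1]),
      b = numeric(chans[i + 2]))))
  }
  act <- c(rep(0L, length(kernels)), 3L)   # sigmoid only on the gate
  st <- new.env(parent = emptyenv())
  st$ptr <- cpp_cs_create(spec, act, w)
  st$spec <- spec
  st$act <- act
  class(st) <- "hmhn_fast_stack"
  st
}

cs_step <- function(st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    weight_decay = 0.01, t = 1L) {
  cpp_cs_step(st$ptr, lr, beta1, beta2, eps, weight_decay, as.integer(t))
  invisible(st)
}

cs_weights <- function(st) cpp_cs_get_weights(st$ptr)

cs_set_weights <- function(st, weights) {
  cpp_cs_set_weights(st$ptr, weights)
  invisible(st)
}

cs_grads <- function(st) cpp_cs_get_grads(st$ptr)

cs_n_params <- function(st) cpp_cs_count_params(st$ptr)
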