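# Cross-attention heads: gate ranges, broadcasting identities, kernel
# separability, head independence and the fast spatial stack against the
# R reference.

test_that("spatial and channel gates lie in (0,1) and shapes match", {
  set.seed(1)
  cfg <- head_config(num_heads = 2L)
  hd <- hmhn:::cross_head(512L, cfg)
  x <- array(rnorm(7 * 7 * 512 * 2), c(7, 7, 512, 2))
  out <- hmhn:::head_forward(hd, x, train = FALSE)
  expect_true(all(out$spatial_gate > 0 & out$spatial_gate < 1))
  expect_true(all(out$channel_gate > 0 & out$channel_gate < 1))
  expect_identical(dim(out$s), dim(x))
  expect_identical(dim(out$c), dim(x))
  expect_identical(dim(out$spatial_gate), c(7L, 7L, 1L, 2L))
  expect_identical(dim(out$channel_gate), c(2L, 512L))
})

test_that("C_i equals S_i times the broadcast channel gate", {
  set.seed(2)
  cfg <- head_config()
  hd <- hmhn:::cross_head(64L, cfg)
  x <- array(rnorm(5 * 5 * 64 * 3), c(5, 5, 64, 3))
  out <- hmhn:::head_forward(hd, x, train = FALSE)
  gce <- hmhn:::expand_channel_gate(out$channel_gate, dim(x))
  expect_equal(out$c, out$s * gce, tolerance = 1e-12)
  # all-ones gate is the multiplicative identity
  ones <- hmhn:::expand_channel_gate(matrix(1, 3, 64), dim(x))
  expect_equal(out$s * ones, out$s)
})

test_that("1x3 then 3x1 convolution equals the rank-1 3x3 convolution", {
  set.seed(3)
  u <- rnorm(3); v <- rnorm(3)
  c13 <- hmhn:::nn_conv2d(1, 1, 1, 3, pad = c(0L, 1L))
  c31 <- hmhn:::nn_conv2d(1, 1, 3, 1, pad = c(1L, 0L))
  c33 <- hmhn:::nn_conv2d(1, 1, 3, 3, pad = c(1L, 1L))
  c13$w <- array(u, c(1, 3, 1, 1)); c13$b <- 0
  c31$w <- array(v, c(3, 1, 1, 1)); c31$b <- 0
  c33$w <- array(outer(v, u), c(3, 3, 1, 1)); c33$b <- 0
  x <- array(rnorm(12 * 12), c(12, 12, 1, 1))
  sep <- hmhn:::layer_forward(c31, hmhn:::layer_forward(c13, x))
  full <- hmhn:::layer_forward(c33, x)
  expect_lt(max(abs(sep - full)), 1e-5)
})

test_that("channel unit equals the naive two-matrix oracle", {
  set.seed(4)
  cfg <- head_config(channel_bottleneck = 8L)
  cu <- hmhn:::make_channel_unit(32L, cfg)
  ls <- hmhn:::seq_layers(cu)
  v <- matrix(rnorm(3 * 32), 3, 32)
  got <- hmhn:::seq_forward(cu, v, train = FALSE)
  h <- sweep(v %*% ls[[1]]$w, 2, ls[[1]]$b, "+")
  h <- ifelse(h > 0, h, 0.01 * h)
  z <- sweep(h %*% ls[[3]]$w, 2, ls[[3]]$b, "+")
  expect_equal(got, 1 / (1 + exp(-z)), tolerance = 1e-12)
})

test_that("heads are independent and k = 1 degenerates to one unit", {
  set.seed(5)
  cfg2 <- head_config(num_heads = 2L)
  mab <- hmhn:::mab_module(64L, cfg2)
  x <- array(rnorm(4 * 4 * 64 * 2), c(4, 4, 64, 2))
  out <- hmhn:::mab_forward(mab, x, train = FALSE)
  solo <- lapply(mab$heads, function(h)
    hmhn:::head_forward(h, x, train = FALSE)$c)
  expect_equal(out$c_maps[[1]], solo[[1]])
  expect_equal(out$c_maps[[2]], solo[[2]])
  mab1 <- hmhn:::mab_module(64L, head_config(num_heads = 1L))
  out1 <- hmhn:::mab_forward(mab1, x, train = FALSE)
  expect_length(out1$c_maps, 1)
})

test_that("parameter counting matches closed forms", {
  set.seed(6)
  expect_equal(hmhn:::n_params_layer(hmhn:::nn_conv2d(3, 12, 1, 1)), 48)
  expect_equal(hmhn:::n_params_layer(hmhn:::nn_linear(10, 7)), 77)
})

test_that("fast spatial stack matches the R reference", {
  cfg <- head_config()
  set.seed(31)
  ref <- hmhn:::make_spatial_unit(512L, cfg)
  set.seed(31)
  fst <- hmhn:::fast_spatial_unit(512L, cfg)
  expect_equal(hmhn:::cs_n_params(fst),
               sum(vapply(hmhn:::seq_layers(ref), hmhn:::n_params_layer,
                          0)))
  x <- array(rnorm(7 * 7 * 512 * 2), c(7, 7, 512, 2))
  yr <- hmhn:::seq_forward(ref, x, train = TRUE)
  yf <- hmhn:::spatial_forward(fst, x, train = TRUE)
  expect_lt(rel_diff(yf, yr), 1e-4)
  dy <- array(rnorm(length(yr)), dim(yr))
  dxr <- hmhn:::seq_backward(ref, dy)
  dxf <- hmhn:::spatial_backward(fst, dy)
  expect_lt(rel_diff(dxf, dxr), 1e-3)
  gr <- hmhn:::seq_layers(ref)[[1]]$gw
  gf <- hmhn:::cs_grads(fst)[[1]]$dw
  expect_lt(rel_diff(gf, gr), 1e-3)
})

test_that("head gradients reach both gate parameter sets", {
  set.seed(7)
  cfg <- head_config(reduce_channels = 8L, head_widths = c(8L, 8L),
                     channel_bottleneck = 4L)
  hd <- hmhn:::cross_head(16L, cfg)
  x <- array(rnorm(4 * 4 * 16 * 2), c(4, 4, 16, 2))
  out <- hmhn:::head_forward(hd, x, train = TRUE)
  hmhn:::head_backward(hd, array(1, dim(out$c)))
  gsp <- hmhn:::cs_grads(hd$spatial)[[1]]$dw
  gch <- hmhn:::seq_layers(hd$channel)[[1]]$gw
  expect_gt(max(abs(gsp)), 0)
  expect_gt(max(abs(gch)), 0)
})
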