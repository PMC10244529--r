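# Deep feature fusion: shape contracts, FT independence, linearity of the
# sum node and agreement between the single-precision implementation and
# the R reference.

test_that("DFF preserves the image shape", {
  set.seed(1)
  df <- hmhn:::fast_dff(3L, 16L)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- hmhn:::dff_forward(df, x, x, train = FALSE)
  expect_identical(dim(y), dim(x))
})

test_that("independently initialised FT nets differ elementwise", {
  set.seed(2)
  ref <- hmhn:::dff_module(3L, 16L)
  x <- array(runif(8 * 8 * 3 * 1), c(8, 8, 3, 1))
  a1 <- hmhn:::seq_forward(ref$ft1, x, train = FALSE)
  a2 <- hmhn:::seq_forward(ref$ft2, x, train = FALSE)
  expect_gt(min(abs(a1 - a2)), 0)
})

test_that("with FT2 copied from FT1, dff(g, g) = fusion(2 FT1(g))", {
  set.seed(3)
  ref <- hmhn:::dff_module(3L, 16L)
  l1 <- hmhn:::seq_layers(ref$ft1)
  l2 <- hmhn:::seq_layers(ref$ft2)
  for (i in seq_along(l1))
    for (f in c("w", "b", "gamma", "beta", "run_mean", "run_var"))
      if (!is.null(l1[[i]][[f]])) assign(f, l1[[i]][[f]], envir = l2[[i]])
  x <- array(runif(10 * 10 * 3 * 2), c(10, 10, 3, 2))
  got <- hmhn:::dff_forward(ref, x, x, train = FALSE)
  want <- hmhn:::seq_forward(ref$fusion,
                             2 * hmhn:::seq_forward(ref$ft1, x,
                                                    train = FALSE),
                             train = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("shape mismatch between the two inputs is rejected", {
  set.seed(4)
  df <- hmhn:::fast_dff(3L, 16L)
  a <- array(0, c(8, 8, 3, 1)); b <- array(0, c(9, 8, 3, 1))
  expect_error(hmhn:::dff_forward(df, a, b), "identical shapes")
})

test_that("fast DFF matches the R reference forward and backward", {
  set.seed(11)
  ref <- hmhn:::dff_module(3L, 16L)
  set.seed(11)
  fst <- hmhn:::fast_dff(3L, 16L)
  x <- array(runif(24 * 24 * 3 * 3), c(24, 24, 3, 3))
  gt <- array(runif(24 * 24 * 3 * 3), c(24, 24, 3, 3))
  yr <- hmhn:::dff_forward(ref, x, gt, train = TRUE)
  yf <- hmhn:::dff_forward(fst, x, gt, train = TRUE)
  expect_lt(rel_diff(yf, yr), 1e-4)
  dy <- array(rnorm(length(yr)), dim(yr))
  dr <- hmhn:::dff_backward(ref, dy)
  df <- hmhn:::dff_backward(fst, dy)
  expect_lt(rel_diff(df, dr), 1e-3)
  # parameter gradients of FT1's first convolution agree
  gref <- hmhn:::seq_layers(ref$ft1)[[1]]$gw
  gfst <- hmhn:::dff_grads(fst)[[1]]$dw
  expect_lt(rel_diff(gfst, gref), 1e-3)
  expect_equal(hmhn:::dff_n_params(fst), hmhn:::dff_n_params(ref))
})
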