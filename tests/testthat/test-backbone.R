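# ResNet-18 feature extractor: shapes, parameter count, determinism and
# agreement with the R reference implementation.
#
# The equivalence check runs at 64x64 with batch 4 rather than at a tinier
# size: with smaller batches the deepest batch-norm layers normalise over
# almost no values and the network becomes so ill-conditioned that even
# two runs of one implementation drift apart (see the methods vignette).

test_that("a 224 input yields a 512-channel 7x7 map", {
  set.seed(1)
  bb <- hmhn:::fast_backbone(3L)
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  y <- hmhn:::backbone_forward(bb, x, train = FALSE)
  expect_identical(dim(y), c(7L, 7L, 512L, 1L))
})

test_that("backbone has exactly 11,176,512 parameters", {
  set.seed(1)
  expect_equal(hmhn:::backbone_n_params(hmhn:::fast_backbone(3L)),
               11176512)
  set.seed(1)
  expect_equal(hmhn:::backbone_n_params(hmhn:::resnet18_backbone(3L)),
               11176512)
})

test_that("eval-mode forward is bit-deterministic", {
  set.seed(2)
  bb <- hmhn:::fast_backbone(3L)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y1 <- hmhn:::backbone_forward(bb, x, train = FALSE)
  y2 <- hmhn:::backbone_forward(bb, x, train = FALSE)
  expect_identical(y1, y2)
})

test_that("fast backbone matches the R reference", {
  set.seed(21)
  ref <- hmhn:::resnet18_backbone(3L)
  set.seed(21)
  fst <- hmhn:::fast_backbone(3L)
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  yr <- hmhn:::backbone_forward(ref, x, train = TRUE)
  yf <- hmhn:::backbone_forward(fst, x, train = TRUE)
  expect_identical(dim(yf), dim(yr))
  expect_lt(rel_diff(yf, yr), 1e-3)
  dy <- array(rnorm(length(yr), sd = 0.1), dim(yr))
  dxr <- hmhn:::backbone_backward(ref, dy, need_dx = TRUE)
  dxf <- hmhn:::backbone_backward(fst, dy, need_dx = TRUE)
  # the stem convolution's weight gradient has accumulated the whole
  # depth of float round-off; require near-perfect alignment, not bits
  gr <- hmhn:::backbone_layers(ref)[[1]]$gw
  gf <- hmhn:::fb_grads(fst)[[1]]$dw
  expect_gt(cor(as.vector(gf), as.vector(gr)), 0.999)
  expect_gt(cor(as.vector(dxf), as.vector(dxr)), 0.999)
})
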