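# Grid partition, LGFE, scaled dot-product grid attention, squeeze and
# image re-weighting.

test_that("partition with a 1x1 grid is the identity", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  gs <- partition_grid(img, grid_spec(1, 1, 8, 8))
  expect_identical(dim(gs$grids), c(8L, 8L, 3L, 1L))
  expect_equal(gs$grids[, , , 1], img)
})

test_that("2x2 partition of an exactly divisible image", {
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  gs <- partition_grid(img, grid_spec(2, 2, 6, 6))
  expect_identical(dim(gs$grids), c(3L, 3L, 3L, 4L))
  # row-major order: grid 2 is the top-right block
  expect_equal(gs$grids[, , , 2], img[1:3, 4:6, ])
})

test_that("3x3 grid over 224 pads to 225 and yields 75x75 patches", {
  spec <- grid_spec(3, 3, 224, 224)
  expect_identical(spec$H_pad, 225L)
  expect_identical(spec$W_pad, 225L)
  expect_identical(spec$ph, 75L)
  expect_identical(spec$pw, 75L)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  gs <- partition_grid(img, spec)
  expect_identical(dim(gs$grids), c(75L, 75L, 3L, 9L))
  # reflect padding mirrors the interior row next to the edge
  expect_equal(gs$grids[75, 1:74, , 7], img[223, 1:74, ])
})

test_that("ungrid(partition(x)) reproduces x exactly for random shapes", {
  set.seed(7)
  for (i in 1:50) {
    H <- sample(6:30, 1); W <- sample(6:30, 1)
    h <- sample(1:3, 1); w <- sample(1:3, 1)
    pol <- sample(c("reflect", "zero"), 1)
    img <- array(runif(H * W * 3), c(H, W, 3))
    spec <- grid_spec(h, w, H, W, pad_policy = pol)
    back <- ungrid(partition_grid(img, spec), crop = TRUE)
    expect_identical(back, img)
  }
})

test_that("partition rejects bad inputs", {
  expect_error(grid_spec(0, 1, 8, 8), "grid counts")
  expect_error(partition_grid(matrix(0, 3, 3), grid_spec(1, 1, 3, 3)),
               "3-D")
  expect_error(partition_grid(array(0, c(4, 4, 3)), grid_spec(2, 2, 6, 6)),
               "spec expects")
})

test_that("attention rows are stochastic and in (0,1)", {
  set.seed(1)
  spec <- grid_spec(2, 2, 8, 8)
  feats <- array(rnorm(4 * 4 * 3 * 4), c(4, 4, 3, 4))
  att <- grid_attention(feats, spec)
  sums <- apply(att, c(1, 3, 4), sum)
  expect_true(max(abs(sums - 1)) < 1e-6)
  expect_true(all(att > 0 & att < 1))
})

test_that("constant features give uniform attention rows", {
  spec <- grid_spec(2, 2, 8, 8)
  feats <- array(0.7, c(4, 4, 1, 1))
  att <- grid_attention(feats, spec)
  expect_equal(as.vector(att), rep(1 / 4, 16))
})

test_that("2x2 identity patch matches the closed-form softmax", {
  spec <- grid_spec(1, 1, 2, 2)      # d_k = pw = 2
  feats <- array(diag(2), c(2, 2, 1, 1))
  att <- grid_attention(feats, spec)
  p <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(att[1, , 1, 1], c(p, 1 - p), tolerance = 1e-10)
  expect_equal(att[2, , 1, 1], c(1 - p, p), tolerance = 1e-10)
})

test_that("squeeze_expand averages each attention matrix to one scalar", {
  spec <- grid_spec(1, 1, 2, 2)
  att <- array(matrix(c(1, 3, 2, 4), 2), c(2, 2, 1, 1))
  sq <- squeeze_expand(att, spec)
  expect_equal(sq$scalars[1, 1], 2.5)
  expect_equal(sq$map[, , 1, 1], matrix(2.5, 2, 2))
  expect_identical(dim(sq$map), c(spec$ph, spec$pw, 1L, 1L))
})

test_that("ungrid_and_weight obeys identity and annihilation", {
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  spec <- grid_spec(2, 2, 6, 6)
  ones <- array(1, c(3, 3, 3, 4))
  expect_equal(ungrid_and_weight(ones, img, spec), img)
  expect_equal(ungrid_and_weight(ones * 0, img, spec), img * 0)
  # distinct per-grid scalars scale each block
  w <- array(0, c(3, 3, 3, 4))
  for (g in 1:4) w[, , , g] <- g
  out <- ungrid_and_weight(w, img, spec)
  expect_equal(out[1:3, 1:3, ], img[1:3, 1:3, ] * 1)
  expect_equal(out[1:3, 4:6, ], img[1:3, 4:6, ] * 2)
  expect_equal(out[4:6, 1:3, ], img[4:6, 1:3, ] * 3)
  expect_equal(out[4:6, 4:6, ], img[4:6, 4:6, ] * 4)
})

test_that("channel permutation permutes grid weights identically", {
  set.seed(3)
  spec <- grid_spec(2, 2, 8, 8, C = 3)
  feats <- array(rnorm(4 * 4 * 3 * 4), c(4, 4, 3, 4))
  perm <- c(3, 1, 2)
  s1 <- squeeze_expand(grid_attention(feats, spec), spec)$scalars
  s2 <- squeeze_expand(grid_attention(feats[, , perm, , drop = FALSE],
                                      spec), spec)$scalars
  expect_equal(s2, s1[perm, ])
})

test_that("LGFE maps zero to zero in eval mode with identity-like stats", {
  set.seed(2)
  lgfe <- hmhn:::make_lgfe(3L, 4L)
  for (l in hmhn:::seq_layers(lgfe)) {
    if (!is.null(l$b)) l$b <- numeric(length(l$b))
  }
  z <- array(0, c(5, 5, 3, 2))
  out <- hmhn:::seq_forward(lgfe, z, train = FALSE)
  expect_equal(max(abs(out)), 0)
})

test_that("GWA output keeps the image shape and trains its LGFE", {
  set.seed(4)
  mod <- hmhn:::gwa_module(grid_spec(3, 3, 20, 20), k_e = 4L)
  x <- array(runif(20 * 20 * 3 * 2), c(20, 20, 3, 2))
  y <- hmhn:::gwa_forward(mod, x, train = TRUE)
  expect_identical(dim(y), dim(x))
  hmhn:::gwa_backward(mod, array(1, dim(y)))
  g <- hmhn:::seq_layers(mod$lgfe)[[1]]$gw
  expect_gt(max(abs(g)), 0)
})
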