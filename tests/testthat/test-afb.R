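# Fusion, partition loss and the joint objective.

test_that("fuse_heads is the element-wise mean", {
  a <- array(1, c(2, 2, 1, 1)); b <- array(3, c(2, 2, 1, 1))
  expect_equal(fuse_heads(list(a)), a)
  expect_equal(fuse_heads(list(a, a)), a)
  expect_equal(fuse_heads(list(a, b)), array(2, c(2, 2, 1, 1)))
  expect_error(fuse_heads(list()), "at least one")
  expect_error(fuse_heads(list(a, array(1, c(3, 2, 1, 1)))), "shape")
})

test_that("partition loss closed forms hold", {
  # N=1, C=1, k=2, pooled values {0, 2}: population variance 1
  l <- partition_loss(list(matrix(0, 1, 1), matrix(2, 1, 1)), eps = 0)
  expect_equal(as.numeric(l), log(3), tolerance = 1e-12)
  # identical heads hit the eps floor: log(1 + 4e6) per term
  li <- partition_loss(rep(list(matrix(5, 1, 1)), 4), eps = 1e-6)
  expect_equal(as.numeric(li), log(1 + 4e6), tolerance = 1e-9)
  # huge spread drives the loss toward zero
  lh <- partition_loss(list(matrix(0, 1, 1), matrix(2e8, 1, 1)))
  expect_lt(as.numeric(lh), 1e-9)
  # k = 1 is defined as zero
  expect_equal(as.numeric(partition_loss(list(matrix(1, 1, 1)))), 0)
})

test_that("partition loss is strictly decreasing in every variance", {
  k <- 3
  sig <- seq(0.01, 10, length.out = 40)
  vals <- log(1 + k / (sig + 1e-6))
  expect_true(all(diff(vals) < 0))
  # and via the API: scaling the head spread up lowers the loss
  h1 <- list(matrix(-1, 2, 3), matrix(0, 2, 3), matrix(1, 2, 3))
  h2 <- lapply(h1, function(m) m * 3)
  expect_lt(as.numeric(partition_loss(h2)),
            as.numeric(partition_loss(h1)))
})

test_that("partition loss rejects non-finite heads", {
  expect_error(partition_loss(list(matrix(NaN, 1, 1), matrix(1, 1, 1))),
               "non-finite")
})

test_that("total loss is additive to machine precision", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    pred <- rnorm(n); truth <- rnorm(n)
    heads <- lapply(1:4, function(j) matrix(rnorm(n * 5), n, 5))
    lb <- total_loss(pred, truth, heads)
    expect_identical(lb$l_sum, lb$l_att + lb$l_mse)
    expect_gte(lb$l_att, 0)
    expect_gte(lb$l_mse, 0)
  }
})

test_that("total loss worked example: L_mse 4 plus L_att ln 3", {
  lb <- total_loss(1, 3, list(matrix(0, 1, 1), matrix(2, 1, 1)), eps = 0)
  expect_equal(lb$l_mse, 4)
  expect_equal(lb$l_att, log(3), tolerance = 1e-12)
  expect_equal(lb$l_sum, 4 + log(3), tolerance = 1e-12)
  expect_error(total_loss(c(1, 2), 3, NULL), "equal length")
})

test_that("partition loss gradient matches finite differences", {
  set.seed(2)
  pooled <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  eps <- 1e-6
  g <- hmhn:::partition_loss_grad(pooled, eps)
  f <- function(p) {
    heads <- lapply(seq_len(dim(p)[3]), function(i) p[, , i])
    as.numeric(partition_loss(heads, eps))
  }
  h <- 1e-5
  for (idx in list(c(1, 1, 1), c(2, 3, 4), c(1, 2, 3))) {
    pp <- pooled; pp[idx[1], idx[2], idx[3]] <- pp[idx[1], idx[2], idx[3]] + h
    pm <- pooled; pm[idx[1], idx[2], idx[3]] <- pm[idx[1], idx[2], idx[3]] - h
    fd <- (f(pp) - f(pm)) / (2 * h)
    expect_equal(g[idx[1], idx[2], idx[3]], fd, tolerance = 1e-4)
  }
})

test_that("regression head: one scalar per sample, eval deterministic", {
  set.seed(3)
  afb <- hmhn:::afb_module(8L, dropout = 0.2)
  x <- array(rnorm(3 * 3 * 8 * 5), c(3, 3, 8, 5))
  p1 <- hmhn:::afb_forward(afb, x, train = FALSE)
  p2 <- hmhn:::afb_forward(afb, x, train = FALSE)
  expect_length(p1, 5)
  expect_identical(p1, p2)
})
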