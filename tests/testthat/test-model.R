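# Full model assembly: ablation parity, determinism and configuration
# validation.

test_that("all ablation variants construct, step and backpropagate", {
  toggles <- list(
    A = c(gwa = FALSE, dff = FALSE, mab = FALSE),
    B = c(gwa = TRUE,  dff = FALSE, mab = FALSE),
    C = c(gwa = TRUE,  dff = TRUE,  mab = FALSE),
    D = c(gwa = FALSE, dff = FALSE, mab = TRUE),
    E = c(gwa = TRUE,  dff = TRUE,  mab = TRUE))
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- c(10, 40)
  for (nm in names(toggles)) {
    tg <- toggles[[nm]]
    cfg <- hmhn_config(image_size = 64L, seed = 3L,
                       use_gwa = tg[["gwa"]], use_dff = tg[["dff"]],
                       use_mab = tg[["mab"]])
    m <- hmhn_model(cfg)
    hmhn:::zero_grads(m)
    fwd <- hmhn:::model_forward(m, x, train = TRUE)
    expect_length(fwd$pred, 2)
    expect_true(all(is.finite(fwd$pred)), info = nm)
    hmhn:::model_backward(m, 2 * (fwd$pred - y) / 2)
    hmhn:::optimizer_step(m, 1e-3, 1L)
    fwd2 <- hmhn:::model_forward(m, x, train = TRUE)
    expect_false(identical(fwd2$pred, fwd$pred), info = nm)
  }
})

test_that("seeded construction and eval forward are deterministic", {
  cfg <- hmhn_config(image_size = 64L, seed = 9L)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p1 <- hmhn:::model_predict(hmhn_model(cfg), x)
  p2 <- hmhn:::model_predict(hmhn_model(cfg), x)
  expect_identical(p1, p2)
})

test_that("kernel configurations build and count consistently", {
  for (kc in c("k313", "standard", "k31")) {
    set.seed(1)
    cfg <- hmhn_config(kernel_config = kc, seed = 1L)
    expect_gt(count_parameters(hmhn_model(cfg)), 11176512)
  }
})

test_that("configuration validation", {
  expect_error(hmhn_config(lr = 0), "positive")
  expect_error(hmhn_config(batch_size = 0), ">= 1")
  expect_error(hmhn_config(fusion = "max"))
  expect_error(head_config(kernel_config = "k9"))
  expect_error(head_config(num_heads = 0), ">= 1")
})

test_that("print methods summarise model and config", {
  m <- hmhn_model(hmhn_config(image_size = 64L, seed = 1L))
  expect_output(print(m), "GWA -> DFF -> ResNet-18")
  expect_output(print(m), "19,718,974")
})
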