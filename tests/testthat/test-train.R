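# Desk-scale training behaviour. All tests share the two memoised seeded
# runs from helper-runs.R (identical data and seed; partition loss on vs
# off): 112-px images, 200 train / 50 dev / 50 test, 5 epochs, batch 16.

test_that("the smoke run completes with a well-formed history", {
  fit <- desk_run(TRUE)
  h <- tidy(fit)
  expect_identical(h$epoch, 1:5)
  expect_true(all(is.finite(h$l_sum)))
  expect_true(all(is.finite(h$dev_mae)))
  expect_equal(h$l_sum, h$l_mse + h$l_att, tolerance = 1e-12)
  expect_false(is.na(fit$best_epoch))
  g <- glance(fit)
  expect_identical(g$epochs, 5L)
  expect_equal(g$n_parameters, 19718974)
})

test_that("epoch-5 train loss is at most 0.8 x epoch-1 loss", {
  h <- tidy(desk_run(TRUE))
  expect_lte(h$l_sum[5], 0.8 * h$l_sum[1])
})

test_that("the same seed reproduces the epoch-1 loss exactly", {
  dd <- desk_data()
  cfg1 <- desk_config(TRUE); cfg1$epochs <- 1L
  refit <- hmhn_train(dd$manifest, cfg1, base_dir = dd$dir,
                      verbose = FALSE)
  expect_identical(tidy(refit)$l_sum[1], tidy(desk_run(TRUE))$l_sum[1])
})

test_that("test MAE beats the mean-predictor baseline", {
  fit <- desk_run(TRUE)
  dd <- desk_data()
  te <- desk_images("test")
  pred <- predict(fit, te$x)
  y_train <- dd$manifest$bdi2_score[dd$manifest$split == "train"]
  baseline <- bdi_mae(te$y, rep(mean(y_train), length(te$y)))
  expect_lt(bdi_mae(te$y, pred$.pred), baseline)
})

test_that("the partition loss decorrelates the attention heads", {
  te <- desk_images("test")
  x <- te$x[, , , 1:32, drop = FALSE]
  cos_on <- mean_head_cosine(desk_run(TRUE)$model, x)
  cos_off <- mean_head_cosine(desk_run(FALSE)$model, x)
  expect_lt(cos_on, cos_off)
})

test_that("prediction records obey their contract", {
  fit <- desk_run(TRUE)
  dd <- desk_data()
  rows <- dd$manifest[dd$manifest$split == "test", ][1:5, ]
  p1 <- predict(fit, rows, base_dir = dd$dir)
  p2 <- predict(fit, rows, base_dir = dd$dir)
  expect_identical(nrow(p1), 5L)
  expect_identical(p1$.pred, p2$.pred)
  expect_true(all(p1$.pred >= 0 & p1$.pred <= 63))
  expect_s3_class(p1$.pred_band, "factor")
})

test_that("evaluation and checkpointing work on the fitted model", {
  fit <- desk_run(TRUE)
  dd <- desk_data()
  ev <- hmhn_evaluate(fit, dd$manifest, base_dir = dd$dir)
  expect_true(is.finite(ev$metrics$mae))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, ck)
  m2 <- load_checkpoint(ck)
  te <- desk_images("test")
  x <- te$x[, , , 1:4, drop = FALSE]
  expect_identical(hmhn:::model_predict(m2, x),
                   hmhn:::model_predict(fit$model, x))
})

test_that("training plots and attention maps build", {
  fit <- desk_run(TRUE)
  dd <- desk_data()
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  am <- attention_maps(fit, file.path(dd$dir, dd$manifest$path[1]))
  expect_identical(sort(unique(am$head)), 1:4)
  # trained gates can saturate to 1.0 in float32, so closed bounds
  expect_true(all(am$gate >= 0 & am$gate <= 1))
  expect_s3_class(ggplot2::autoplot(am), "ggplot")
})

test_that("non-finite losses abort with a diagnostic", {
  man <- tibble::tibble(path = "a.png", bdi2_score = 10, split = "train")
  expect_error(hmhn_train(man[0, ], desk_config()), "no train rows")
})
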