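# MAE/RMSE and the BDI-II severity-band mapping.

test_that("all 64 integer scores map to their severity band", {
  expected <- c(rep("None or minimal", 14),  # 0-13
                rep("Mild", 6),              # 14-19
                rep("Moderate", 9),          # 20-28
                rep("Severe", 35))           # 29-63
  got <- severity_from_score(0:63)
  expect_identical(as.character(got), expected)
})

test_that("the example scores 3, 16 and 44 map correctly", {
  expect_identical(as.character(severity_from_score(c(3, 16, 44))),
                   c("None or minimal", "Mild", "Severe"))
})

test_that("band boundaries, clamping and rounding behave", {
  expect_identical(as.character(severity_from_score(13)), "None or minimal")
  expect_identical(as.character(severity_from_score(14)), "Mild")
  expect_identical(as.character(severity_from_score(13.4)),
                   "None or minimal")
  expect_identical(as.character(severity_from_score(13.5)), "Mild")
  expect_identical(as.character(severity_from_score(-5)), "None or minimal")
  expect_identical(as.character(severity_from_score(99)), "Severe")
  expect_error(severity_from_score(NaN), "finite")
  expect_error(severity_from_score("a"), "numeric")
})

test_that("the band table partitions 0..63", {
  b <- severity_bands()
  expect_identical(b$lower, c(0L, 14L, 20L, 29L))
  expect_identical(b$upper, c(13L, 19L, 28L, 63L))
  expect_identical(b$lower[-1], b$upper[-4] + 1L)
})

test_that("MAE and RMSE closed forms", {
  truth <- c(10, 20, 30); est <- c(12, 18, 33)
  expect_equal(bdi_mae(truth, est), 7 / 3, tolerance = 1e-12)
  expect_equal(bdi_rmse(truth, est), sqrt(17 / 3), tolerance = 1e-12)
  expect_equal(bdi_mae(5, 5), 0)
  expect_error(bdi_mae(1:3, 1:2), "lengths differ")
  expect_error(bdi_rmse(numeric(0), numeric(0)), "at least one")
})

test_that("RMSE >= MAE on random vectors, equality for constant error", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    truth <- runif(n, 0, 63); est <- runif(n, 0, 63)
    expect_gte(bdi_rmse(truth, est) - bdi_mae(truth, est), -1e-12)
  }
  expect_equal(bdi_rmse(1:5, 1:5 + 2), bdi_mae(1:5, 1:5 + 2))
})

test_that("evaluate_scores returns tidy metrics and confusion", {
  ev <- evaluate_scores(c(3, 16, 44), c(5, 21, 40))
  expect_identical(ev$metrics$n, 3L)
  expect_equal(ev$metrics$mae, mean(c(2, 5, 4)))
  expect_s3_class(ev$confusion, "tbl_df")
  expect_identical(sum(ev$confusion$n), 3L)
  row <- ev$confusion[ev$confusion$truth_band == "Mild", ]
  expect_identical(as.character(row$estimate_band), "Moderate")
})
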