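# Synthetic face generator: determinism, geometry laws, monotone signal
# and on-disk datasets.

test_that("generate_sample is bit-reproducible and seed-sensitive", {
  a <- generate_sample(7, 44)
  b <- generate_sample(7, 44)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, generate_sample(8, 44)$image))
  expect_false(identical(a$image, generate_sample(7, 10)$image))
})

test_that("images satisfy the shape and value contract", {
  s <- generate_sample(1, 30)
  expect_identical(dim(s$image), c(224L, 224L, 3L))
  expect_true(all(s$image >= 0 & s$image <= 1))
  small <- generate_sample(1, 30, synth_config(size = 96L))
  expect_identical(dim(small$image), c(96L, 96L, 3L))
})

test_that("scores outside [0, 63] are rejected", {
  expect_error(generate_sample(1, -0.5), "\\[0, 63\\]")
  expect_error(generate_sample(1, 63.1), "\\[0, 63\\]")
  expect_error(face_params(Inf), "finite")
})

test_that("geometry parameters are affine and strictly monotone in score", {
  cfg <- synth_config()
  p0 <- face_params(0, cfg); p1 <- face_params(31.5, cfg)
  p2 <- face_params(63, cfg)
  expect_equal(p0$curvature - p2$curvature, cfg$alpha)
  expect_equal(p1$curvature, (p0$curvature + p2$curvature) / 2)
  expect_true(p0$curvature > p1$curvature && p1$curvature > p2$curvature)
  expect_true(p0$openness > p2$openness)
  expect_true(p0$brow_angle < p2$brow_angle)
  expect_equal(p2$droop - p0$droop, cfg$delta)
})

test_that("mouth-region intensity is monotone in score (|rho| > 0.95)", {
  ms <- mouth_signal(seq(0, 63, length.out = 64))
  rho <- cor(ms$score, ms$intensity, method = "spearman")
  expect_gt(abs(rho), 0.95)
})

test_that("the default score sampler matches its Beta moments", {
  set.seed(99)
  s <- score_sampler_beta(4000)
  expect_true(all(s >= 0 & s <= 63))
  expect_equal(mean(s), 63 * 1.2 / 3.7, tolerance = 0.05)
  # right-skewed: mean above median
  expect_gt(mean(s), stats::median(s))
})

test_that("generate_dataset writes images and a valid manifest", {
  dir <- file.path(tempdir(), "hmhn-synth-test")
  man <- generate_dataset(24, 5, dir,
                          splits = c(train = 0.5, dev = 0.25, test = 0.25),
                          config = synth_config(size = 64L))
  expect_identical(nrow(man), 24L)
  expect_named(man, c("path", "bdi2_score", "split"))
  expect_identical(as.integer(table(man$split)[c("train", "dev", "test")]),
                   c(12L, 6L, 6L))
  expect_true(all(file.exists(file.path(dir, man$path))))
  expect_true(all(man$bdi2_score >= 0 & man$bdi2_score <= 63))
  # splits are disjoint over distinct files
  expect_identical(anyDuplicated(man$path), 0L)
  # the manifest round-trips through the loader
  m2 <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m2$bdi2_score, man$bdi2_score, tolerance = 1e-9)
  # regeneration with the same seed is identical on disk
  dir2 <- file.path(tempdir(), "hmhn-synth-test2")
  man2 <- generate_dataset(24, 5, dir2,
                           splits = c(train = 0.5, dev = 0.25,
                                      test = 0.25),
                           config = synth_config(size = 64L))
  expect_equal(man2$bdi2_score, man$bdi2_score)
  f1 <- readBin(file.path(dir, man$path[1]), "raw", 1e6)
  f2 <- readBin(file.path(dir2, man2$path[1]), "raw", 1e6)
  expect_identical(f1, f2)
})

test_that("generate_dataset validates its inputs", {
  expect_error(generate_dataset(0, 1, tempdir()), ">= 1")
  expect_error(generate_dataset(5, 1, tempdir(),
                                splits = c(a = 1, b = 1, c = 1)),
               "train")
})
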