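test_that("dataset specs enforce grade-monotone lesion burden", {
  spec <- small_dataset_spec()
  totals <- Reduce(`+`, lapply(spec$grade_params, function(a) a$mean))
  expect_equal(totals[1], 0)
  expect_true(all(diff(totals) > 0))
  bad <- default_params <- fundusgrade:::default_grade_params()
  bad$microaneurysm$mean <- rev(bad$microaneurysm$mean)
  expect_error(synthetic_dataset_spec(grade_params = bad), "increasing")
  expect_error(synthetic_dataset_spec(class_counts = c(10, 0, 5, 2, 2)), "positive")
})

test_that("image generation is deterministic, bounded and grade-sensitive", {
  spec <- small_dataset_spec()
  img1 <- generate_fundus_image(2, spec, stream_seed = 99)
  img2 <- generate_fundus_image(2, spec, stream_seed = 99)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1) && all(is.finite(img1)))
  expect_error(generate_fundus_image(5, spec), "grade")

  # lesion pixel statistics rise with grade: bright exudate and dark lesion
  # fractions at grade 4 exceed grade 1 on average
  frac <- function(grade, seeds) {
    vapply(seeds, function(s) {
      im <- generate_fundus_image(grade, spec, s)
      lum <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
      mean(lum > 0.75) + mean(lum < 0.12)
    }, numeric(1))
  }
  expect_gt(mean(frac(4, 1:60)), mean(frac(1, 1:60)))
})

test_that("dataset generation honors class counts and the long-tailed default", {
  spec <- synthetic_dataset_spec(class_counts = c(100L, 10L, 21L, 3L, 3L), seed = 5)
  ds <- generate_dataset(spec)
  expect_length(ds$labels, 137)
  expect_equal(as.integer(table(ds$labels)), c(100L, 10L, 21L, 3L, 3L))
  ds2 <- generate_dataset(spec)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$labels, ds2$labels)

  counts <- synthetic_dataset_spec()$class_counts
  expect_gte(max(counts) / min(counts), 10)
})

test_that("train/test splits are stratified, seeded partitions", {
  spec <- synthetic_dataset_spec(class_counts = rep(20L, 5), seed = 2)
  ds <- generate_dataset(spec)
  sp <- train_test_split(ds, 0.2, seed = 3)
  expect_length(sp$test$labels, 20)
  expect_equal(as.integer(table(sp$test$labels)), rep(4L, 5))
  expect_equal(as.integer(table(sp$train$labels)), rep(16L, 5))
  sp2 <- train_test_split(ds, 0.2, seed = 3)
  expect_identical(sp$test$labels, sp2$test$labels)
  expect_identical(sp$test$images, sp2$test$images)
  # partition: together they recover the dataset exactly
  expect_equal(length(sp$train$labels) + length(sp$test$labels), length(ds$labels))
  key <- function(d) vapply(d$images, function(i) paste(head(i, 12), collapse = ","), "")
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_error(train_test_split(ds, 1.2, seed = 1), "between 0 and 1")

  lone <- generate_dataset(synthetic_dataset_spec(class_counts = c(5L, 1L, 2L, 2L, 2L), seed = 1))
  expect_warning(train_test_split(lone, 0.3, seed = 1), "single image")
})

test_that("grade 0 and grade 4 are separable by nearest-centroid lesion statistics", {
  spec <- small_dataset_spec()
  feats <- function(grade, seeds) {
    t(vapply(seeds, function(s) {
      im <- generate_fundus_image(grade, spec, derive_seed <- s)
      lum <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
      c(dark = mean(lum < 0.12), bright = mean(lum > 0.75))
    }, numeric(2)))
  }
  f0 <- feats(0, 1:100); f4 <- feats(4, 101:200)
  c0 <- colMeans(f0[1:50, ]); c4 <- colMeans(f4[1:50, ])
  held <- rbind(f0[51:100, ], f4[51:100, ])
  truth <- rep(c(0, 4), each = 50)
  pred <- ifelse(rowSums(sweep(held, 2, c0)^2) < rowSums(sweep(held, 2, c4)^2), 0, 4)
  expect_gte(mean(pred == truth), 0.9)
})

test_that("datasets round-trip through PNG + CSV on disk", {
  spec <- synthetic_dataset_spec(class_counts = c(4L, 2L, 2L, 2L, 2L), seed = 9)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  back <- read_image_dataset(dir)
  expect_identical(back$labels, ds$labels)
  # PNG is 8-bit: pixel values survive within quantization error
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 1 / 255)
})
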