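test_that("sketch projections are in-range, deterministic and seed-sensitive", {
  p <- make_sketch_projection(4, 4, 16, seed = 0)
  expect_length(p$hash1, 4); expect_length(p$hash2, 4)
  expect_true(all(p$hash1 >= 1 & p$hash1 <= 16))
  expect_true(all(p$sign1 %in% c(-1, 1)) && all(p$sign2 %in% c(-1, 1)))
  expect_identical(p, make_sketch_projection(4, 4, 16, seed = 0))

  tables <- vapply(1:100, function(s) {
    q <- make_sketch_projection(8, 8, 64, seed = s)
    paste(c(q$hash1, q$hash2, q$sign1, q$sign2), collapse = ",")
  }, character(1))
  expect_gte(length(unique(tables)), 99)

  expect_error(make_sketch_projection(4, 4, 0, seed = 1), "d must be")
})

test_that("count sketch evaluates and is linear", {
  expect_equal(count_sketch(numeric(3), c(1, 2, 3), c(1, 1, 1), 8), numeric(8))
  v <- count_sketch(2, hash_table = 4, sign_table = -1, d = 8)
  expect_equal(v, c(0, 0, 0, -2, 0, 0, 0, 0))
  set.seed(2)
  h <- sample.int(16, 10, replace = TRUE); s <- sample(c(-1, 1), 10, replace = TRUE)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(count_sketch(a + b, h, s, 16),
               count_sketch(a, h, s, 16) + count_sketch(b, h, s, 16))
  expect_error(count_sketch(1:3, c(1, 2), c(1, 1), 4), "length")
})

test_that("tensor sketch matches a direct circular-convolution oracle", {
  proj <- make_sketch_projection(6, 6, 32, seed = 3)
  expect_equal(tensor_sketch(numeric(6), rnorm(6), proj), numeric(32))

  circ_conv <- function(a, b) {
    d <- length(a)
    vapply(seq_len(d), function(m) {
      sum(a * b[((m - seq_len(d)) %% d) + 1])
    }, numeric(1))
  }
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(6); y <- rnorm(6)
    sx <- count_sketch(x, proj$hash1, proj$sign1, 32)
    sy <- count_sketch(y, proj$hash2, proj$sign2, 32)
    expect_equal(tensor_sketch(x, y, proj), circ_conv(sx, sy), tolerance = 1e-10)
  }
})

test_that("sketch self inner products are unbiased for the squared norm", {
  set.seed(9)
  x <- rnorm(16); x <- x / sqrt(sum(x^2))
  vals <- vapply(1:500, function(s) {
    proj <- make_sketch_projection(16, 16, 64, seed = s)
    ts <- tensor_sketch(x, x, proj)
    sum(ts * ts)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.05)   # <x,x>^2 = 1
})

test_that("compact pooling reduces to the tensor sketch and is additive over positions", {
  proj <- make_sketch_projection(3, 3, 64, seed = 4)
  z <- feature_map(array(0, c(2, 2, 3)))
  expect_equal(compact_bilinear_pool(z, z, proj), numeric(64))

  set.seed(5)
  v <- rnorm(3)
  one <- feature_map(array(v, c(1, 1, 3)))
  expect_equal(compact_bilinear_pool(one, one, proj), tensor_sketch(v, v, proj))

  # splitting the spatial positions splits the sum
  vals <- matrix(rnorm(6), 2, 3)
  both <- feature_map(array(vals, c(2, 1, 3)))
  p1 <- feature_map(array(vals[1, ], c(1, 1, 3)))
  p2 <- feature_map(array(vals[2, ], c(1, 1, 3)))
  expect_equal(compact_bilinear_pool(both, both, proj),
               compact_bilinear_pool(p1, p1, proj) + compact_bilinear_pool(p2, p2, proj),
               tolerance = 1e-10)

  expect_error(compact_bilinear_pool(rand_fm(2, 2, 4), rand_fm(2, 2, 4), proj), "channel")
})

test_that("compact descriptor inner products track the exact bilinear oracle", {
  fx <- rand_fm(4, 4, 8, seed = 21)
  fy <- rand_fm(4, 4, 8, seed = 22)
  oracle <- bilinear_inner_product(fx, fx, fy, fy)
  approx <- vapply(1:50, function(s) {
    proj <- make_sketch_projection(8, 8, 1024, seed = s)
    sum(compact_bilinear_pool(fx, fx, proj) * compact_bilinear_pool(fy, fy, proj))
  }, numeric(1))
  med_rel <- stats::median(abs(approx - oracle) / abs(oracle))
  expect_lt(med_rel, 0.20)
})

test_that("signed-sqrt normalization behaves at fixed points and degenerate input", {
  out <- normalize_descriptor(c(4, 0, -4))
  expect_equal(out, c(2, 0, -2) / sqrt(8))
  expect_equal(normalize_descriptor(c(0, 1, 0)), c(0, 1, 0))
  expect_equal(normalize_descriptor(numeric(5)), numeric(5))
  expect_error(normalize_descriptor(c(1, Inf)), "finite")
})

test_that("projection serialization round-trips through the seed record", {
  proj <- make_sketch_projection(8, 12, 256, seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_projection(proj, path)
  expect_identical(read_projection(path), proj)
})
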