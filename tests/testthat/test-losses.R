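cfg <- loss_config()

test_that("cross entropy matches closed forms and mean reduction", {
  perfect <- labeled_batch(matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE), c(0, 1))
  expect_equal(cross_entropy(perfect, cfg), 0, tolerance = 1e-6)
  unif <- labeled_batch(matrix(0.2, 3, 5), c(0, 2, 4))
  expect_equal(cross_entropy(unif, cfg), log(5))
  # two samples average their per-sample losses
  b2 <- labeled_batch(matrix(c(0.5, 0.5, 0.8, 0.2), 2, byrow = TRUE), c(0, 0))
  expect_equal(cross_entropy(b2, cfg), (log(2) - log(0.8)) / 2)
})

test_that("complement entropy hits its closed forms and bounds", {
  b <- labeled_batch(c(0.5, 0.25, 0.25), 0)
  expect_equal(complement_entropy(b, cfg), log(2))
  degenerate <- labeled_batch(c(0.5, 0.5, 0), 0)
  expect_equal(complement_entropy(degenerate, cfg), 0)
  maxent <- labeled_batch(c(0.6, rep(0.1, 4)), 0)
  expect_equal(complement_entropy(maxent, cfg), log(4))
  expect_equal(balanced_complement_entropy(maxent, cfg), log(4) / 4)
  two_class <- labeled_batch(c(0.7, 0.3), 0)
  expect_equal(balanced_complement_entropy(two_class, cfg),
               complement_entropy(two_class, cfg))
  expect_error(complement_entropy(labeled_batch(matrix(1, 1, 1), 0), cfg), "2 classes")
})

test_that("complement entropy is bounded, maximal at uniform, permutation-invariant", {
  set.seed(10)
  violations <- sum(vapply(1:2000, function(i) {
    K <- sample(2:10, 1)
    b <- labeled_batch(random_simplex(K), sample(0:(K - 1), 1))
    val <- complement_entropy(b, cfg)
    val < 0 || val > log(K - 1) + 1e-12
  }, logical(1)))
  expect_identical(violations, 0L)
  # grid over the 2-simplex at K = 3: maximum iff non-target mass is even
  grid <- seq(0.01, 0.97, by = 0.02)
  best <- -Inf; best_split <- NA
  for (p2 in grid) for (p3 in grid) {
    if (p2 + p3 >= 0.995) next
    b <- labeled_batch(c(1 - p2 - p3, p2, p3), 0)
    v <- complement_entropy(b, cfg)
    if (v > best) { best <- v; best_split <- abs(p2 - p3) }
  }
  expect_equal(best, log(2), tolerance = 1e-3)
  expect_lt(best_split, 1e-9)

  # permuting the non-target classes changes nothing
  b1 <- labeled_batch(c(0.4, 0.3, 0.2, 0.1), 0)
  b2 <- labeled_batch(c(0.4, 0.1, 0.3, 0.2), 0)
  expect_equal(complement_entropy(b1, cfg), complement_entropy(b2, cfg))
})

test_that("cce and focal reduce to cross entropy at neutral settings", {
  set.seed(11)
  P <- t(replicate(6, random_simplex(5)))
  b <- labeled_batch(P, sample(0:4, 6, replace = TRUE))
  expect_identical(cce_loss(b, loss_config(gamma = 0)), cross_entropy(b, cfg))
  expect_equal(focal_loss(b, loss_config(focal_gamma = 0, focal_alpha = 1)),
               cross_entropy(b, cfg))
  single <- labeled_batch(c(0.5, 0.25, 0.25), 0)
  expect_equal(cce_loss(single, loss_config(gamma = -1)), log(2) - log(2) / 2)
  expect_equal(focal_loss(labeled_batch(c(0.5, 0.3, 0.2), 0),
                          loss_config(focal_gamma = 2, focal_alpha = 1)),
               0.25 * log(2))
  expect_equal(focal_loss(labeled_batch(c(1, 0, 0), 0), cfg), 0, tolerance = 1e-6)
})

test_that("analytic loss gradients agree with central finite differences", {
  set.seed(12)
  losses <- list(cross_entropy, complement_entropy, balanced_complement_entropy,
                 cce_loss, focal_loss)
  P <- t(replicate(4, random_simplex(5)))
  labels <- sample(0:4, 4, replace = TRUE)
  h <- 1e-6
  for (fn in losses) {
    g <- fn(labeled_batch(P, labels), cfg, grad = TRUE)$grad
    for (i in seq_len(4)) for (j in seq_len(5)) {
      bump <- function(s) {
        Q <- P; Q[i, j] <- Q[i, j] + s
        structure(list(probs = Q, labels = labels + 1L, N = 4L, K = 5L),
                  class = "labeled_batch")
      }
      num <- (fn(bump(h), cfg) - fn(bump(-h), cfg)) / (2 * h)
      expect_lt(abs(num - g[i, j]), 1e-5)
    }
  }
})

test_that("invalid batches and configs are rejected", {
  expect_error(labeled_batch(c(0.5, 0.6), 0), "sum to 1")
  expect_error(labeled_batch(c(0.5, 0.5), 2), "labels")
  expect_error(loss_config(epsilon = 0), "epsilon")
  expect_error(loss_config(focal_gamma = -1), "focal_gamma")
})
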