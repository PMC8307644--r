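test_that("convolution matches a direct sliding-window oracle", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  layer <- fundusgrade:::conv_layer(2L, 3L, kh = 3L, kw = 3L, stride = 2L, pad = 1L)
  out <- fundusgrade:::conv_forward(layer, x)$out
  # oracle: explicit loops over output positions and kernel offsets
  W <- array(layer$W, c(3, 3, 2, 3))
  xp <- array(0, c(8, 7, 2, 2)); xp[2:7, 2:6, , ] <- x
  for (n in 1:2) for (co in 1:3) for (i in seq_len(dim(out)[1])) for (j in seq_len(dim(out)[2])) {
    acc <- layer$b[co]
    for (dh in 1:3) for (dw in 1:3) for (ci in 1:2) {
      acc <- acc + xp[(i - 1) * 2 + dh, (j - 1) * 2 + dw, ci, n] * W[dh, dw, ci, co]
    }
    expect_equal(out[i, j, co, n], acc, tolerance = 1e-12)
  }
})

test_that("stream alignment pools to the coarser grid", {
  a <- rand_fm(8, 8, 3, seed = 1)
  b <- rand_fm(4, 4, 5, seed = 2)
  al <- align_streams(a, b)
  expect_identical(dim(al$a), c(4L, 4L, 3L))
  expect_identical(al$b, b)
  # 8x8 -> 4x4 is exact 2x2 block averaging
  expect_equal(al$a[1, 1, ], apply(a[1:2, 1:2, , drop = FALSE], 3, mean))
  expect_equal(al$a[3, 2, ], apply(a[5:6, 3:4, , drop = FALSE], 3, mean))

  same <- align_streams(a, rand_fm(8, 8, 2, seed = 3))
  expect_identical(same$a, a)

  # 7x7 -> 4x4 adaptive windows: compare to direct window means
  c7 <- rand_fm(7, 7, 2, seed = 4)
  al2 <- align_streams(c7, b)
  win <- fundusgrade:::adaptive_windows(7, 4)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(al2$a[i, j, ],
                 apply(c7[win[i, 1]:win[i, 2], win[j, 1]:win[j, 2], , drop = FALSE], 3, mean))
  }
})

test_that("model construction is deterministic and checks its contracts", {
  sp <- tiny_specs()
  m1 <- tiny_model(seed = 3)
  m2 <- tiny_model(seed = 3)
  expect_equal(m1, m2)
  expect_identical(m1$projection$input_dims, c(8L, 12L))
  expect_identical(ncol(m1$classifier$W), 5L)
  expect_error(build_model(sp$a, sp$b, d = 64, K = 1), "K must be")
  expect_error(backbone_spec("vgg"), "arg")
  expect_error(backbone_spec("resnet50", pretrained = TRUE), "pretrained")
})

test_that("large backbone families are constructible offline", {
  rn <- build_backbone(backbone_spec("resnet50"), seed = 1)
  dn <- build_backbone(backbone_spec("densenet121"), seed = 1)
  expect_identical(rn$out_channels, 2048L)
  expect_identical(dn$out_channels, 1024L)
  expect_gt(length(rn$layers), 10)
  m <- build_model(backbone_spec("resnet50"), backbone_spec("densenet121"),
                   d = 128, K = 5, seed = 1)
  expect_identical(m$input_size, c(224L, 224L))
  expect_identical(m$projection$input_dims, c(2048L, 1024L))
})

test_that("forward emits normalized, deterministic probability vectors", {
  m <- tiny_model(seed = 5)
  set.seed(6)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  p <- forward(m, x)
  expect_identical(dim(p), c(4L, 5L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_identical(forward(m, x), p)
  expect_error(forward(m, array(0, c(8, 8, 3, 1))), "expects")
})

test_that("homologous shared-stream features give symmetric bilinear descriptors", {
  sp <- backbone_spec("tiny", output_channels = 6L, depth = 2L)
  m <- build_model(sp, sp, d = 64, K = 5, seed = 2, input_size = c(16L, 16L),
                   homologous = TRUE)
  set.seed(7)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  fa <- fundusgrade:::backbone_forward(m$stream_a, x)$out
  fm <- feature_map(array(fa, dim(fa)[1:3]))
  w <- excitation(global_average_pool(fm), m$attention_a)
  att <- apply_attention(fm, w)
  B <- bilinear_pool(att, att)
  expect_equal(B, t(B))
})

test_that("loss gradients reach every trainable parameter", {
  m <- tiny_model(seed = 9, d = 32L)
  set.seed(10)
  x <- array(runif(16 * 16 * 3 * 6), c(16, 16, 3, 6))
  fwd <- fundusgrade:::model_forward(m, x, want_cache = TRUE)
  lg <- cce_loss(labeled_batch(fwd$probs, c(0, 1, 2, 3, 4, 0)), loss_config(), grad = TRUE)
  grads <- fundusgrade:::model_backward(m, fwd, lg$grad)
  for (pair in fundusgrade:::trainable_pairs(m)) {
    g <- fundusgrade:::path_get(grads, pair$g)
    expect_gt(sum(abs(g)), 0, label = paste(unlist(pair$m), collapse = "/"))
  }
})

test_that("analytic model gradients match finite differences", {
  # normalize off: the signed sqrt is non-smooth near zero descriptor entries
  m <- tiny_model(seed = 1, d = 32L, normalize = FALSE)
  set.seed(2)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  labels <- c(1L, 3L)
  lossfun <- function(model) {
    pr <- fundusgrade:::model_forward(model, x)$probs
    cce_loss(labeled_batch(pr, labels), loss_config())
  }
  fwd <- fundusgrade:::model_forward(m, x, want_cache = TRUE)
  lg <- cce_loss(labeled_batch(fwd$probs, labels), loss_config(), grad = TRUE)
  grads <- fundusgrade:::model_backward(m, fwd, lg$grad)
  paths <- list(
    list(m = c("classifier", "W"), g = c("classifier", "dW")),
    list(m = c("attention_a", "W1"), g = c("attention_a", "dW1")),
    list(m = c("attention_b", "W2"), g = c("attention_b", "dW2")),
    list(m = list("stream_a", "layers", 1L, "W"), g = list("stream_a", 1L, "dW")),
    list(m = list("stream_b", "layers", 5L, "W"), g = list("stream_b", 5L, "dW"))
  )
  h <- 1e-5
  for (pr in paths) {
    g <- fundusgrade:::path_get(grads, pr$g)
    p0 <- fundusgrade:::path_get(m, pr$m)
    set.seed(42)
    for (i in sample(length(p0), 3)) {
      up <- fundusgrade:::path_set(m, pr$m, replace(p0, i, p0[i] + h))
      dn <- fundusgrade:::path_set(m, pr$m, replace(p0, i, p0[i] - h))
      num <- (lossfun(up) - lossfun(dn)) / (2 * h)
      expect_lt(abs(num - g[i]), 1e-5)
    }
  }
})

test_that("checkpoints round-trip the model and its sidecar", {
  m <- tiny_model(seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  restored <- load_checkpoint(path)
  set.seed(5)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  expect_identical(forward(restored, x), forward(m, x))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(side$d, m$d)
  expect_identical(side$projection_seed, m$projection$seed)
})
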