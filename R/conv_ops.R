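# Batched convolution / pooling primitives.
#
# Layout convention throughout: a batch is an (H, W, C, N) array; a single
# feature map is (H, W, C). Spatial positions flatten column-major with the
# row index fastest, matching fm_positions().

# Gather-index table for im2col on a padded input of shape (Hp, Wp, C):
# element [(pos, k)] is the 1-based linear index of patch element k (ordered
# dh fastest, then dw, then channel) for output position pos (row fastest).
im2col_index <- function(H, W, C, kh, kw, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop_shape("kernel %dx%d too large for %dx%d input", kh, kw, H, W)
  h0 <- rep(seq(0L, by = stride, length.out = Ho), times = Wo)   # top-left offsets
  w0 <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  dh <- rep(seq_len(kh), times = kw * C)
  dw <- rep(rep(seq_len(kw), each = kh), times = C)
  dc <- rep(seq_len(C), each = kh * kw)
  # outer sum: positions (P) x patch elements (K)
  idx <- outer(h0, dh, "+") + Hp * (outer(w0, dw, "+") - 1L) +
    (Hp * Wp) * matrix(dc - 1L, nrow = Ho * Wo, ncol = kh * kw * C, byrow = TRUE)
  list(idx = as.integer(idx), Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
       P = Ho * Wo, K = kh * kw * C)
}

pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

conv_layer <- function(Cin, Cout, kh = 3L, kw = 3L, stride = 1L, pad = 1L) {
  K <- kh * kw * Cin
  list(type = "conv", kh = as.integer(kh), kw = as.integer(kw),
       stride = as.integer(stride), pad = as.integer(pad),
       Cin = as.integer(Cin), Cout = as.integer(Cout),
       W = matrix(stats::rnorm(K * Cout, sd = sqrt(2 / K)), K, Cout),
       b = numeric(Cout),
       memo = new.env(parent = emptyenv()))
}

layer_geometry <- function(layer, H, W) {
  key <- paste0("g", H, "x", W)
  g <- layer$memo[[key]]
  if (is.null(g)) {
    g <- im2col_index(H, W, layer$Cin, layer$kh, layer$kw, layer$stride, layer$pad)
    assign(key, g, envir = layer$memo)
  }
  g
}

# x: (H, W, Cin, N) -> list(out = (Ho, Wo, Cout, N), cache)
conv_forward <- function(layer, x) {
  d <- dim(x); N <- d[4]
  if (d[3] != layer$Cin) stop_shape("conv expects %d channels, got %d", layer$Cin, d[3])
  g <- layer_geometry(layer, d[1], d[2])
  xp <- pad_batch(x, layer$pad)
  dim(xp) <- c(g$Hp * g$Wp * layer$Cin, N)
  patches <- xp[g$idx, , drop = FALSE]                 # (P*K) x N
  dim(patches) <- c(g$P, g$K, N)
  Pm <- aperm(patches, c(1, 3, 2))                     # P x N x K
  dim(Pm) <- c(g$P * N, g$K)
  out <- Pm %*% layer$W
  out <- sweep(out, 2, layer$b, "+")
  dim(out) <- c(g$P, N, layer$Cout)
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(g$Ho, g$Wo, layer$Cout, N)
  list(out = out, cache = list(Pm = Pm, g = g, N = N, in_dim = d))
}

# dout: same shape as forward out. Returns dx and parameter gradients.
conv_backward <- function(layer, cache, dout) {
  g <- cache$g; N <- cache$N
  dim(dout) <- c(g$P, layer$Cout, N)
  dm <- aperm(dout, c(1, 3, 2))
  dim(dm) <- c(g$P * N, layer$Cout)
  dW <- crossprod(cache$Pm, dm)
  db <- colSums(dm)
  dPm <- dm %*% t(layer$W)                             # (P*N) x K
  dim(dPm) <- c(g$P, N, g$K)
  dpatches <- aperm(dPm, c(1, 3, 2))                   # P x K x N
  dim(dpatches) <- c(g$P * g$K, N)
  agg <- rowsum(dpatches, group = g$idx)               # unique padded indices x N
  dxp <- matrix(0, g$Hp * g$Wp * layer$Cin, N)
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(g$Hp, g$Wp, layer$Cin, N)
  pad <- layer$pad
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(cache$in_dim[1]), pad + seq_len(cache$in_dim[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_backward <- function(cache, dout) dout * cache

# Fixed-window max / average pooling (forward only; used by the large
# backbone families, which are inference-only).
pool_layer <- function(kind, k, stride, pad = 0L) {
  list(type = "pool", kind = kind, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       memo = new.env(parent = emptyenv()))
}

pool_forward <- function(layer, x) {
  d <- dim(x); C <- d[3]; N <- d[4]
  key <- paste0("g", d[1], "x", d[2])
  g <- layer$memo[[key]]
  if (is.null(g)) {
    g <- im2col_index(d[1], d[2], 1L, layer$k, layer$k, layer$stride, layer$pad)
    assign(key, g, envir = layer$memo)
  }
  xp <- pad_batch(x, layer$pad)
  if (layer$kind == "max" && layer$pad > 0L) {
    # padding must not win a max over negative activations
    mask <- pad_batch(array(1, d), layer$pad) == 0
    xp[mask] <- -Inf
  }
  dim(xp) <- c(g$Hp * g$Wp, C * N)
  red <- if (layer$kind == "max") pmax else `+`
  acc <- NULL
  Kk <- layer$k * layer$k
  idx <- matrix(g$idx, g$P, Kk)
  for (k in seq_len(Kk)) {
    sl <- xp[idx[, k], , drop = FALSE]
    acc <- if (is.null(acc)) sl else red(acc, sl)
  }
  if (layer$kind == "avg") acc <- acc / Kk
  dim(acc) <- c(g$Ho, g$Wo, C, N)
  acc
}

# Adaptive average pooling: output cell (i, j) averages the input window
# rows [floor((i-1)*H/H2)+1, ceil(i*H/H2)], same for columns — windows tile
# the input exactly, uneven sizes allowed.
adaptive_windows <- function(H, H2) {
  lo <- floor((seq_len(H2) - 1) * H / H2) + 1
  hi <- ceiling(seq_len(H2) * H / H2)
  cbind(lo, hi)
}

# P2 x P averaging matrix mapping flattened (H, W) to flattened (H2, W2).
adaptive_pool_matrix <- function(H, W, H2, W2) {
  rw <- adaptive_windows(H, H2); cw <- adaptive_windows(W, W2)
  A <- matrix(0, H2 * W2, H * W)
  for (j2 in seq_len(W2)) for (i2 in seq_len(H2)) {
    rows <- rw[i2, 1]:rw[i2, 2]; cols <- cw[j2, 1]:cw[j2, 2]
    cells <- as.vector(outer(rows, (cols - 1) * H, "+"))
    A[i2 + (j2 - 1) * H2, cells] <- 1 / length(cells)
  }
  A
}

#' Adaptive average pooling of a feature map
#'
#' Averages over near-uniform windows chosen so any input grid maps exactly
#' onto the requested `H2 x W2` output grid; channels are untouched. This is
#' how the two streams' grids are reconciled before bilinear fusion.
#'
#' @param fm A [feature_map()].
#' @param H2,W2 Target spatial size.
#' @return A feature map of dimension `H2 x W2 x C`.
#' @export
adaptive_avg_pool <- function(fm, H2, W2) {
  d <- dim(fm)
  if (H2 < 1 || W2 < 1) stop("target size must be positive", call. = FALSE)
  A <- adaptive_pool_matrix(d[1], d[2], H2, W2)
  out <- A %*% fm_positions(fm)
  feature_map(array(out, c(H2, W2, d[3])))
}

# Batched adaptive pooling: x (H, W, C, N) -> (H2, W2, C, N); dual used in
# backprop.
adaptive_avg_pool_batch <- function(x, A, H2, W2) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  out <- A %*% x
  dim(out) <- c(H2, W2, d[3], d[4])
  out
}
adaptive_avg_pool_batch_back <- function(dout, A, H, W) {
  d <- dim(dout)
  dim(dout) <- c(d[1] * d[2], d[3] * d[4])
  dx <- crossprod(A, dout)
  dim(dx) <- c(H, W, d[3], d[4])
  dx
}
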