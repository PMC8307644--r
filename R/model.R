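#' Align two feature-map grids
#'
#' Adaptively average-pools both maps to their common (elementwise smaller)
#' spatial grid so per-position channel vectors can be paired for bilinear
#' fusion; channel counts are untouched and equal grids pass through
#' unchanged.
#'
#' @param fm_a,fm_b [feature_map()]s, possibly with different grids.
#' @return List with the two aligned maps.
#' @export
align_streams <- function(fm_a, fm_b) {
  da <- dim(fm_a); db <- dim(fm_b)
  H <- min(da[1], db[1]); W <- min(da[2], db[2])
  list(
    a = if (da[1] == H && da[2] == W) fm_a else adaptive_avg_pool(fm_a, H, W),
    b = if (db[1] == H && db[2] == W) fm_b else adaptive_avg_pool(fm_b, H, W)
  )
}

#' Build the two-stream bilinear classifier
#'
#' Assembles the full architecture: two backbone streams (architecturally
#' different by default — the non-homologous configuration), a
#' squeeze-excite attention gate per stream, compact bilinear fusion through
#' a frozen seeded sketch projection, signed-sqrt + L2 descriptor
#' normalization, and a single affine layer onto the K grade logits,
#' exponentially normalized to probabilities.
#'
#' @param spec_a,spec_b [backbone_spec()]s for the two streams.
#' @param d Sketch dimension of the compact bilinear descriptor
#'   (default 8192 at full scale; tests use a few hundred).
#' @param K Number of grades (>= 2).
#' @param r Attention reduction ratio.
#' @param seed Integer seed; construction is fully deterministic given it.
#' @param input_size Expected image size `(H, W)`; 32 x 32 for tiny streams,
#'   224 x 224 otherwise.
#' @param attention If `FALSE`, the gates are omitted (ablation axis).
#' @param homologous If `TRUE`, stream B shares spec and weights with
#'   stream A (ablation axis); requires identical specs.
#' @param fusion `"bilinear"` (compact bilinear pooling of the two streams)
#'   or `"single"` (global average descriptor of stream A only; the
#'   single-stream ablation baseline).
#' @param normalize Apply [normalize_descriptor()] before the classifier.
#' @return A list of class `two_stream_model`.
#' @export
build_model <- function(spec_a, spec_b = spec_a, d = 8192L, K = 5L, r = 16L,
                        seed = 0L, input_size = NULL,
                        attention = TRUE, homologous = FALSE,
                        fusion = c("bilinear", "single"), normalize = TRUE) {
  fusion <- match.arg(fusion)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (homologous && !identical(spec_a, spec_b)) {
    stop("homologous configuration requires identical stream specs", call. = FALSE)
  }
  if (is.null(input_size)) {
    input_size <- if (spec_a$family == "tiny" && spec_b$family == "tiny") c(32L, 32L) else c(224L, 224L)
  }
  seed <- as.integer(seed)
  stream_a <- build_backbone(spec_a, 3L, derive_seed(seed, 1L))
  stream_b <- if (homologous) stream_a else build_backbone(spec_b, 3L, derive_seed(seed, 2L))
  C1 <- spec_a$output_channels; C2 <- spec_b$output_channels
  attention_a <- if (attention) make_excitation_params(C1, r, derive_seed(seed, 3L)) else NULL
  attention_b <- if (!attention) NULL else if (homologous) attention_a else
    make_excitation_params(C2, r, derive_seed(seed, 4L))
  projection <- make_sketch_projection(C1, C2, d, derive_seed(seed, 5L))
  desc_dim <- if (fusion == "bilinear") as.integer(d) else C1
  classifier <- with_seed(derive_seed(seed, 6L), list(
    W = matrix(stats::rnorm(desc_dim * K, sd = 1 / sqrt(desc_dim)), desc_dim, K),
    b = numeric(K)
  ))
  structure(list(
    stream_a = stream_a, stream_b = stream_b,
    attention_a = attention_a, attention_b = attention_b,
    projection = projection, classifier = classifier,
    num_classes = as.integer(K), d = as.integer(d), r = as.integer(r),
    seed = seed, input_size = as.integer(input_size),
    attention = attention, homologous = homologous,
    fusion = fusion, normalize = normalize,
    spec_a = spec_a, spec_b = spec_b
  ), class = "two_stream_model")
}

# --- batched attention over (H, W, C, N) -----------------------------------

attention_forward_batch <- function(x, params) {
  d <- dim(x); P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Fm <- x; dim(Fm) <- c(P, C * N)
  va <- matrix(colMeans(Fm), C, N)
  h <- params$W1 %*% va
  if (!is.null(params$b1)) h <- h + params$b1
  mask <- h > 0
  hr <- h * mask
  z <- params$W2 %*% hr
  if (!is.null(params$b2)) z <- z + params$b2
  w <- 1 / (1 + exp(-z))
  out <- sweep(Fm, 2, as.vector(w), "*")
  dim(out) <- d
  list(out = out, cache = list(Fm = Fm, va = va, hr = hr, mask = mask, w = w,
                               d = d, P = P))
}

attention_backward_batch <- function(cache, params, dout) {
  d <- cache$d; P <- cache$P
  dim(dout) <- c(P, d[3] * d[4])
  wv <- as.vector(cache$w)
  dFm <- sweep(dout, 2, wv, "*")
  dw <- matrix(colSums(dout * cache$Fm), d[3], d[4])
  dz <- dw * cache$w * (1 - cache$w)
  dW2 <- dz %*% t(cache$hr)
  dhr <- crossprod(params$W2, dz)
  dh <- dhr * cache$mask
  dW1 <- dh %*% t(cache$va)
  dva <- crossprod(params$W1, dh)
  dFm <- dFm + matrix(rep(as.vector(dva) / P, each = P), P)
  dim(dFm) <- d
  list(dx = dFm, dW1 = dW1, dW2 = dW2,
       db1 = if (is.null(params$b1)) NULL else rowSums(dh),
       db2 = if (is.null(params$b2)) NULL else rowSums(dz))
}

# --- batched compact bilinear fusion ---------------------------------------

# Xa, Xb: (P, C, N) arrays of aligned per-position channel vectors.
cbp_forward_batch <- function(Xa, Xb, proj) {
  dA <- dim(Xa); P <- dA[1]; N <- dA[3]
  d <- proj$output_dim
  Ma <- count_sketch_matrix(proj$hash1, proj$sign1, d)
  Mb <- count_sketch_matrix(proj$hash2, proj$sign2, d)
  Xa2 <- aperm(Xa, c(1, 3, 2)); dim(Xa2) <- c(P * N, dA[2])
  dB <- dim(Xb)
  Xb2 <- aperm(Xb, c(1, 3, 2)); dim(Xb2) <- c(P * N, dB[2])
  Fa <- stats::mvfft(t(Xa2 %*% Ma))          # d x (P*N), complex
  Fb <- stats::mvfft(t(Xb2 %*% Mb))
  prod <- Fa * Fb
  dim(prod) <- c(d, P, N)
  acc <- matrix(0 + 0i, d, N)
  for (p in seq_len(P)) acc <- acc + prod[, p, ]
  desc <- Re(stats::mvfft(acc, inverse = TRUE)) / d   # d x N
  list(desc = desc, cache = list(Fa = Fa, Fb = Fb, Ma = Ma, Mb = Mb,
                                 P = P, N = N, dA = dA, dB = dB))
}

cbp_backward_batch <- function(cache, proj, ddesc) {
  d <- proj$output_dim; P <- cache$P; N <- cache$N
  Fg <- stats::mvfft(ddesc)                  # d x N
  Fgb <- Fg[, rep(seq_len(N), each = P), drop = FALSE]
  back <- function(Fother, M, C) {
    dS <- Re(stats::mvfft(Fgb * Conj(Fother), inverse = TRUE)) / d  # d x (P*N)
    dX2 <- t(dS) %*% t(M)                    # (P*N) x C
    dim(dX2) <- c(P, N, C)
    aperm(dX2, c(1, 3, 2))
  }
  list(dXa = back(cache$Fb, cache$Ma, cache$dA[2]),
       dXb = back(cache$Fa, cache$Mb, cache$dB[2]))
}

# --- descriptor normalization (column-wise on d x N) -----------------------

normalize_forward_batch <- function(desc) {
  z <- sign(desc) * sqrt(abs(desc))
  nrm <- sqrt(colSums(z^2))
  nz <- pmax(nrm, .Machine$double.eps)
  y <- sweep(z, 2, nz, "/")
  zerocol <- nrm == 0
  if (any(zerocol)) y[, zerocol] <- desc[, zerocol]
  list(out = y, cache = list(desc = desc, z = z, nrm = nz, y = y))
}

normalize_backward_batch <- function(cache, dy) {
  dz <- sweep(dy - sweep(cache$y, 2, colSums(cache$y * dy), "*"), 2, cache$nrm, "/")
  dz / (2 * sqrt(abs(cache$desc)) + 1e-8)
}

# --- full model forward / backward -----------------------------------------

as_image_batch <- function(images, input_size) {
  if (is.list(images)) {
    x <- array(0, c(input_size[1], input_size[2], 3L, length(images)))
    for (i in seq_along(images)) {
      di <- dim(images[[i]])
      if (length(di) != 3L || di[1] != input_size[1] || di[2] != input_size[2] || di[3] != 3L) {
        stop_shape("image %d has shape %s; model expects %dx%dx3",
                   i, paste(di, collapse = "x"), input_size[1], input_size[2])
      }
      x[, , , i] <- images[[i]]
    }
    x
  } else {
    d <- dim(images)
    if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
    if (length(d) != 4L || d[1] != input_size[1] || d[2] != input_size[2] || d[3] != 3L) {
      stop_shape("image batch has shape %s; model expects %dx%dx3xN",
                 paste(d, collapse = "x"), input_size[1], input_size[2])
    }
    images
  }
}

model_forward <- function(model, x, want_cache = FALSE) {
  x <- as_image_batch(x, model$input_size)
  N <- dim(x)[4]
  fa <- backbone_forward(model$stream_a, x, want_cache)
  fb <- if (model$homologous) fa else if (model$fusion == "single") NULL else
    backbone_forward(model$stream_b, x, want_cache)
  za <- fa$out; zb <- if (is.null(fb)) NULL else fb$out
  att_a <- att_b <- NULL
  if (model$attention) {
    att_a <- attention_forward_batch(za, model$attention_a)
    za <- att_a$out
    if (!is.null(zb)) {
      if (model$homologous) { zb <- za; att_b <- att_a } else {
        att_b <- attention_forward_batch(zb, model$attention_b)
        zb <- att_b$out
      }
    }
  } else if (model$homologous && !is.null(zb)) zb <- za

  if (model$fusion == "single") {
    dz <- dim(za); P <- dz[1] * dz[2]
    Fm <- za; dim(Fm) <- c(P, dz[3] * N)
    desc <- matrix(colMeans(Fm), dz[3], N)
    cbp_cache <- list(P = P, dz = dz)
    align_cache <- NULL
  } else {
    dza <- dim(za); dzb <- dim(zb)
    H <- min(dza[1], dzb[1]); W <- min(dza[2], dzb[2])
    Aa <- if (dza[1] != H || dza[2] != W) adaptive_pool_matrix(dza[1], dza[2], H, W) else NULL
    Ab <- if (dzb[1] != H || dzb[2] != W) adaptive_pool_matrix(dzb[1], dzb[2], H, W) else NULL
    pa <- if (is.null(Aa)) za else adaptive_avg_pool_batch(za, Aa, H, W)
    pb <- if (is.null(Ab)) zb else adaptive_avg_pool_batch(zb, Ab, H, W)
    dim(pa) <- c(H * W, dza[3], N)
    dim(pb) <- c(H * W, dzb[3], N)
    fused <- cbp_forward_batch(pa, pb, model$projection)
    desc <- fused$desc
    cbp_cache <- fused$cache
    align_cache <- list(Aa = Aa, Ab = Ab, dza = dza, dzb = dzb, H = H, W = W)
  }

  norm <- if (model$normalize) normalize_forward_batch(desc) else list(out = desc, cache = NULL)
  logits <- t(norm$out) %*% model$classifier$W
  logits <- sweep(logits, 2, model$classifier$b, "+")
  probs <- softmax(logits)
  cache <- if (want_cache) list(
    fa = fa, fb = fb, att_a = att_a, att_b = att_b,
    cbp = cbp_cache, align = align_cache, norm = norm, desc_in = norm$out, N = N
  ) else NULL
  list(probs = probs, logits = logits, cache = cache)
}

# dprobs: gradient of the loss w.r.t. the probability matrix (N x K).
model_backward <- function(model, fwd, dprobs) {
  probs <- fwd$probs
  cache <- fwd$cache
  dlogits <- probs * (dprobs - rowSums(probs * dprobs))   # softmax Jacobian
  Y <- cache$desc_in                                      # d x N
  gW <- Y %*% dlogits
  gb <- colSums(dlogits)
  dY <- model$classifier$W %*% t(dlogits)                 # d x N
  ddesc <- if (model$normalize) normalize_backward_batch(cache$norm$cache, dY) else dY

  grads <- list(classifier = list(dW = gW, db = gb))
  if (model$fusion == "single") {
    cc <- cache$cbp
    dFm <- matrix(rep(as.vector(ddesc) / cc$P, each = cc$P), cc$P)
    dza <- dFm; dim(dza) <- cc$dz
    dzb <- NULL
  } else {
    al <- cache$align
    dXab <- cbp_backward_batch(cache$cbp, model$projection, ddesc)
    dpa <- dXab$dXa; dim(dpa) <- c(al$H, al$W, al$dza[3], cache$N)
    dpb <- dXab$dXb; dim(dpb) <- c(al$H, al$W, al$dzb[3], cache$N)
    dza <- if (is.null(al$Aa)) dpa else adaptive_avg_pool_batch_back(dpa, al$Aa, al$dza[1], al$dza[2])
    dzb <- if (is.null(al$Ab)) dpb else adaptive_avg_pool_batch_back(dpb, al$Ab, al$dzb[1], al$dzb[2])
  }

  if (model$homologous && !is.null(dzb)) { dza <- dza + dzb; dzb <- NULL }

  if (model$attention) {
    ab <- attention_backward_batch(cache$att_a$cache, model$attention_a, dza)
    dza <- ab$dx
    grads$attention_a <- ab[c("dW1", "dW2", "db1", "db2")]
    if (!is.null(dzb)) {
      bb <- attention_backward_batch(cache$att_b$cache, model$attention_b, dzb)
      dzb <- bb$dx
      grads$attention_b <- bb[c("dW1", "dW2", "db1", "db2")]
    }
  }

  ga <- backbone_backward(model$stream_a, cache$fa$caches, dza)
  grads$stream_a <- ga$grads
  if (!is.null(dzb)) {
    gbk <- backbone_backward(model$stream_b, cache$fb$caches, dzb)
    grads$stream_b <- gbk$grads
  }
  grads
}

#' Forward pass: images to grade probabilities
#'
#' Runs the full pipeline — backbone streams, channel attention, stream
#' alignment, compact bilinear pooling, descriptor normalization, affine
#' classifier, softmax — and returns one probability vector over the K
#' grades per image.
#'
#' @param model A [build_model()] object.
#' @param images An `H x W x 3 x N` array (or a list of `H x W x 3` arrays)
#'   matching the model's `input_size`.
#' @return An `N x K` matrix of class probabilities (rows sum to 1).
#' @export
forward <- function(model, images) {
  model_forward(model, images, want_cache = FALSE)$probs
}

#' Save / load a model checkpoint
#'
#' The parameter archive is written with [saveRDS()] next to a JSON sidecar
#' recording the architecture arguments (families, d, K, r, seed, fusion,
#' attention flags) sufficient to rebuild the model and regenerate its
#' frozen sketch projection.
#'
#' @param model A `two_stream_model`.
#' @param path Checkpoint path (`.rds`); the sidecar gets `.json` appended.
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  sidecar <- list(
    family_a = model$spec_a$family, family_b = model$spec_b$family,
    output_channels_a = model$spec_a$output_channels,
    output_channels_b = model$spec_b$output_channels,
    depth_a = model$spec_a$depth, depth_b = model$spec_b$depth,
    d = model$d, K = model$num_classes, r = model$r, seed = model$seed,
    input_size = model$input_size, attention = model$attention,
    homologous = model$homologous, fusion = model$fusion,
    normalize = model$normalize, projection_seed = model$projection$seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
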