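#' Global average pooling (squeeze step)
#'
#' Collapses the spatial grid of a feature map to one mean activation per
#' channel: `v[c] = mean over (i, j) of fm[i, j, c]`.
#'
#' @param fm A [feature_map()].
#' @return Numeric vector of length C.
#' @export
global_average_pool <- function(fm) {
  d <- dim(fm)
  if (is.null(d) || length(d) != 3L || any(d < 1L)) {
    stop_shape("global_average_pool needs a nonempty H x W x C array")
  }
  colMeans(fm_positions(fm))
}

#' Create excitation (channel-gate) parameters
#'
#' The two fully connected layers of the squeeze-and-excite gate: `W1` maps
#' the C pooled activations down to `max(1, floor(C / r))` units, `W2` maps
#' back up to C. Weights are Gaussian, scaled by 1/sqrt(fan-in), drawn from
#' a seeded generator. Biases are omitted by default (the gate is a pure
#' weight product) but can be enabled.
#'
#' @param C Channel count.
#' @param r Reduction ratio (default 16).
#' @param seed Integer seed.
#' @param bias If `TRUE`, include zero-initialized bias vectors.
#' @return List of class `excitation_params` with `W1` (C_r x C), `W2`
#'   (C x C_r), optional `b1`, `b2`, and `reduction_ratio`.
#' @export
make_excitation_params <- function(C, r = 16, seed = 0L, bias = FALSE) {
  if (C < 1 || r < 1) stop("C and r must be positive", call. = FALSE)
  Cr <- max(1L, C %/% as.integer(r))
  with_seed(as.integer(seed), {
    p <- list(
      W1 = matrix(stats::rnorm(Cr * C, sd = 1 / sqrt(C)), Cr, C),
      W2 = matrix(stats::rnorm(C * Cr, sd = 1 / sqrt(Cr)), C, Cr),
      b1 = if (bias) numeric(Cr) else NULL,
      b2 = if (bias) numeric(C) else NULL,
      reduction_ratio = as.integer(r)
    )
    structure(p, class = "excitation_params")
  })
}

#' Excitation: pooled activations to channel weights
#'
#' The gate `sigma(W2 %*% relu(W1 %*% v))`: a bottleneck ReLU layer followed
#' by a sigmoid, producing one weight strictly in (0, 1) per channel. The
#' weights express learned interdependence between channels; multiplying
#' them back onto the map re-scales each channel by its importance.
#'
#' @param v Pooled channel vector (length C, from [global_average_pool()]).
#' @param params An [make_excitation_params()] object.
#' @return `channel_weights`: numeric vector of length C, entries in (0, 1).
#' @export
excitation <- function(v, params) {
  if (length(v) != ncol(params$W1)) {
    stop_shape("excitation: input length %d does not match W1 columns %d",
               length(v), ncol(params$W1))
  }
  h <- as.vector(params$W1 %*% v)
  if (!is.null(params$b1)) h <- h + params$b1
  h <- pmax(h, 0)
  z <- as.vector(params$W2 %*% h)
  if (!is.null(params$b2)) z <- z + params$b2
  1 / (1 + exp(-z))
}

#' Re-weight feature-map channels
#'
#' Multiplies channel `c` of the map by `w[c]` at every spatial position.
#' Output shape equals input shape, so the module can sit between a backbone
#' and the pooling stage.
#'
#' @param fm A [feature_map()].
#' @param w Channel weights, length C.
#' @return A feature map of identical dimensions.
#' @export
apply_attention <- function(fm, w) {
  d <- dim(fm)
  if (length(w) != d[3]) {
    stop_shape("apply_attention: %d weights for %d channels", length(w), d[3])
  }
  out <- fm * rep(w, each = d[1] * d[2])
  feature_map(array(out, d))
}

# Bilinear (two-axis linear interpolation) resize of a matrix, align-corners
# convention; used only for heatmap rendering.
resize_bilinear <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ri <- if (H2 == 1) rep(1, 1) else seq(1, H, length.out = H2)
  ci <- if (W2 == 1) rep(1, 1) else seq(1, W, length.out = W2)
  r0 <- pmin(floor(ri), H - 1); r0 <- pmax(r0, 1); rf <- ri - r0
  c0 <- pmin(floor(ci), W - 1); c0 <- pmax(c0, 1); cf <- ci - c0
  if (H == 1) { r0 <- rep(1, H2); rf <- rep(0, H2) }
  if (W == 1) { c0 <- rep(1, W2); cf <- rep(0, W2) }
  a <- m[r0, c0, drop = FALSE]; b <- m[pmin(r0 + 1, H), c0, drop = FALSE]
  cc <- m[r0, pmin(c0 + 1, W), drop = FALSE]; dd <- m[pmin(r0 + 1, H), pmin(c0 + 1, W), drop = FALSE]
  RF <- matrix(rf, H2, W2); CF <- matrix(cf, H2, W2, byrow = TRUE)
  a * (1 - RF) * (1 - CF) + b * RF * (1 - CF) + cc * (1 - RF) * CF + dd * RF * CF
}

#' Attention heatmap
#'
#' Renders where the gated model is looking: the channel-weighted sum
#' `sum_c w[c] * fm[, , c]`, bilinearly resized to `out_size` and min-max
#' scaled to `[0, 1]` (red = high weight when colorized). A spatially
#' constant map has no contrast and yields all zeros.
#'
#' @param fm A [feature_map()].
#' @param w Channel weights, length C.
#' @param out_size Integer `(H', W')` of the rendered grid.
#' @return `H' x W'` numeric matrix with values in `[0, 1]`.
#' @export
attention_heatmap <- function(fm, w, out_size = dim(fm)[1:2]) {
  if (any(out_size < 1)) stop("out_size entries must be positive", call. = FALSE)
  d <- dim(fm)
  if (length(w) != d[3]) stop_shape("%d weights for %d channels", length(w), d[3])
  acc <- matrix(fm_positions(fm) %*% w, d[1], d[2])
  acc <- resize_bilinear(acc, out_size[1], out_size[2])
  rng <- range(acc)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(matrix(0, out_size[1], out_size[2]))
  }
  (acc - rng[1]) / (rng[2] - rng[1])
}

#' Write a heatmap as an 8-bit PNG
#'
#' Maps `[0, 1]` heat to a blue-to-red ramp; with `overlay` (an H x W x 3
#' raster in `[0, 1]`, resized heat grid must match) the colors are
#' alpha-blended onto the source image.
#'
#' @param heat Matrix in `[0, 1]` from [attention_heatmap()].
#' @param path Output PNG path.
#' @param overlay Optional H x W x 3 array in `[0, 1]`.
#' @param alpha Blend weight of the heat layer when overlaying.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heat, path, overlay = NULL, alpha = 0.45) {
  col <- array(0, c(nrow(heat), ncol(heat), 3))
  col[, , 1] <- heat                 # red ramps up with weight
  col[, , 3] <- 1 - heat             # blue ramps down
  col[, , 2] <- 1 - abs(2 * heat - 1) * 0.6
  if (!is.null(overlay)) {
    if (!all(dim(overlay)[1:2] == dim(heat))) {
      stop_shape("overlay grid %dx%d does not match heatmap %dx%d",
                 dim(overlay)[1], dim(overlay)[2], nrow(heat), ncol(heat))
    }
    col <- (1 - alpha) * overlay + alpha * col
  }
  png::writePNG(clamp(col, 0, 1), path)
  invisible(path)
}
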