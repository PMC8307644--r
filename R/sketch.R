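#' Create a seeded sketch projection
#'
#' Builds the frozen random tables of the tensor-sketch projection
#' `phi: R^C1 x R^C2 -> R^d`: for each input stream, a hash table mapping
#' each channel to one of `d` buckets and a Rademacher sign table. Tables are
#' drawn uniformly from a generator seeded with `seed`, so the same
#' `(C1, C2, d, seed)` always reproduces bit-identical tables; they are never
#' learned.
#'
#' @param C1,C2 Channel counts of the two input streams.
#' @param d Output (sketch) dimension; the full-scale default used by
#'   [build_model()] is 8192, desk-scale tests use a few hundred.
#' @param seed Integer seed.
#' @return An object of class `sketch_projection` with fields `input_dims`,
#'   `output_dim`, `hash1`, `hash2` (1-based bucket indices in `[1, d]`),
#'   `sign1`, `sign2` (in `{-1, +1}`), and `seed`.
#' @export
make_sketch_projection <- function(C1, C2, d, seed = 0L) {
  if (length(d) != 1L || is.na(d) || d < 1) stop("output dimension d must be >= 1", call. = FALSE)
  if (C1 < 1 || C2 < 1) stop("channel counts must be >= 1", call. = FALSE)
  C1 <- as.integer(C1); C2 <- as.integer(C2); d <- as.integer(d)
  tabs <- with_seed(as.integer(seed), list(
    hash1 = sample.int(d, C1, replace = TRUE),
    sign1 = sample(c(-1, 1), C1, replace = TRUE),
    hash2 = sample.int(d, C2, replace = TRUE),
    sign2 = sample(c(-1, 1), C2, replace = TRUE)
  ))
  structure(
    c(list(input_dims = c(C1, C2), output_dim = d, seed = as.integer(seed)), tabs),
    class = "sketch_projection"
  )
}

#' Count sketch of a vector
#'
#' The count-sketch linear map: entry `k` of the output accumulates
#' `sign[i] * v[i]` over all `i` hashed to bucket `k`. Linear in `v`; it is
#' the building block of the tensor-sketch projection.
#'
#' @param v Numeric vector.
#' @param hash_table 1-based bucket index per entry of `v`.
#' @param sign_table Signs in `{-1, +1}`, same length as `v`.
#' @param d Sketch length.
#' @return Numeric vector of length `d`.
#' @export
count_sketch <- function(v, hash_table, sign_table, d) {
  if (length(v) != length(hash_table) || length(v) != length(sign_table)) {
    stop_shape("count_sketch: vector length %d does not match table length %d",
               length(v), length(hash_table))
  }
  out <- numeric(d)
  sv <- sign_table * v
  for (i in seq_along(v)) out[hash_table[i]] <- out[hash_table[i]] + sv[i]
  out
}

# Count sketch of a whole matrix of row vectors (one sketch per row),
# realized as a dense multiply by the C x d indicator-sign matrix. Used on
# the hot path where X holds the channel vectors of many spatial positions.
count_sketch_matrix <- function(hash_table, sign_table, d) {
  M <- matrix(0, nrow = length(hash_table), ncol = d)
  M[cbind(seq_along(hash_table), hash_table)] <- sign_table
  M
}

#' Tensor sketch of the outer product of two vectors
#'
#' Sketches `x %o% y` without forming it: the circular convolution of the two
#' count sketches, computed in the frequency domain (`O(d log d)`). Over
#' independent draws of the projection tables the sketch is unbiased for the
#' second-order polynomial kernel:
#' `E <ts(x, y), ts(x', y')> = <x, x'> * <y, y'>`.
#'
#' @param x,y Numeric vectors of lengths `proj$input_dims`.
#' @param proj A [make_sketch_projection()] object.
#' @return Numeric vector of length `proj$output_dim`.
#' @export
tensor_sketch <- function(x, y, proj) {
  if (length(x) != proj$input_dims[1] || length(y) != proj$input_dims[2]) {
    stop_shape("tensor_sketch: input lengths (%d, %d) do not match projection dims (%d, %d)",
               length(x), length(y), proj$input_dims[1], proj$input_dims[2])
  }
  sx <- count_sketch(x, proj$hash1, proj$sign1, proj$output_dim)
  sy <- count_sketch(y, proj$hash2, proj$sign2, proj$output_dim)
  Re(stats::fft(stats::fft(sx) * stats::fft(sy), inverse = TRUE)) / proj$output_dim
}

#' Compact bilinear pooling
#'
#' The low-dimensional randomized counterpart of [bilinear_pool()]: the
#' tensor sketches of the per-position channel-vector outer products, summed
#' over all spatial positions, `C(X) = sum_s phi(a_s, b_s)`. Inner products of
#' compact descriptors approximate inner products of the exact bilinear
#' descriptors, with relative error shrinking as `d` grows.
#'
#' @param fm_a,fm_b Feature maps sharing the spatial grid, with channel
#'   counts equal to `proj$input_dims`.
#' @param proj A [make_sketch_projection()] object.
#' @return Numeric vector of length `proj$output_dim` (the compact
#'   descriptor).
#' @export
compact_bilinear_pool <- function(fm_a, fm_b, proj) {
  check_same_grid(fm_a, fm_b)
  Xa <- fm_positions(fm_a)
  Xb <- fm_positions(fm_b)
  if (ncol(Xa) != proj$input_dims[1] || ncol(Xb) != proj$input_dims[2]) {
    stop_shape("channel counts (%d, %d) do not match projection dims (%d, %d)",
               ncol(Xa), ncol(Xb), proj$input_dims[1], proj$input_dims[2])
  }
  cbp_from_positions(Xa, Xb, proj)
}

# Hot path shared with the model forward pass: positions-by-channels inputs.
# Sum of circular convolutions done with a single inverse FFT by linearity.
cbp_from_positions <- function(Xa, Xb, proj) {
  d <- proj$output_dim
  Sa <- Xa %*% count_sketch_matrix(proj$hash1, proj$sign1, d)   # P x d
  Sb <- Xb %*% count_sketch_matrix(proj$hash2, proj$sign2, d)
  Fa <- stats::mvfft(t(Sa))                                     # d x P
  Fb <- stats::mvfft(t(Sb))
  acc <- rowSums(Fa * Fb)                                       # sum over positions
  Re(stats::fft(acc, inverse = TRUE)) / d
}

#' Normalize a compact descriptor
#'
#' Standard post-pooling normalization for bilinear features: elementwise
#' signed square root (`sign(e) * sqrt(|e|)`), then scaling to unit Euclidean
#' length. Dampens bursty components and puts descriptors on a common scale
#' before the linear classifier. The all-zero descriptor is returned
#' unchanged.
#'
#' @param desc Numeric vector (finite entries).
#' @return Normalized vector of the same length.
#' @export
normalize_descriptor <- function(desc) {
  if (!all(is.finite(desc))) stop("descriptor has non-finite entries", call. = FALSE)
  z <- sign(desc) * sqrt(abs(desc))
  nrm <- sqrt(sum(z^2))
  if (nrm == 0) return(desc)
  z / nrm
}

#' Serialize / restore a sketch projection
#'
#' Writes the defining record `(C1, C2, d, seed)` as plain-text key-value
#' lines; the tables themselves are regenerated from the seed on load, so the
#' round trip is exact.
#'
#' @param proj A `sketch_projection`.
#' @param path File path.
#' @return `read_projection()` returns the reconstructed projection.
#' @export
write_projection <- function(proj, path) {
  writeLines(sprintf("%s: %d",
                     c("C1", "C2", "d", "seed"),
                     c(proj$input_dims, proj$output_dim, proj$seed)), path)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  kv <- yaml::read_yaml(path)
  make_sketch_projection(kv$C1, kv$C2, kv$d, kv$seed)
}
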