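#' Exact bilinear pooling
#'
#' Sums the outer products of the two streams' channel vectors over all
#' spatial positions: `B[i, j] = sum_s a[s, i] * b[s, j]`. The result is the
#' full (uncompressed) bilinear descriptor of dimension C1 x C2; with both
#' streams equal it is symmetric positive semi-definite. This exact form is
#' the oracle against which the compact sketch approximation
#' ([compact_bilinear_pool()]) is validated.
#'
#' @param fm_a,fm_b Feature maps sharing the spatial grid (H, W); channel
#'   counts may differ.
#' @return A C1 x C2 numeric matrix.
#' @seealso [bilinear_inner_product()], [compact_bilinear_pool()]
#' @examples
#' fm <- feature_map(array(c(1, 2), c(1, 1, 2)))
#' bilinear_pool(fm, fm)  # outer product of (1, 2) with itself
#' @export
bilinear_pool <- function(fm_a, fm_b) {
  check_same_grid(fm_a, fm_b)
  crossprod(fm_positions(fm_a), fm_positions(fm_b))
}

#' Inner product of two bilinear descriptors
#'
#' Computes `<B(X), B(Y)>` where `B(X) = bilinear_pool(fm_a, fm_b)` and
#' `B(Y) = bilinear_pool(fm_c, fm_d)`. For self-stream inputs
#' (`fm_a == fm_b`, `fm_c == fm_d`) this equals the second-order polynomial
#' kernel `sum_s sum_u <x_s, y_u>^2` — the quantity the tensor sketch
#' approximates in expectation.
#'
#' @param fm_a,fm_b Streams defining the first descriptor.
#' @param fm_c,fm_d Streams defining the second descriptor.
#' @return A scalar.
#' @export
bilinear_inner_product <- function(fm_a, fm_b, fm_c = fm_a, fm_d = fm_b) {
  ba <- bilinear_pool(fm_a, fm_b)
  bb <- bilinear_pool(fm_c, fm_d)
  if (!all(dim(ba) == dim(bb))) {
    stop_shape("descriptor shapes differ: %dx%d vs %dx%d",
               dim(ba)[1], dim(ba)[2], dim(bb)[1], dim(bb)[2])
  }
  sum(ba * bb)
}
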