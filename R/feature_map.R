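#' Construct a feature map
#'
#' A feature map is the H x W x C activation grid emitted by a convolutional
#' backbone: at each of the H*W spatial positions it holds a C-dimensional
#' channel vector. All entries must be finite.
#'
#' @param values Numeric 3-d array of dimension H x W x C, or a matrix
#'   (interpreted as H x W x 1), or anything coercible by [array()].
#' @return A numeric array of class `feature_map`.
#' @examples
#' fm <- feature_map(array(rnorm(2 * 2 * 3), c(2, 2, 3)))
#' dim(fm)
#' @export
feature_map <- function(values) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_shape("a feature map must be an H x W x C array (got %s dims)",
               length(dim(values)))
  }
  if (any(dim(values) < 1L)) stop_shape("feature map dimensions must all be >= 1")
  if (!all(is.finite(values))) stop_shape("feature map entries must all be finite")
  storage.mode(values) <- "double"
  class(values) <- c("feature_map", class(values))
  values
}

# Flatten an H x W x C map to a (H*W) x C matrix of per-position channel
# vectors. Position order is column-major over (H, W), and is the single
# order used everywhere a map is iterated spatially.
fm_positions <- function(fm) {
  d <- dim(fm)
  matrix(as.vector(fm), nrow = d[1] * d[2], ncol = d[3])
}

fm_channels <- function(fm) dim(fm)[3]

check_same_grid <- function(fm_a, fm_b) {
  da <- dim(fm_a); db <- dim(fm_b)
  if (da[1] != db[1] || da[2] != db[2]) {
    stop_shape("feature maps must share the spatial grid: %dx%d vs %dx%d",
               da[1], da[2], db[1], db[2])
  }
  invisible(TRUE)
}
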