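#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: mixes a base seed with a stream index
# into [0, 2^31 - 2]. Used so per-image / per-epoch randomness is independent
# of generation order.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807 + 12345
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Softmax normalization
#'
#' Exponential normalization of a logit vector (or of each row of a logit
#' matrix) to a probability vector summing to one. Shift-invariant and
#' overflow-safe.
#'
#' @param z Numeric vector of logits, or a matrix with one sample per row.
#' @return Probabilities with the same shape as `z`.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
  }
}

stop_shape <- function(...) stop(sprintf(...), call. = FALSE)
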