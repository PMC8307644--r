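#' Bundle predicted probabilities with ground-truth grades
#'
#' @param probs Numeric matrix, one row per sample: nonnegative entries
#'   summing to 1 within 1e-6 (a probability vector over the K grades).
#' @param labels Integer vector of true grades, 0-based in `[0, K)`.
#' @return An object of class `labeled_batch` with fields `probs`, `labels`
#'   (1-based internally), `N`, `K`.
#' @export
labeled_batch <- function(probs, labels) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  N <- nrow(probs); K <- ncol(probs)
  if (N < 1L) stop("batch must contain at least one sample", call. = FALSE)
  if (length(labels) != N) stop_shape("probs has %d rows but %d labels given", N, length(labels))
  if (any(probs < -1e-9)) stop("probabilities must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("each probability vector must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= K)) {
    stop(sprintf("labels must lie in [0, %d)", K), call. = FALSE)
  }
  structure(list(probs = probs, labels = labels + 1L, N = N, K = K),
            class = "labeled_batch")
}

#' Loss configuration
#'
#' @param gamma Adjustment factor on the balanced complement-entropy term of
#'   [cce_loss()]. Default -1: minimizing the combined loss then pushes the
#'   complement entropy up, i.e. spreads the non-target probability mass
#'   uniformly, which is the behaviour the objective is designed for.
#'   Positive values are accepted for the literal-sum variant.
#' @param epsilon Clamp floor for logs and for `1 - p_g` denominators; must
#'   lie in (0, 1e-3].
#' @param focal_gamma,focal_alpha Focusing exponent (>= 0) and weight of
#'   [focal_loss()].
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(gamma = -1, epsilon = 1e-7, focal_gamma = 2, focal_alpha = 1) {
  if (epsilon <= 0 || epsilon > 1e-3) stop("epsilon must be in (0, 1e-3]", call. = FALSE)
  if (focal_gamma < 0) stop("focal_gamma must be nonnegative", call. = FALSE)
  structure(list(gamma = gamma, epsilon = epsilon,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "loss_config")
}

target_probs <- function(batch) batch$probs[cbind(seq_len(batch$N), batch$labels)]

#' Cross-entropy loss
#'
#' Mean negative natural log of the probability assigned to the true grade,
#' with the probability clamped to `[epsilon, 1]` for numerical safety.
#'
#' @param batch A [labeled_batch()].
#' @param cfg A [loss_config()].
#' @param grad If `TRUE`, also return the analytic gradient with respect to
#'   the probability matrix (same shape as `batch$probs`).
#' @return The scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
cross_entropy <- function(batch, cfg = loss_config(), grad = FALSE) {
  pg <- clamp(target_probs(batch), cfg$epsilon, 1)
  value <- -mean(log(pg))
  if (!grad) return(value)
  G <- matrix(0, batch$N, batch$K)
  G[cbind(seq_len(batch$N), batch$labels)] <- -1 / (batch$N * pg)
  list(value = value, grad = G)
}

#' Complement entropy
#'
#' Mean (over the batch) Shannon entropy of the predicted distribution
#' restricted to the incorrect grades, each sample's non-target mass
#' renormalized by `1 - p_g`. Lies in `[0, log(K - 1)]`; it is maximal
#' exactly when the non-target mass is spread uniformly, so *raising* it
#' makes the model non-committal among wrong grades — the mechanism by which
#' the combined objective protects minority grades. A sample whose target
#' probability is 1 contributes 0.
#'
#' @inheritParams cross_entropy
#' @return The scalar entropy, or `list(value, grad)`.
#' @export
complement_entropy <- function(batch, cfg = loss_config(), grad = FALSE) {
  if (batch$K < 2L) stop("complement entropy needs at least 2 classes", call. = FALSE)
  P <- batch$probs
  N <- batch$N; K <- batch$K
  idx <- cbind(seq_len(N), batch$labels)
  pg <- clamp(P[idx], 0, 1 - cfg$epsilon)
  q <- 1 - pg                                  # per-sample non-target mass
  Pn <- P
  Pn[idx] <- 0                                 # zero out the target column
  R <- Pn / q                                  # renormalized non-target probs
  L <- ifelse(R > 0, log(R), 0)
  value <- max(-sum(R * L) / N, 0)   # guard the [0, log(K-1)] range against rounding
  if (!grad) return(value)
  G <- -(L + 1) / (q * N)                      # d/dp_j, j != g, where R > 0
  G[R == 0] <- 0
  # d/dp_g through q = 1 - p_g (zero where the clamp is active)
  gg <- rowSums(ifelse(R > 0, Pn * (L + 1), 0)) / (q^2 * N)
  gg[P[idx] >= 1 - cfg$epsilon] <- 0
  G[idx] <- -gg
  list(value = value, grad = G)
}

#' Balanced complement entropy
#'
#' [complement_entropy()] scaled by the balance coefficient `1 / (K - 1)`,
#' which puts it on the same scale as the cross entropy.
#'
#' @inheritParams cross_entropy
#' @export
balanced_complement_entropy <- function(batch, cfg = loss_config(), grad = FALSE) {
  out <- complement_entropy(batch, cfg, grad = grad)
  if (!grad) return(out / (batch$K - 1))
  list(value = out$value / (batch$K - 1), grad = out$grad / (batch$K - 1))
}

#' Complement cross-entropy (CCE) loss
#'
#' The combined objective
#' `L = H(y, p) + gamma / (K - 1) * C(y, p)`:
#' cross entropy plus the balanced complement entropy scaled by the
#' adjustment factor `gamma`. With the default `gamma = -1` the optimizer
#' maximizes the complement entropy while minimizing the cross entropy,
#' flattening the probability mass over incorrect grades; `gamma = 0`
#' reduces exactly to [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @export
cce_loss <- function(batch, cfg = loss_config(), grad = FALSE) {
  ce <- cross_entropy(batch, cfg, grad = grad)
  if (batch$K < 2L || (!grad && cfg$gamma == 0)) return(ce)
  comp <- complement_entropy(batch, cfg, grad = grad)
  w <- cfg$gamma / (batch$K - 1)
  if (!grad) return(ce + w * comp)
  list(value = ce$value + w * comp$value, grad = ce$grad + w * comp$grad)
}

#' Focal loss
#'
#' Cross entropy with the modulating factor `(1 - p_g)^focal_gamma`, which
#' down-weights already well-classified samples; the classical baseline for
#' long-tailed image classification. `focal_gamma = 0, focal_alpha = 1`
#' recovers [cross_entropy()] exactly.
#'
#' @inheritParams cross_entropy
#' @export
focal_loss <- function(batch, cfg = loss_config(), grad = FALSE) {
  if (cfg$focal_gamma < 0) stop("focal_gamma must be nonnegative", call. = FALSE)
  pg_raw <- target_probs(batch)
  pg <- clamp(pg_raw, cfg$epsilon, 1)
  a <- cfg$focal_alpha; fg <- cfg$focal_gamma
  mod <- (1 - pg_raw)^fg
  value <- -mean(a * mod * log(pg))
  if (!grad) return(value)
  # d/dp [ -a (1-p)^fg log p ] = a * fg * (1-p)^(fg-1) * log p - a (1-p)^fg / p
  dmod <- if (fg == 0) 0 else fg * (1 - pg_raw)^(fg - 1)
  gvec <- (a * dmod * log(pg) - a * mod / pg) / batch$N
  G <- matrix(0, batch$N, batch$K)
  G[cbind(seq_len(batch$N), batch$labels)] <- gvec
  list(value = value, grad = G)
}

# Dispatch used by the training loop; name in {"ce", "focal", "cce"}.
loss_by_name <- function(name) {
  switch(name,
    ce = cross_entropy,
    focal = focal_loss,
    cce = cce_loss,
    stop(sprintf("unknown loss '%s' (expected ce, focal or cce)", name), call. = FALSE)
  )
}
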