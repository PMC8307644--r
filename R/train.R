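#' Training configuration
#'
#' @param epochs Passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD step size.
#' @param momentum Momentum coefficient.
#' @param optimizer Only `"sgd"` (momentum SGD) is implemented.
#' @param seed Seed controlling batch shuffling; recorded in the history.
#' @param loss One of `"ce"`, `"focal"`, `"cce"`.
#' @param loss_cfg A [loss_config()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 0.01,
                         momentum = 0.9, optimizer = "sgd", seed = 0L,
                         loss = c("cce", "ce", "focal"), loss_cfg = loss_config()) {
  loss <- match.arg(loss)
  if (epochs < 0 || batch_size < 1 || learning_rate <= 0 || momentum < 0) {
    stop("epochs/batch_size/learning_rate/momentum must be positive", call. = FALSE)
  }
  if (optimizer != "sgd") stop("only the momentum-SGD optimizer is implemented", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 optimizer = optimizer, seed = as.integer(seed),
                 loss = loss, loss_cfg = loss_cfg),
            class = "train_config")
}

# Enumerate (path into model, path into grads) pairs for every trainable
# parameter of a tiny-family model.
trainable_pairs <- function(model) {
  pairs <- list(
    list(m = c("classifier", "W"), g = c("classifier", "dW")),
    list(m = c("classifier", "b"), g = c("classifier", "db"))
  )
  add_att <- function(pairs, slot) {
    p <- model[[slot]]
    pairs <- c(pairs,
               list(list(m = c(slot, "W1"), g = c(slot, "dW1")),
                    list(m = c(slot, "W2"), g = c(slot, "dW2"))))
    if (!is.null(p$b1)) {
      pairs <- c(pairs,
                 list(list(m = c(slot, "b1"), g = c(slot, "db1")),
                      list(m = c(slot, "b2"), g = c(slot, "db2"))))
    }
    pairs
  }
  if (model$attention) {
    pairs <- add_att(pairs, "attention_a")
    if (!model$homologous && model$fusion != "single") pairs <- add_att(pairs, "attention_b")
  }
  add_stream <- function(pairs, slot) {
    for (i in backbone_param_refs(model[[slot]])) {
      pairs <- c(pairs,
                 list(list(m = list(slot, "layers", i, "W"), g = list(slot, i, "dW")),
                      list(m = list(slot, "layers", i, "b"), g = list(slot, i, "db"))))
    }
    pairs
  }
  pairs <- add_stream(pairs, "stream_a")
  if (!model$homologous && model$fusion != "single") pairs <- add_stream(pairs, "stream_b")
  pairs
}

# Paths are lists so numeric layer indices keep their type (a character "1"
# would silently miss on unnamed lists).
path_get <- function(x, path) {
  for (p in path) {
    x <- x[[p]]
    if (is.null(x)) stop("internal: empty parameter path", call. = FALSE)
  }
  x
}
path_set <- function(x, path, value) {
  if (length(path) == 1L) { x[[path[[1]]]] <- value; return(x) }
  x[[path[[1]]]] <- path_set(x[[path[[1]]]], path[-1], value)
  x
}

#' Train a model
#'
#' Mini-batch momentum SGD on the selected loss. Shuffling is seeded per
#' epoch from `cfg$seed`, so identical `(model, data, cfg)` inputs give
#' identical parameter trajectories and histories. Training aborts with a
#' diagnostic if the loss turns non-finite. With `epochs = 0` the model is
#' returned unchanged.
#'
#' @param model A `tiny`-family [build_model()] object.
#' @param train_ds A `labeled_image_set`.
#' @param cfg A [train_config()].
#' @param eval_ds Optional held-out set; when given, metrics are recorded
#'   per epoch.
#' @return `list(model =, history =)` where `history` is a data.frame with
#'   one row per epoch (`epoch`, `loss`, and metrics when `eval_ds` given).
#' @export
train <- function(model, train_ds, cfg = train_config(), eval_ds = NULL) {
  n <- length(train_ds$labels)
  if (n < 1L) stop("training set is empty", call. = FALSE)
  loss_fn <- loss_by_name(cfg$loss)
  pairs <- trainable_pairs(model)
  velocity <- vector("list", length(pairs))
  history <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    order <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1L, n)]
      x <- as_image_batch(train_ds$images[idx], model$input_size)
      fwd <- model_forward(model, x, want_cache = TRUE)
      batch <- labeled_batch(fwd$probs, train_ds$labels[idx])
      lg <- loss_fn(batch, cfg$loss_cfg, grad = TRUE)
      if (!is.finite(lg$value)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      }
      epoch_loss <- epoch_loss + lg$value; nb <- nb + 1L
      grads <- model_backward(model, fwd, lg$grad)
      for (k in seq_along(pairs)) {
        g <- path_get(grads, pairs[[k]]$g)
        v <- velocity[[k]]
        v <- if (is.null(v)) g else cfg$momentum * v + g
        velocity[[k]] <- v
        model <- path_set(model, pairs[[k]]$m,
                          path_get(model, pairs[[k]]$m) - cfg$learning_rate * v)
      }
      if (model$homologous) model$stream_b <- model$stream_a
    }
    row <- data.frame(epoch = epoch, loss = epoch_loss / nb)
    if (!is.null(eval_ds)) {
      m <- evaluate(model, eval_ds)
      row$accuracy <- m$accuracy; row$precision <- m$precision
      row$recall <- m$recall; row$f1 <- m$f1
    }
    history[[epoch]] <- row
  }
  history <- if (cfg$epochs > 0) do.call(rbind, history) else
    data.frame(epoch = integer(0), loss = numeric(0))
  attr(history, "seed") <- cfg$seed
  list(model = model, history = history)
}
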