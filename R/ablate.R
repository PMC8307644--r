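#' Desk-scale ablation harness
#'
#' Runs a set of named single-axis variations of a shared base
#' configuration over several seeds on a synthetic dataset and tabulates
#' mean and s.d. of the evaluation metrics per configuration, plus the mean
#' recall on the two rarest grades (the quantity the imbalance loss is
#' meant to improve). The supported axes mirror the model's design choices:
#' `fusion` (single-stream vs bilinear), `homologous` (shared vs distinct
#' streams), `backbone_b` (stream-B family mix), `loss` (ce / focal / cce)
#' and `attention` (gates on / off).
#'
#' @param grid Named list; each element is `list(axis =, value =)` touching
#'   exactly one axis (conflicting specifications are rejected).
#' @param data_spec A [synthetic_dataset_spec()]; the dataset is generated
#'   once and re-split per seed.
#' @param seeds Integer vector of run seeds.
#' @param base List of shared arguments: `spec_a`, `spec_b`, `d`, `K`, `r`,
#'   `attention`, `train` (a [train_config()]), `test_fraction`.
#' @return A data.frame, one row per configuration.
#' @export
ablate <- function(grid, data_spec, seeds, base = list()) {
  axes <- c("fusion", "homologous", "backbone_b", "loss", "attention")
  for (nm in names(grid)) {
    g <- grid[[nm]]
    if (!is.list(g) || is.null(g$axis) || length(g$axis) != 1L || !(g$axis %in% axes)) {
      stop(sprintf("configuration '%s' must name exactly one axis among: %s",
                   nm, paste(axes, collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(names(g), c("axis", "value"))
    if (length(extra)) {
      stop(sprintf("configuration '%s' sets fields beyond its axis: %s",
                   nm, paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  spec_a <- base$spec_a %||% backbone_spec("tiny", output_channels = 8L, depth = 2L)
  spec_b <- base$spec_b %||% backbone_spec("tiny", output_channels = 12L, depth = 3L)
  d <- base$d %||% 256L
  K <- base$K %||% data_spec$num_classes
  r <- base$r %||% 4L
  tf <- base$test_fraction %||% 0.21
  base_train <- base$train %||% train_config()
  ds <- generate_dataset(data_spec)

  rows <- list()
  for (nm in names(grid)) {
    g <- grid[[nm]]
    acc <- prc <- rec <- f1 <- minr <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      seed <- seeds[si]
      split <- train_test_split(ds, tf, seed = seed)
      sb <- if (g$axis == "backbone_b") g$value else spec_b
      homo <- if (g$axis == "homologous") isTRUE(g$value) else FALSE
      model <- build_model(
        spec_a = spec_a,
        spec_b = if (homo) spec_a else sb,
        d = d, K = K, r = r, seed = seed,
        attention = if (g$axis == "attention") isTRUE(g$value) else (base$attention %||% TRUE),
        homologous = homo,
        fusion = if (g$axis == "fusion") g$value else "bilinear"
      )
      cfg <- base_train
      cfg$seed <- as.integer(seed)
      if (g$axis == "loss") cfg$loss <- g$value
      fit <- train(model, split$train, cfg)
      m <- evaluate(fit$model, split$test)
      acc[si] <- m$accuracy; prc[si] <- m$precision
      rec[si] <- m$recall; f1[si] <- m$f1
      rare <- order(data_spec$class_counts)[1:2] - 1L
      minr[si] <- mean(m$per_class_recall[rare + 1L])
    }
    rows[[nm]] <- data.frame(
      config = nm, axis = g$axis, value = paste(g$value, collapse = ","),
      accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
      precision_mean = mean(prc), recall_mean = mean(rec), f1_mean = mean(f1),
      minority_recall_mean = mean(minr), minority_recall_sd = stats::sd(minr),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
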