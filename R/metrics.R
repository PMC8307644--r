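#' Classification metrics from predictions
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction)
#' and derives accuracy (fraction of exact matches — the Jaccard index of
#' singleton label sets), macro-averaged precision, recall and F1 (harmonic
#' mean of the macro precision and macro recall), and the per-class recall
#' vector. Classes absent from both truth and prediction contribute 0 to
#' the macro terms.
#'
#' @param predicted,truth Integer vectors of 0-based grades.
#' @param K Number of classes.
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `per_class_recall`, `confusion`.
#' @export
metrics_from_predictions <- function(predicted, truth, K) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    stop("predicted and truth must be nonempty vectors of equal length", call. = FALSE)
  }
  lev <- 0:(K - 1)
  confusion <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  confusion <- matrix(as.integer(confusion), K, K,
                      dimnames = list(truth = lev, predicted = lev))
  tp <- diag(confusion)
  row_n <- rowSums(confusion)   # support per true class
  col_n <- colSums(confusion)   # predictions per class
  prec_c <- ifelse(col_n > 0, tp / col_n, 0)
  rec_c <- ifelse(row_n > 0, tp / row_n, 0)
  precision <- mean(prec_c)
  recall <- mean(rec_c)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = sum(tp) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 per_class_recall = rec_c, confusion = confusion),
            class = "metrics_report")
}

# Argmax with ties broken toward the lowest class index.
predict_grades <- function(probs) max.col(probs, ties.method = "first") - 1L

#' Evaluate a model on a labeled image set
#'
#' Predicts each image's grade as the class of maximal probability (ties to
#' the lowest index) and scores against the true grades.
#'
#' @param model A [build_model()] object.
#' @param ds A `labeled_image_set`.
#' @param batch_size Images per forward pass.
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, ds, batch_size = 64L) {
  n <- length(ds$labels)
  if (n == 0L) stop("evaluation set is empty", call. = FALSE)
  preds <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs <- forward(model, ds$images[idx])
    preds[idx] <- predict_grades(probs)
  }
  metrics_from_predictions(preds, ds$labels, model$num_classes)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, f1 = report$f1,
    per_class_recall = as.numeric(report$per_class_recall),
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
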