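# Classifier evaluation: confusion matrix (rows = predicted class, columns
# = true class), per-class precision / recall / F1, macro averages and
# overall accuracy. Classes absent from the test set get NA metrics (they
# are undefined, not zero) and are flagged.

#' Evaluate a trained pulse classifier on a test set
#'
#' Computes per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)`, their macro averages over the classes present, the
#' overall accuracy, and the confusion matrix with rows for predictions and
#' columns for the truth.
#'
#' @param model A `pulse_cnn` from [train_cnn()].
#' @param test A `segment_set` with labels.
#' @return An `evaluation_report`: list with `confusion`, `metrics` (tibble),
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, `n_test`.
#' @export
evaluate_cnn <- function(model, test) {
  stopifnot(inherits(model, "pulse_cnn"))
  if (!inherits(test, "segment_set") || nrow(test) == 0) {
    abort_pulsekit("`test` must be a non-empty segment_set.", "pulsekit_bad_argument")
  }
  truth <- factor(test$label, levels = model$classes)
  pred <- factor(predict(model, test), levels = model$classes)
  confusion <- table(predicted = pred, true = truth)
  metrics <- metrics_from_confusion(confusion)

  structure(
    list(
      confusion = confusion, metrics = metrics,
      accuracy = sum(diag(confusion)) / sum(confusion),
      macro_precision = mean(metrics$precision, na.rm = TRUE),
      macro_recall = mean(metrics$recall, na.rm = TRUE),
      macro_f1 = mean(metrics$f1, na.rm = TRUE),
      n_test = nrow(test)
    ),
    class = "evaluation_report"
  )
}

#' Per-class metrics from a confusion matrix
#'
#' Applies the standard definitions — precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` — to a square confusion matrix with rows
#' for predicted and columns for true classes. Classes with no true
#' examples get `NA` (undefined) rather than 0.
#'
#' @param confusion Square numeric matrix or table, rows = predicted,
#'   columns = true; row and column names are the class labels.
#' @return A tibble with one row per class.
#' @export
#' @examples
#' m <- matrix(c(8, 2, 2, 8), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' metrics_from_confusion(m)
metrics_from_confusion <- function(confusion) {
  if (nrow(confusion) != ncol(confusion)) {
    abort_pulsekit("`confusion` must be square (predicted x true).",
      "pulsekit_bad_argument")
  }
  classes <- rownames(confusion)
  purrr::map_dfr(classes, function(cls) {
    tp <- confusion[cls, cls]
    fp <- sum(confusion[cls, ]) - tp
    fn <- sum(confusion[, cls]) - tp
    present <- sum(confusion[, cls]) > 0
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (present) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      NA_real_
    }
    tibble(
      class = cls, n_true = as.numeric(tp + fn), precision = precision,
      recall = recall, f1 = f1, present = present
    )
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n = %d, accuracy %.4f, macro F1 %.4f\n",
    x$n_test, x$accuracy, x$macro_f1
  ))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  x$metrics
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, macro_precision = x$macro_precision,
    macro_recall = x$macro_recall, macro_f1 = x$macro_f1, n_test = x$n_test
  )
}

#' @export
tidy.pulse_cnn <- function(x, ...) {
  x$history
}

#' @export
glance.pulse_cnn <- function(x, ...) {
  tibble(
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    final_train_accuracy = x$final_train_accuracy,
    n_classes = x$config$n_classes
  )
}
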