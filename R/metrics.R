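#' Binary classification metrics with ROC/AUC
#'
#' Computes the confusion counts and standard metrics (accuracy,
#' precision, recall, F-measure as the harmonic mean of precision and
#' recall), plus a ROC curve and its trapezoidal AUC. With continuous
#' `scores` the ROC sweeps the score thresholds; without scores the
#' binary predictions themselves act as a single-threshold score, giving
#' the two-segment ROC. If the truth contains a single class the AUC is
#' undefined and reported as `NA`.
#'
#' @param truth Integer 0/1 vector of true labels.
#' @param pred Integer 0/1 vector of predicted labels, same length.
#' @param scores Optional numeric decision scores (larger = class 1).
#' @return A list of class `metrics_report`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f_measure`, `auc`, and
#'   `roc_points` (data frame of `fpr`, `tpr`).
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0)) # all metrics 0.5
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  if (length(truth) != length(pred)) stop("length mismatch: truth vs pred")
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  if (!is.null(scores) && length(scores) != length(truth)) {
    stop("length mismatch: scores")
  }
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fn <- sum(truth == 1L & pred == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_

  roc <- NULL
  auc <- NA_real_
  if (length(unique(truth)) == 2L) {
    s <- if (is.null(scores)) as.numeric(pred) else as.numeric(scores)
    roc <- roc_points(truth, s)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(truth),
         precision = precision, recall = recall, f_measure = f,
         auc = auc, roc_points = roc),
    class = "metrics_report"
  )
}

# ROC by sweeping unique score thresholds from high to low; starts at
# (0, 0) and ends at (1, 1), with tied scores collapsed to one point
roc_points <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]; scores <- scores[ord]
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  tps <- cumsum(truth == 1L)
  fps <- cumsum(truth == 0L)
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  data.frame(fpr = c(0, fps[last_of_tie] / N),
             tpr = c(0, tps[last_of_tie] / P))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %s | recall %s | F %s | AUC %s\n",
    x$accuracy, format(x$precision, digits = 4),
    format(x$recall, digits = 4), format(x$f_measure, digits = 4),
    format(x$auc, digits = 4)))
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Write ROC points as CSV
#'
#' @param report A [compute_metrics()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  if (is.null(report$roc_points)) stop("report has no ROC (single-class truth)")
  utils::write.csv(report$roc_points, path, row.names = FALSE)
  invisible(path)
}
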