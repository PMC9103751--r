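#' Confusion-matrix metrics for binary classification
#'
#' Accuracy, sensitivity (recall of the positive class) and specificity
#' (recall of the negative class).  The positive class defaults to label
#' 1 (Yin deficiency).  When the evaluated set contains no positives (or
#' no negatives), sensitivity (or specificity) is undefined and reported
#' as `NaN` with a warning.
#'
#' @param labels integer vector of gold labels in `{0, 1}`.
#' @param predictions integer vector of predicted labels, same length.
#' @param positive_class the label counted as positive.
#' @return an object of class `eval_report` with fields `task`,
#'   `accuracy`, `specificity`, `sensitivity`, `confusion` (2 x 2 matrix,
#'   gold in rows) and `n`.
#' @export
classification_metrics <- function(labels, predictions, positive_class = 1L) {
  if (length(labels) != length(predictions))
    stop("classification_metrics: length mismatch")
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  n <- length(labels)
  sens <- if (tp + fn == 0L) {
    warning("no positive examples: sensitivity undefined"); NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) {
    warning("no negative examples: specificity undefined"); NaN
  } else tn / (tn + fp)
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(gold = c("neg", "pos"),
                                      pred = c("neg", "pos")))
  structure(list(task = "classification",
                 accuracy = (tp + tn) / n,
                 specificity = spec, sensitivity = sens,
                 confusion = confusion, n = n),
            class = "eval_report")
}

#' Character-tag metrics for the segmentation task
#'
#' Accuracy is the fraction of real (unmasked) characters with the
#' correct tag.  Sensitivity is the macro-average over the tags `{B, I,
#' O}` of per-tag recall, and specificity the macro-average of per-tag
#' one-vs-rest specificity; tags absent from the gold standard are
#' excluded from the recall macro-average.
#'
#' @param gold_tags list of per-record gold tag vectors (integer codes
#'   1/2/3 or characters `"B"/"I"/"O"`).
#' @param pred_tags list of predicted tag vectors, aligned with
#'   `gold_tags`.
#' @return an object of class `eval_report` with the 3 x 3 `confusion`
#'   matrix (gold in rows) and `n` the number of evaluated characters.
#' @export
segmentation_metrics <- function(gold_tags, pred_tags) {
  to_int <- function(x) {
    if (is.character(x)) c(B = 1L, I = 2L, O = 3L)[x] else as.integer(x)
  }
  g <- to_int(unlist(gold_tags, use.names = FALSE))
  p <- to_int(unlist(pred_tags, use.names = FALSE))
  if (length(g) != length(p)) stop("segmentation_metrics: length mismatch")
  n <- length(g)
  confusion <- matrix(0L, 3L, 3L,
                      dimnames = list(gold = c("B", "I", "O"),
                                      pred = c("B", "I", "O")))
  for (i in 1:3) for (j in 1:3) confusion[i, j] <- sum(g == i & p == j)
  acc <- sum(diag(confusion)) / n
  recalls <- vapply(1:3, function(k) {
    tot <- sum(confusion[k, ])
    if (tot == 0L) NA_real_ else confusion[k, k] / tot
  }, numeric(1L))
  specs <- vapply(1:3, function(k) {
    tn <- sum(confusion[-k, -k])
    fp <- sum(confusion[-k, k])
    if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  }, numeric(1L))
  structure(list(task = "segmentation",
                 accuracy = acc,
                 sensitivity = mean(recalls, na.rm = TRUE),
                 specificity = mean(specs, na.rm = TRUE),
                 per_tag_recall = recalls,
                 confusion = confusion, n = n),
            class = "eval_report")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (classifying `score >=
#' threshold` as positive), yielding one ROC point per threshold plus the
#' endpoints (0,0) and (1,1); the AUC is the trapezoidal area, which
#' under this construction equals the rank/U-statistic estimator with
#' ties counted as half.
#'
#' @param labels integer vector of gold labels in `{0, 1}` (1 positive).
#' @param scores numeric scores, larger meaning more positive.
#' @return list with `roc_points` (data frame `fpr`, `tpr`,
#'   nondecreasing in both coordinates) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("roc_auc: length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1L))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s metrics (n = %d)\n", x$task, x$n))
  cat(sprintf("  accuracy:    %.4f\n", x$accuracy))
  cat(sprintf("  specificity: %.4f\n", x$specificity))
  cat(sprintf("  sensitivity: %.4f\n", x$sensitivity))
  if (!is.null(x$auc)) cat(sprintf("  AUC:         %.4f\n", x$auc))
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the report as JSON, and its ROC points (if any) as CSV next to
#' it.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  roc <- x$roc_points
  x$roc_points <- NULL
  x$confusion <- as.data.frame.matrix(x$confusion)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(roc))
    utils::write.csv(roc, sub("\\.json$", "_roc.csv", path), row.names = FALSE)
  invisible(path)
}
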