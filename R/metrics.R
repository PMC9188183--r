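# Ranking metrics: AUROC (Mann-Whitney rank statistic, ties count 0.5),
# AUPRC (precision-recall step integration / average precision), and F1
# at a fixed threshold.

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic; tied scores contribute 0.5.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve (average precision):
#' scores are sorted in decreasing order and precision is accumulated at
#' every positive hit.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  if (np == 0L || np == length(labels)) {
    stop("AUPRC needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / np
}

#' F1 score at a fixed threshold
#'
#' @inheritParams auroc
#' @param threshold scores `>= threshold` are predicted positive.
#' @return F1 in `[0, 1]` (0 when no positive predictions or positives).
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Compute the full metrics report
#'
#' @inheritParams f1_score
#' @param seed optional seed annotation carried into the report.
#' @return object of class `metrics_report`: list with `auroc`, `auprc`,
#'   `f1`, `n_pos`, `n_neg`, `threshold`, `seed`.
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5,
                            seed = NA_integer_) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("metrics need at least one positive and one negative label")
  }
  structure(list(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 f1 = f1_score(scores, labels, threshold),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 threshold = threshold, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUROC %.4f  AUPRC %.4f  F1 %.4f  (%d pos / %d neg, thr %.2f)\n",
              x$auroc, x$auprc, x$f1, x$n_pos, x$n_neg, x$threshold))
  invisible(x)
}
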