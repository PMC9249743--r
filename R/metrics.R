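# Binary-classification metrics: confusion table, accuracy, PPV, recall,
# specificity, F1, and rank-statistic AUC.

#' Rank-statistic AUC (ties counted half)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties contributing 1/2 — computed from mid-ranks,
#' equivalent to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels aligned with `scores`.
#' @return the AUC in `[0, 1]`; `NA` with a warning if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Compute a metrics report from labels, predictions and scores
#'
#' Positive class is 1.  PPV (precision) is `NA` with a warning when
#' nothing is predicted positive; specificity and AUC are `NA` with a
#' warning when a class is absent from `labels` — never silently zero.
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @param positive_scores optional continuous scores for AUC (e.g. the
#'   forest's vote fraction).
#' @return a `metrics_report`: accuracy, ppv, recall, specificity, f1,
#'   auc, n, and the 2 x 2 `confusion` table (rows = truth,
#'   cols = prediction).
#' @export
compute_metrics <- function(labels, predicted, positive_scores = NULL) {
  if (!length(labels) || length(labels) != length(predicted))
    stop("labels and predicted must be non-empty and aligned")
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  tp <- sum(labels == 1L & predicted == 1L)
  fp <- sum(labels == 0L & predicted == 1L)
  tn <- sum(labels == 0L & predicted == 0L)
  fn <- sum(labels == 1L & predicted == 0L)
  n <- length(labels)
  acc <- (tp + tn) / n
  ppv <- if (tp + fp == 0L) {
    warning("PPV undefined: no positive predictions"); NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) {
    warning("recall undefined: no positive labels"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) {
    warning("specificity undefined: no negative labels"); NA_real_
  } else tn / (tn + fp)
  f1 <- if (!is.na(ppv) && !is.na(recall) && (ppv + recall) > 0)
    2 * ppv * recall / (ppv + recall) else NA_real_
  auc <- if (is.null(positive_scores)) NA_real_
         else auc_rank(positive_scores, labels)
  confusion <- matrix(c(tn, fn, fp, tp), 2L, 2L,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  structure(list(accuracy = acc, ppv = ppv, recall = recall,
                 specificity = spec, f1 = f1, auc = auc,
                 confusion = confusion, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | ppv %.4f | recall %.4f | specificity %.4f | f1 %.4f | auc %s  (n = %d)\n",
    x$accuracy, x$ppv, x$recall, x$specificity, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, ppv = x$ppv, recall = x$recall,
             specificity = x$specificity, f1 = x$f1, auc = x$auc, n = x$n)
}
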