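check_two_class <- function(labels) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (length(unique(labels)) < 2) abort("both classes must be present")
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a random positive outranks a random negative, with
#' ties given half credit; computed from midranks, equivalent to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_class(labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area: thresholds descend through the unique scores
#' and each recall increment is credited with the precision at that
#' threshold (the average-precision summation).
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_two_class(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # cut after each block of tied scores
  cuts <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[cuts]
  n_at <- cuts
  n_pos <- sum(y)
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Youden-optimal classification threshold
#'
#' Scans all candidate cuts (midpoints between adjacent distinct sorted
#' scores, plus one boundary cut below the minimum and one above the
#' maximum) and returns the threshold maximizing Youden's
#' `J = sensitivity + specificity - 1` under the rule `score >= t` =>
#' positive. Ties are broken toward the smaller threshold.
#'
#' @inheritParams roc_auc
#' @return List with `threshold` and `j` (the maximal J).
#' @export
youden_threshold <- function(scores, labels) {
  check_two_class(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / n_pos + sum(!pred & labels == 0) / n_neg - 1
  }, numeric(1))
  best <- which.max(j)   # first maximum = smallest threshold on ties
  list(threshold = cand[best], j = j[best])
}

#' Matthews correlation coefficient at a threshold
#'
#' MCC of the confusion matrix obtained with the rule `score >= t` =>
#' positive. Returns 0 when any confusion-matrix marginal is zero (the
#' usual degenerate-case convention).
#'
#' @inheritParams roc_auc
#' @param t Classification threshold.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_at_threshold <- function(scores, labels, t) {
  if (!is.finite(t)) abort("threshold must be finite")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  pred <- as.integer(scores >= t)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

accuracy_at_threshold <- function(scores, labels, t) {
  mean((scores >= t) == (labels == 1))
}
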