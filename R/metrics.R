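# Classification and affinity-regression metrics with brute-force-verifiable
# definitions: rank-based AUC with midrank ties, precision-recall step-curve
# area, and the tie-aware concordance index.

#' ROC AUC (rank-based, midrank tie handling)
#'
#' Equals the Mann-Whitney statistic: the probability that a random positive
#' is scored above a random negative, with half credit for score ties.
#'
#' @param scores Numeric prediction scores (any monotone scale).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall step curve
#'
#' Thresholds are swept over all distinct scores (descending); the area is
#' the step-curve sum `sum (recall_t - recall_{t-1}) * precision_t`.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  npos <- sum(labels == 1)
  if (npos == 0) stop("at least one positive required")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each threshold
  tp <- tp[keep]
  fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Precision and recall at a probability threshold
#'
#' Precision is 0 by convention when nothing is predicted positive.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold on the probabilities (default 0.5).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(scores, labels, threshold = 0.5) {
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Mean squared error
#'
#' @param pred,true Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mse <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  mean((pred - true)^2)
}

#' Concordance index for affinity prediction
#'
#' Over all pairs with distinct true affinities `delta_i > delta_j`, the
#' fraction predicted in concordant order, with half credit for prediction
#' ties: `CI = (1/Z) * sum h(b_i - b_j)` with `h(x) = 1, 0.5, 0` for
#' `x > 0, x = 0, x < 0`.
#'
#' @param true Experimental affinities.
#' @param pred Predicted affinities.
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  n <- length(true)
  if (n < 2L) stop("need at least two observations")
  if (length(unique(true)) < 2L) stop("all true values are equal")
  num <- 0
  z <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- true[i] - true[j]
    b <- pred[i] - pred[j]
    sgn <- sign(d)
    rel <- sgn != 0
    # orient each pair so the larger truth comes first
    h <- ifelse(b * sgn > 0, 1, ifelse(b == 0, 0.5, 0))
    num <- num + sum(h[rel])
    z <- z + sum(rel)
  }
  num / z
}

#' Aggregate per-fold metrics into a report
#'
#' Binds per-fold metric rows and appends a mean row (`fold = "mean"`).
#'
#' @param fold_metrics List of one-row data.frames as returned by
#'   [evaluate()].
#' @return `data.frame` with a `fold` column, one row per fold plus a mean.
#' @export
metric_report <- function(fold_metrics) {
  df <- do.call(rbind, fold_metrics)
  df <- cbind(fold = as.character(seq_len(nrow(df))), df)
  mean_row <- cbind(fold = "mean",
                    as.data.frame(as.list(colMeans(df[-1]))))
  rownames(df) <- NULL
  rbind(df, mean_row)
}
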