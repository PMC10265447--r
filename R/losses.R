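# Relation losses. Binary relations are scored as raw logits; the sigmoid
# lives inside the numerically stable cross-entropy (and in prediction).

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Class-balanced binary cross-entropy on logits
#'
#' Binary cross-entropy of `plogis(scores)` against `labels`, with the
#' positive class re-weighted by the relation-wide class balance. The loss is
#' the weighted mean (weights `pos_weight` for positives, 1 for negatives,
#' normalised by their sum), so a perfectly class-balanced gradient is
#' obtained when `pos_weight` is the negative:positive count ratio.
#'
#' @param scores Numeric logits.
#' @param labels Values in `{0, 1}`.
#' @param pos_weight Positive-class weight; `NULL` computes the
#'   negative:positive count ratio from `labels` (1 if a class is absent).
#' @return Scalar loss.
#' @export
balanced_bce <- function(scores, labels, pos_weight = NULL) {
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  if (length(scores) != length(labels)) stop("length mismatch")
  if (is.null(pos_weight)) pos_weight <- bce_pos_weight(labels)
  w <- ifelse(labels == 1, pos_weight, 1)
  l <- ifelse(labels == 1, softplus(-scores), softplus(scores))
  sum(w * l) / sum(w)
}

# per-score gradient of balanced_bce
balanced_bce_grad <- function(scores, labels, pos_weight) {
  w <- ifelse(labels == 1, pos_weight, 1)
  w * (plogis(scores) - labels) / sum(w)
}

#' Positive-class weight from a label vector
#'
#' @param values Binary labels of a relation's (training) cells.
#' @param direction `"neg_over_pos"` (default: up-weight minority positives
#'   by `N_neg / N_pos`) or `"pos_over_neg"` for the literal positive:negative
#'   ratio.
#' @return Scalar weight; 1 when either class is absent.
#' @export
bce_pos_weight <- function(values, direction = c("neg_over_pos", "pos_over_neg")) {
  direction <- match.arg(direction)
  npos <- sum(values == 1)
  nneg <- sum(values == 0)
  if (npos == 0 || nneg == 0) return(1)
  if (direction == "neg_over_pos") nneg / npos else npos / nneg
}

# loss value + dscore for one batch of one relation
relation_loss_grad <- function(rel, scores, values, pos_weight) {
  if (rel$loss == "bce_balanced") {
    list(loss = balanced_bce(scores, values, pos_weight),
         dscore = balanced_bce_grad(scores, values, pos_weight))
  } else {
    r <- scores - values
    list(loss = mean(r * r), dscore = 2 * r / length(r))
  }
}
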