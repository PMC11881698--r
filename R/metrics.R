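#' Area under the ROC curve
#'
#' Mann-Whitney rank form: the probability that a random positive outscores a
#' random negative, with ties counted half. Agrees with the trapezoidal ROC
#' integral.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, one per score.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC requires both a positive and a negative example")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: thresholds are placed at each distinct score
#' (descending) and AUPRC is the sum of precision times the recall increment
#' at each threshold. Tied scores enter as one threshold group, so the value
#' does not depend on the order of tied predictions.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || sum(labels == 0) == 0) {
    stop("AUPRC requires both a positive and a negative example")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # distinct-score threshold groups
  tp_g <- rowsum(as.numeric(y), grp)[, 1]
  n_g <- rowsum(rep(1, length(y)), grp)[, 1]
  tp <- cumsum(tp_g)
  np <- cumsum(n_g)
  precision <- tp / np
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Evaluation result container
#'
#' @param auroc,auprc areas under the ROC / precision-recall curves.
#' @param n_pos,n_neg test-set class counts.
#' @return An object of class `EvalResult`.
#' @export
eval_result <- function(auroc, auprc, n_pos, n_neg) {
  stopifnot(auroc >= 0, auroc <= 1, auprc >= 0, auprc <= 1)
  structure(list(auroc = auroc, auprc = auprc, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg)),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult: AUROC %.4f, AUPRC %.4f (%d pos / %d neg)\n",
              x$auroc, x$auprc, x$n_pos, x$n_neg))
  invisible(x)
}
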