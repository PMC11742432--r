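# Bag- and instance-level evaluation. ROC AUC is the Mann-Whitney rank
# statistic with tie-averaging; PR AUC integrates precision over recall
# steps. Bag-level evaluation scores the pooled site probability F(B),
# instance-level evaluation the Platt-scaled per-read probabilities.

#' ROC and PR AUC
#'
#' ROC AUC is computed from average ranks (equivalent to the probability a
#' random positive outranks a random negative, ties counting one half). PR
#' AUC sums precision at each positive, stepping recall (the average
#' precision estimator), with ties grouped so the result is invariant to the
#' input order.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels, both classes present.
#' @return List with `roc_auc` and `pr_auc`.
#' @export
roc_pr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("undefined AUC: single-class labels")
  r <- rank(scores, ties.method = "average")
  roc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # PR AUC over unique score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))             # tie groups
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))  # end of each group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  pr <- sum(diff(c(0, recall)) * precision)
  list(roc_auc = roc, pr_auc = pr)
}

#' Precision, recall and F1 at a threshold
#'
#' Predicted positive iff `score >= threshold`. When there are no predicted
#' positives, precision is undefined and reported as 0 with
#' `precision_defined = FALSE`; F1 is 0 when precision + recall = 0.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param threshold Operating point in `[0, 1]` (default 0.5).
#' @return List with `precision`, `recall`, `f1`, `precision_defined`.
#' @export
prf_at <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1, all(labels %in% c(0, 1)))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       precision_defined = precision_defined)
}

#' Precision among the top-n scored items
#'
#' Fraction of true positives among the `n` highest-scoring items; ties are
#' broken by stable original order.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param n Number of top items, 1 <= n <= length(scores).
#' @return Scalar precision.
#' @export
top_n_precision <- function(scores, labels, n) {
  if (n <= 0) stop("n must be positive")
  stopifnot(n <= length(scores), all(labels %in% c(0, 1)))
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord[seq_len(n)]] == 1)
}

#' Coverage-stratified site evaluation
#'
#' Re-applies the bag builder's coverage filter at each threshold and
#' evaluates predicted site probabilities against the truth on exactly the
#' surviving site set, guaranteeing identical site sets between pipeline and
#' evaluation.
#'
#' @param predictions `sites` data frame from [predict_bags()].
#' @param truth Named 0/1 vector of true bag labels keyed by bag id.
#' @param min_reads_grid Coverage thresholds (default `c(3, 5, 20)`).
#' @param threshold Operating point for precision/recall/F1.
#' @return A data frame with one row per threshold: `min_reads`,
#'   `n_evaluated`, `roc_auc`, `pr_auc`, `precision`, `recall`, `f1`.
#' @export
evaluate_by_coverage <- function(predictions, truth,
                                 min_reads_grid = c(3L, 5L, 20L),
                                 threshold = 0.5) {
  rows <- lapply(min_reads_grid, function(mr) {
    keep <- predictions$n_reads >= mr
    sub <- predictions[keep, , drop = FALSE]
    y <- truth[sub$bag_id]
    if (nrow(sub) == 0L || length(unique(y)) < 2L) {
      return(data.frame(min_reads = mr, n_evaluated = nrow(sub),
                        roc_auc = NA_real_, pr_auc = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_))
    }
    auc <- roc_pr(sub$site_prob, y)
    prf <- prf_at(sub$site_prob, y, threshold)
    data.frame(min_reads = mr, n_evaluated = nrow(sub),
               roc_auc = auc$roc_auc, pr_auc = auc$pr_auc,
               precision = prf$precision, recall = prf$recall, f1 = prf$f1)
  })
  do.call(rbind, rows)
}
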