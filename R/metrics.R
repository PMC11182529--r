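# Classification and ranking metrics.

#' Threshold-free binary classification metrics
#'
#' ROC-AUC via the rank statistic (ties get half credit), AUPR via
#' precision-recall step integration (average precision), and F1 at a fixed
#' decision threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (at least one of each class).
#' @param threshold decision threshold for F1 (default 0.5).
#' @return list with `auc`, `aupr`, `f1`, `n_samples`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_ddi("binary_metrics needs both classes present",
             class = "ddigcl_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # average precision: mean of precision@k over positive ranks (descending
  # score order, stable tie-break by original index)
  ord <- order(-scores)
  ysort <- labels[ord]
  cum_pos <- cumsum(ysort)
  prec <- cum_pos / seq_along(ysort)
  aupr <- sum(prec[ysort == 1]) / n_pos
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc, aupr = aupr, f1 = f1, n_samples = length(labels))
}

#' Ranking metrics over a scored candidate list
#'
#' Items are ranked by descending score (stable tie-break by input order).
#' MRR is the mean over positives of 1/rank; MAP is average precision.
#' Two HIT@K conventions are reported: `hit_at_k` (1 if any positive is in
#' the top K) and `hit_frac_at_k` (fraction of the top K that is positive).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels with at least one positive.
#' @param ks integer vector of cutoffs (default c(1, 3, 10)).
#' @return list with `map`, `mrr`, `hit_at_k`, `hit_frac_at_k`
#'   (named by K), and `n_samples`.
#' @export
ranking_metrics <- function(scores, labels, ks = c(1L, 3L, 10L)) {
  if (!length(scores)) {
    stop_ddi("empty input", class = "ddigcl_metric_error")
  }
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (sum(labels == 1) == 0) {
    stop_ddi("ranking_metrics needs at least one positive",
             class = "ddigcl_metric_error")
  }
  ord <- order(-scores)
  ysort <- labels[ord]
  pos_ranks <- which(ysort == 1)
  mrr <- mean(1 / pos_ranks)
  cum_pos <- cumsum(ysort)
  prec <- cum_pos / seq_along(ysort)
  map <- mean(prec[pos_ranks])
  hit <- hitf <- setNames(numeric(length(ks)), paste0("K", ks))
  for (t in seq_along(ks)) {
    k <- min(ks[t], length(ysort))
    top <- ysort[seq_len(k)]
    hit[t] <- as.numeric(any(top == 1))
    hitf[t] <- mean(top == 1)
  }
  list(map = map, mrr = mrr, hit_at_k = hit, hit_frac_at_k = hitf,
       n_samples = length(labels))
}
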