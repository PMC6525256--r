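#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer counts, at least one positive
#' @return object of class `confusion_counts`
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    abort_param("confusion counts must be nonnegative integers")
  if (sum(v) < 1) abort_param("confusion counts must sum to at least 1")
  structure(as.list(v), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced single-number summary of a binary confusion table, in
#' `[-1, 1]` and robust to class imbalance. When any denominator factor is
#' zero the value is 0 by convention (logged via `message`).
#'
#' @param counts a [confusion_counts()] (or a list with tp/tn/fp/fn)
#' @return numeric MCC
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    message("mcc: zero factor in denominator; returning 0 by convention")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' Threshold-free ranking metric: the probability that a random positive
#' pixel scores above a random negative one, with ties counted half.
#'
#' @param scores numeric per-pixel scores (larger = more lesion-like)
#' @param labels binary labels (0/1 or logical)
#' @return AUC in `[0, 1]`
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    abort_param("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    abort_data("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing MCC on a score vector
#'
#' Scans candidate thresholds (the midpoints between distinct score
#' quantiles) and returns the one with the highest MCC; ties resolve to the
#' lowest threshold. Used to pick the operating point on training scores.
#'
#' @param scores numeric scores
#' @param labels binary labels
#' @param n_grid maximum number of candidate thresholds
#' @return `list(threshold, mcc)`
#' @keywords internal
best_mcc_threshold <- function(scores, labels, n_grid = 512L) {
  labels <- as.integer(as.logical(labels))
  qs <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_grid),
                               names = FALSE, type = 1L))
  cand <- if (length(qs) > 1L) (qs[-1L] + qs[-length(qs)]) / 2 else qs
  best <- list(threshold = cand[1L], mcc = -Inf)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ord <- order(scores)
  s_sorted <- scores[ord]; l_sorted <- labels[ord]
  cum_pos <- cumsum(l_sorted)
  cum_all <- seq_along(l_sorted)
  for (th in cand) {
    i <- findInterval(th, s_sorted)        # scores <= th are negative calls
    fn <- if (i > 0) cum_pos[i] else 0L
    tn <- (if (i > 0) cum_all[i] else 0L) - fn
    tp <- n1 - fn
    fp <- n0 - tn
    m <- suppressMessages(mcc(list(tp = tp, tn = tn, fp = fp, fn = fn)))
    if (m > best$mcc) best <- list(threshold = th, mcc = m)
  }
  best
}

confusion_at <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores > threshold)
  confusion_counts(tp = sum(pred == 1L & labels == 1L),
                   tn = sum(pred == 0L & labels == 0L),
                   fp = sum(pred == 1L & labels == 0L),
                   fn = sum(pred == 0L & labels == 1L))
}
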