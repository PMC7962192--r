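# Evaluation: confusion counts, Sn/Sp/Acc/MCC, ROC/AUC, stratified
# cross-validation folds.

#' Confusion counts at a threshold
#'
#' A score greater than or equal to `threshold` is called positive (ties are
#' positive).
#'
#' @param scores Numeric probability scores.
#' @param labels Binary labels (0/1 or negative/positive).
#' @param threshold Decision threshold, default 0.5.
#' @return One-row tibble with columns `TP`, `FP`, `TN`, `FN`, `threshold`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) abort_fmt("confusion() needs at least one score")
  y <- as_label01(labels)
  if (length(scores) != length(y)) abort_fmt("scores and labels differ in length")
  pred <- scores >= threshold
  tibble::tibble(TP = sum(pred & y == 1L), FP = sum(pred & y == 0L),
                 TN = sum(!pred & y == 0L), FN = sum(!pred & y == 1L),
                 threshold = threshold)
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' accuracy `Acc = (TP + TN) / n`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. When any
#' marginal of the MCC denominator is zero the MCC is reported as 0 (the
#' standard convention) and `mcc_undefined` is flagged.
#'
#' @param counts One-row tibble (or list) with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble `Sn`, `Sp`, `Acc`, `MCC`, `mcc_undefined` plus the
#'   input counts.
#' @export
metrics_from_counts <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  n <- tp + fp + tn + fn
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  undef <- denom == 0
  mcc <- if (undef) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
                 Acc = (tp + tn) / n, MCC = mcc, mcc_undefined = undef,
                 TP = counts$TP, FP = counts$FP, TN = counts$TN,
                 FN = counts$FN)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic, i.e. the probability that a random
#' positive outscores a random negative (ties count one half); the curve is
#' the full threshold sweep, from which trapezoidal integration recovers the
#' same area.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return An `nts_roc` object: list with `curve` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label01(labels)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0 || nneg == 0) {
    abort_fmt("AUC needs both classes present (have %d pos, %d neg)",
              npos, nneg)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE)  # collapse tied thresholds
  tpr <- c(0, cumsum(ys == 1L)[last] / npos, 1)
  fpr <- c(0, cumsum(ys == 0L)[last] / nneg, 1)
  thr <- c(Inf, ss[last], -Inf)
  keep <- !duplicated(cbind(fpr, tpr))
  structure(list(curve = tibble::tibble(threshold = thr[keep],
                                        fpr = fpr[keep], tpr = tpr[keep]),
                 auc = auc),
            class = "nts_roc")
}

#' @export
print.nts_roc <- function(x, ...) {
  cat(sprintf("<nts_roc> AUC = %.4f (%d points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

# Trapezoidal area under an nts_roc curve; agrees with the Mann-Whitney AUC.
trapezoid_auc <- function(roc) {
  cv <- roc$curve
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}

#' Full metrics report for scored windows
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @return One-row tibble `Sn`, `Sp`, `Acc`, `MCC`, `AUC`, counts,
#'   `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  m <- metrics_from_counts(cm)
  m$AUC <- roc_auc(scores, labels)$auc
  m$threshold <- threshold
  m[, c("Sn", "Sp", "Acc", "MCC", "AUC", "TP", "FP", "TN", "FN",
        "threshold", "mcc_undefined")]
}

#' Threshold achieving a target specificity
#'
#' Returns the smallest threshold whose specificity on `scores`/`labels` is
#' at least `target_sp` — the fixed-specificity operating point used as an
#' alternative to the plain 0.5 cut.
#'
#' @param scores,labels As in [evaluate_scores()].
#' @param target_sp Target specificity, default 0.8.
#' @return A single threshold value.
#' @export
threshold_for_specificity <- function(scores, labels, target_sp = 0.8) {
  y <- as_label01(labels)
  neg <- sort(scores[y == 0L])
  if (length(neg) == 0) abort_fmt("no negatives to calibrate on")
  # Sp at threshold t is mean(neg < t); take the smallest score quantile
  # of the negatives that reaches the target.
  k <- ceiling(target_sp * length(neg))
  if (k >= length(neg)) return(max(neg) + 1e-9)
  (neg[k] + neg[k + 1]) / 2
}

# Stratified fold assignment: class proportions per fold differ from the
# global proportions by at most one sample.
make_folds <- function(labels, k, seed) {
  y <- as_label01(labels)
  if (any(table(y) < k)) {
    abort_fmt("each class needs at least %d samples for %d folds", k, k)
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
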