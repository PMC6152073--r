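#' Confusion counts from truth and prediction
#'
#' @param truth,pred 0/1 vectors of equal length; `truth` 1 marks a known
#'   interacting pair, `pred` 1 a pair predicted to interact.
#' @return list with non-negative integers `TP`, `FP`, `TN`, `FN` summing
#'   to the number of evaluated pairs.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("'truth' and 'pred' lengths differ")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1)) stop("labels must be 0/1")
  list(TP = sum(truth == 1L & pred == 1L),
       FP = sum(truth == 0L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Binary classification metrics as percentages
#'
#' Accuracy Ac = (TP+TN)/total, sensitivity (recall) Sn = TP/(TP+FN),
#' precision Pe = TP/(TP+FP), and the Matthews correlation coefficient
#' \deqn{Mcc = \frac{TP \cdot TN - FP \cdot FN}
#'  {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}},}
#' all reported as percentages (Mcc in [-100, 100]). A metric whose
#' denominator is zero is reported as `NA`.
#'
#' @param counts list with non-negative `TP`, `FP`, `TN`, `FN` (as from
#'   [confusion_counts()]).
#' @return named list with `Ac`, `Sn`, `Pe`, `Mcc`.
#' @export
compute_metrics <- function(counts) {
  v <- as.numeric(counts[c("TP", "FP", "TN", "FN")])
  if (anyNA(v)) stop("counts must contain TP, FP, TN, FN")
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  TP <- v[1]; FP <- v[2]; TN <- v[3]; FN <- v[4]
  total <- TP + FP + TN + FN
  denom_m <- (TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  list(Ac  = if (total > 0) 100 * (TP + TN) / total else NA_real_,
       Sn  = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       Pe  = if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_,
       Mcc = if (denom_m > 0) 100 * (TP * TN - FP * FN) / sqrt(denom_m)
             else NA_real_)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (tied scores are
#' grouped, so ties contribute diagonal ROC segments) and integrates the
#' curve by the trapezoidal rule. The resulting AUC equals the
#' Mann-Whitney statistic P(s+ > s-) + 0.5 P(s+ = s-).
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels 0/1 truth vector; both classes must be present.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`,
#'   starting at (0, 0) and ending at (1, 1)) and `auc` in [0, 1].
#' @export
roc_and_auc <- function(scores, labels) {
  scores <- as.numeric(scores); labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("'scores' and 'labels' lengths differ")
  if (!all(labels %in% 0:1)) stop("labels must be 0/1")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC requires both classes; got ", P, " positives and ", N, " negatives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)     # last index of each tie group
  tpr <- c(0, cumsum(y == 1L)[last] / P)
  fpr <- c(0, cumsum(y == 0L)[last] / N)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, s[last])),
       auc = auc)
}

#' Aggregate per-fold metric values
#'
#' Mean and sample standard deviation (n - 1 denominator) over fold-level
#' percentages, the convention used when reporting k-fold results as
#' "mean +/- sd".
#'
#' @param values numeric vector of per-fold metric values.
#' @return list with `mean` and `sd`.
#' @examples
#' aggregate_folds(c(97.95, 97.52, 97.26, 98.29, 97.61))
#' @export
aggregate_folds <- function(values) {
  values <- as.numeric(values)
  list(mean = mean(values, na.rm = TRUE), sd = stats::sd(values[!is.na(values)]))
}
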