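# Binary-classification metrics: accuracy, Matthews correlation
# coefficient, rank-based ROC AUC (ties counted one half) and the
# log-scaled AUC used to weigh early enrichment in virtual screening.

#' Confusion counts for binary labels
#'
#' @param labels true labels (0/1).
#' @param predicted predicted labels (0/1).
#' @return named vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  c(tp = sum(labels == 1 & predicted == 1),
    tn = sum(labels == 0 & predicted == 0),
    fp = sum(labels == 0 & predicted == 1),
    fn = sum(labels == 1 & predicted == 0))
}

mcc_from_counts <- function(tp, tn, fp, fn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)        # standard zero-denominator convention
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Rank-based ROC AUC
#'
#' Equals the probability that a uniformly random positive outscores a
#' uniformly random negative, with score ties counted one half
#' (Wilcoxon/Mann-Whitney form of the trapezoidal ROC area).
#'
#' @param labels true labels (0/1).
#' @param scores real-valued scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metric set
#'
#' @param labels true labels (0/1).
#' @param predicted predicted labels (0/1).
#' @param scores optional scores for AUC; when absent, AUC is computed from
#'   the predicted labels (a degenerate two-point ROC).
#' @return list of class `"metric_set"`: `tp`, `tn`, `fp`, `fn`, `acc`,
#'   `auc`, `mcc`. AUC is `NA` when only one class is present.
#' @export
compute_metrics <- function(labels, predicted, scores = NULL) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% c(0, 1)), all(predicted %in% c(0, 1)))
  cc <- confusion_counts(labels, predicted)
  n <- sum(cc)
  acc <- (cc[["tp"]] + cc[["tn"]]) / n
  auc <- auc_rank(labels, if (is.null(scores)) predicted else scores)
  mcc <- mcc_from_counts(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
  structure(list(tp = cc[["tp"]], tn = cc[["tn"]], fp = cc[["fp"]],
                 fn = cc[["fn"]], acc = acc, auc = auc, mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metrics: ACC %.3f | AUC %s | MCC %.3f (tp %d fp %d tn %d fn %d)>\n",
              x$acc, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$mcc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Logarithmic AUC (early-enrichment metric)
#'
#' Area under the ROC curve plotted against log10 of the false-positive
#' rate over `[fpr_floor, 1]`, normalized by the log range and expressed as
#' a percentage. The ROC is treated as piecewise linear between its
#' vertices and each segment is integrated analytically in log space. A
#' random scorer gives about `(1 - fpr_floor) / (-log(fpr_floor)) * 100`
#' (~14.47% at the default floor); a perfect scorer gives 100.
#'
#' @param labels true labels (0/1), both classes present.
#' @param scores real-valued scores, higher = more positive.
#' @param fpr_floor lower integration limit on the FPR axis (default 0.001,
#'   i.e. three decades).
#' @return LogAUC percentage in `[0, 100]`.
#' @export
log_auc <- function(labels, scores, fpr_floor = 0.001) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for LogAUC")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # ROC vertices at distinct thresholds
  idx <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(lab == 1)[idx] / n_pos)
  fpr <- c(0, cumsum(lab == 0)[idx] / n_neg)
  area <- 0
  for (s in seq_len(length(fpr) - 1L)) {
    f0 <- fpr[s]; f1 <- fpr[s + 1L]
    t0 <- tpr[s]; t1 <- tpr[s + 1L]
    if (f1 <= fpr_floor || f1 == f0) next
    if (f0 < fpr_floor) {
      t0 <- t0 + (t1 - t0) * (fpr_floor - f0) / (f1 - f0)
      f0 <- fpr_floor
    }
    b <- (t1 - t0) / (f1 - f0)
    a <- t0 - b * f0
    area <- area + a * log(f1 / f0) + b * (f1 - f0)
  }
  # clamp float residue at the boundaries
  min(max(area / (-log(fpr_floor)) * 100, 0), 100)
}
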