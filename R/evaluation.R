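# Evaluation: confusion counts, the seven scalar metrics, and ROC/AUC.
# Class 2 (malignant) is the positive class throughout (configurable).

#' Confusion counts for two-class predictions
#'
#' @param yTrue,yPred integer class codes in `{1, 2}`, equal length.
#' @param positive the positive class code (default 2, malignant).
#' @return named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(yTrue, yPred, positive = 2L) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (!all(c(yTrue, yPred) %in% c(1L, 2L)))
    stop("labels must be drawn from {1, 2}")
  pos <- yTrue == positive
  posHat <- yPred == positive
  c(TP = sum(pos & posHat), FP = sum(!pos & posHat),
    TN = sum(!pos & !posHat), FN = sum(pos & !posHat))
}

#' Scalar classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall of the positive class),
#' specificity, precision, Cohen's kappa (observed agreement corrected by the
#' chance agreement from the marginal products) and F1 (harmonic mean of
#' precision and sensitivity). Zero-denominator conventions: precision,
#' sensitivity and specificity are 0 when their denominator is 0; F1 is 0
#' when precision + sensitivity is 0; kappa is 0 when chance agreement is 1.
#' Any convention that fires is listed in the `warnings` attribute.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (total >= 1).
#' @return named list with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `kappa`, `f1` and attribute `warnings`.
#' @export
scalarMetrics <- function(counts) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(counts)))
    stop("counts must carry TP, FP, TN, FN")
  tp <- as.numeric(counts["TP"]); fp <- as.numeric(counts["FP"])
  tn <- as.numeric(counts["TN"]); fn <- as.numeric(counts["FN"])
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion counts")
  warn <- character(0)
  div <- function(num, den, what) {
    if (den == 0) { warn <<- c(warn, what); 0 } else num / den
  }
  accuracy <- (tp + tn) / n
  sensitivity <- div(tp, tp + fn, "sensitivity")
  specificity <- div(tn, tn + fp, "specificity")
  precision <- div(tp, tp + fp, "precision")
  po <- accuracy
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe == 1) { warn <- c(warn, "kappa"); 0 } else (po - pe) / (1 - pe)
  f1 <- if (precision + sensitivity == 0) { warn <- c(warn, "f1"); 0 } else
    2 * precision * sensitivity / (precision + sensitivity)
  out <- list(accuracy = accuracy, sensitivity = sensitivity,
              specificity = specificity, precision = precision,
              kappa = kappa, f1 = f1)
  attr(out, "warnings") <- warn
  out
}

#' ROC curve and AUC from class-2 probability scores
#'
#' Sweeps thresholds over the unique scores (ties grouped), yielding an
#' ordered `(FPR, TPR)` curve through `(0, 0)` and `(1, 1)`, and integrates
#' it with the trapezoidal rule. Equivalent to the Mann-Whitney pairwise
#' concordance with ties counted one half.
#'
#' @param yTrue integer class codes in `{1, 2}`; both classes must occur.
#' @param scores finite numeric scores (probability of the positive class).
#' @param positive the positive class code (default 2).
#' @return list with `curve` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
rocAuc <- function(yTrue, scores, positive = 2L) {
  if (length(yTrue) != length(scores))
    stop("yTrue and scores must have equal length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- yTrue == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0)
    stop("AUC is undefined unless both classes are present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tpGrp <- tapply(as.numeric(p), grp, sum)
  fpGrp <- tapply(as.numeric(!p), grp, sum)
  tpr <- c(0, cumsum(tpGrp) / nP)
  fpr <- c(0, cumsum(fpGrp) / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full metrics report from labels and scores
#'
#' Confusion counts plus the seven scalar metrics (accuracy, sensitivity,
#' specificity, precision, AUC, kappa, F1).
#'
#' @param yTrue true class codes in `{1, 2}`.
#' @param yPred predicted class codes.
#' @param scores optional class-2 probability scores; AUC is `NA` without
#'   them or when only one class occurs in `yTrue`.
#' @return named list with `counts` and the seven metrics.
#' @export
metricsReport <- function(yTrue, yPred, scores = NULL) {
  counts <- confusionCounts(yTrue, yPred)
  m <- scalarMetrics(counts)
  auc <- NA_real_
  if (!is.null(scores) && length(unique(yTrue)) == 2L)
    auc <- rocAuc(yTrue, scores)$auc
  c(list(counts = counts), m[c("accuracy", "sensitivity", "specificity",
                               "precision")], list(auc = auc),
    m[c("kappa", "f1")])
}
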