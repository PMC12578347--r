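# Multi-label evaluation: the five set-based metrics, micro-averaged F1 and
# MCC over label-instance pairs, and per-class ROC AUC.

#' Set-based multi-label metrics
#'
#' Precision, Coverage, Accuracy (Jaccard), Absolute true (exact-match rate)
#' and Absolute false (mean symmetric set difference normalized by the label
#' count) averaged over samples.
#'
#' Empty-set conventions: a term with zero denominator contributes 0, except
#' the intersection-over-union family when both sets are empty, which
#' contributes 1 (exact agreement).
#'
#' @param true_sets,pred_sets Lists of label subsets (character or integer),
#'   equal length.
#' @param M Size of the label space.
#' @return Named list: `precision`, `coverage`, `accuracy`, `absolute_true`,
#'   `absolute_false`.
#' @export
set_based_metrics <- function(true_sets, pred_sets, M) {
  stopifnot(length(true_sets) == length(pred_sets))
  n <- length(true_sets)
  prec <- cov <- acc <- atrue <- afalse <- numeric(n)
  for (i in seq_len(n)) {
    Li <- unique(true_sets[[i]])
    Pi <- unique(pred_sets[[i]])
    uni <- union(Li, Pi)
    if (length(uni) > M)
      stop("validation error: union of label sets exceeds label space size M")
    ni <- length(intersect(Li, Pi))
    prec[i] <- if (length(Pi)) ni / length(Pi) else 0
    cov[i] <- if (length(Li)) ni / length(Li) else 0
    acc[i] <- if (length(uni)) ni / length(uni) else 1
    atrue[i] <- as.numeric(setequal(Li, Pi))
    afalse[i] <- (length(uni) - ni) / M
  }
  list(precision = mean(prec), coverage = mean(cov), accuracy = mean(acc),
       absolute_true = mean(atrue), absolute_false = mean(afalse))
}

#' Micro-averaged F1 and Matthews correlation
#'
#' TP/FP/TN/FN are counted over all N x M label-instance pairs. A zero MCC
#' denominator yields 0 by convention.
#'
#' @param true_matrix,pred_matrix Binary matrices of equal shape.
#' @return Named list with `f1` and `mcc`.
#' @export
confusion_metrics <- function(true_matrix, pred_matrix) {
  stopifnot(all(dim(true_matrix) == dim(pred_matrix)))
  if (!all(true_matrix %in% c(0, 1)) || !all(pred_matrix %in% c(0, 1)))
    stop("validation error: matrices must be binary")
  tp <- sum(true_matrix == 1 & pred_matrix == 1)
  fp <- sum(true_matrix == 0 & pred_matrix == 1)
  tn <- sum(true_matrix == 0 & pred_matrix == 0)
  fn <- sum(true_matrix == 1 & pred_matrix == 0)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(f1 = f1, mcc = mcc)
}

#' Per-class ROC AUC
#'
#' Concordance (Mann-Whitney) formulation: the probability that a random
#' positive outscores a random negative, with ties counted 1/2 — equivalent
#' to trapezoidal integration of the ROC curve. Classes without both a
#' positive and a negative are reported as `NA` (undefined), not an error.
#'
#' @param true_matrix Binary matrix (N x M).
#' @param score_matrix Numeric score/probability matrix (N x M).
#' @return Numeric vector of per-class AUCs (named if columns are named).
#' @export
roc_auc_per_class <- function(true_matrix, score_matrix) {
  stopifnot(all(dim(true_matrix) == dim(score_matrix)))
  if (!all(is.finite(score_matrix))) stop("scores must be finite")
  vapply(seq_len(ncol(true_matrix)), function(j) {
    y <- true_matrix[, j]
    s <- score_matrix[, j]
    npos <- sum(y == 1); nneg <- sum(y == 0)
    if (npos == 0 || nneg == 0) return(NA_real_)
    r <- rank(s)
    (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }, numeric(1)) |>
    stats::setNames(colnames(true_matrix))
}

#' Full metric report
#'
#' @param true_matrix Binary truth matrix (N x M).
#' @param pred_matrix Binary prediction matrix (N x M).
#' @param score_matrix Optional probability matrix for per-class AUC.
#' @return A `pf_metric_report` list with the seven metrics (and `auc` when
#'   scores are given).
#' @export
metric_report <- function(true_matrix, pred_matrix, score_matrix = NULL) {
  sets_of <- function(m) apply(m, 1L, function(r) which(r == 1), simplify = FALSE)
  sb <- set_based_metrics(sets_of(true_matrix), sets_of(pred_matrix),
                          M = ncol(true_matrix))
  cm <- confusion_metrics(true_matrix, pred_matrix)
  rep <- c(sb, cm)
  if (!is.null(score_matrix)) rep$auc <- roc_auc_per_class(true_matrix, score_matrix)
  structure(rep, class = "pf_metric_report")
}

#' @export
print.pf_metric_report <- function(x, ...) {
  keys <- c("precision", "coverage", "accuracy", "absolute_true",
            "absolute_false", "f1", "mcc")
  for (k in keys) cat(sprintf("%-15s %.4f\n", k, x[[k]]))
  if (!is.null(x$auc))
    cat(sprintf("%-15s %.4f (mean over %d defined classes)\n", "auc",
                mean(x$auc, na.rm = TRUE), sum(!is.na(x$auc))))
  invisible(x)
}
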