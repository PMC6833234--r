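#' Sample-level classification metrics
#'
#' Computes the confusion counts and the derived ratios: sensitivity (recall)
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, precision `TP / (TP + FP)`,
#' F1 (harmonic mean of precision and recall) and the area under the ROC
#' curve. Ratios with a zero denominator are reported as `NA`, never 0.
#'
#' @param labels 0/1 vector of true labels.
#' @param predictions 0/1 vector of hard predictions.
#' @param scores Numeric vector of continuous scores for the positive class
#'   (used only for the AUC; may be `NULL` to skip it).
#' @return A list with `counts` (named TP/TN/FP/FN) and `metrics` (named
#'   sensitivity, specificity, precision, f1, auc).
#' @export
sample_metrics <- function(labels, predictions, scores = NULL) {
  if (length(labels) == 0L) stop("no samples to evaluate", call. = FALSE)
  stopifnot(length(predictions) == length(labels),
            is.null(scores) || length(scores) == length(labels))
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(labels, scores)
  list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    metrics = c(sensitivity = sens, specificity = spec, precision = prec,
                f1 = f1, auc = auc)
  )
}

#' ROC curve and trapezoidal AUC
#'
#' `roc_points()` returns the (FPR, TPR) operating points of the receiver
#' operating characteristic over all distinct score thresholds (ties grouped),
#' anchored at (0, 0) and (1, 1). `roc_auc()` integrates it by the trapezoidal
#' rule, which equals the rank statistic (probability that a random positive
#' outscores a random negative, ties counted 1/2).
#'
#' @param labels 0/1 vector of true labels.
#' @param scores Numeric scores, larger meaning more positive.
#' @return `roc_points()`: a data.frame with columns `fpr`, `tpr`.
#'   `roc_auc()`: the AUC, or `NA` when either class is absent.
#' @export
roc_points <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  P <- sum(lab == 1)
  N <- sum(lab == 0)
  if (P == 0L || N == 0L) {
    return(data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  }
  # cut after the last element of each tie group
  last_of_group <- c(diff(sc) != 0, TRUE)
  cum_tp <- cumsum(lab == 1)[last_of_group]
  cum_fp <- cumsum(lab == 0)[last_of_group]
  data.frame(fpr = c(0, cum_fp / N), tpr = c(0, cum_tp / P))
}

#' @rdname roc_points
#' @export
roc_auc <- function(labels, scores) {
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) return(NA_real_)
  pts <- roc_points(labels, scores)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}
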