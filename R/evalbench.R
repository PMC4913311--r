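# Fold-weighted benchmark evaluation: per-fold weights, weighted ROC curves
# and TPR at a fixed FPR, to assess template detection without compositional
# bias from large folds.

#' Per-member weights that equalize fold contributions
#'
#' Each member of a fold receives 1 / (fold size), so every fold contributes
#' the same total weight to the benchmark.
#'
#' @param fold_assignment named character/factor vector: member id -> fold.
#' @return named numeric weights.
#' @export
fold_weights <- function(fold_assignment) {
  sizes <- table(fold_assignment)
  w <- 1 / as.numeric(sizes[as.character(fold_assignment)])
  names(w) <- names(fold_assignment)
  w
}

#' Weighted ROC curve
#'
#' Sweeps the score threshold descending; at each distinct score, TPR is the
#' weight of positives at or above the threshold over the total positive
#' weight, FPR analogously for negatives.  Tied scores collapse into a
#' single step.  The curve starts at (0,0) and ends at (1,1); the area is
#' computed by the trapezoid rule.
#'
#' @param score numeric scores (higher = more confidently positive).
#' @param label 0/1 (or logical) same-fold labels.
#' @param weight positive per-item weights (default all 1).
#' @return object of class \code{weighted_roc}: \code{curve} (data.frame
#'   with \code{fpr}, \code{tpr}, \code{threshold}) and \code{auc}.
#' @export
weighted_roc <- function(score, label, weight = NULL) {
  label <- as.integer(label)
  if (is.null(weight)) weight <- rep(1, length(score))
  if (any(weight <= 0) || any(!is.finite(weight)))
    stop("weights must be finite and positive")
  if (!any(label == 1) || !any(label == 0))
    stop("need at least one positive and one negative item")
  ord <- order(-score)
  score <- score[ord]; label <- label[ord]; weight <- weight[ord]
  wp <- sum(weight[label == 1]); wn <- sum(weight[label == 0])
  # collapse tied scores into one step
  grp <- cumsum(!duplicated(score))
  tp <- tapply(weight * (label == 1), grp, sum)
  fp <- tapply(weight * (label == 0), grp, sum)
  tpr <- cumsum(tp) / wp
  fpr <- cumsum(fp) / wn
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, score[!duplicated(score)]))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "weighted_roc")
}

#' @export
print.weighted_roc <- function(x, ...) {
  cat(sprintf("weighted_roc: %d thresholds, AUC %.4f\n",
              nrow(x$curve) - 1, x$auc))
  invisible(x)
}

#' True positive rate at a fixed false positive rate
#'
#' Linear interpolation of the ROC curve at the requested FPR level.
#'
#' @param roc a [weighted_roc()] result, or a data.frame with \code{fpr} and
#'   \code{tpr} columns.
#' @param fpr_level target FPR (default 0.10).
#' @return interpolated TPR.
#' @export
tpr_at_fpr <- function(roc, fpr_level = 0.10) {
  curve <- if (inherits(roc, "weighted_roc")) roc$curve else roc
  stats::approx(curve$fpr, curve$tpr, xout = fpr_level, ties = max,
                rule = 2)$y
}
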