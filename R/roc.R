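#' ROC curve over labelled Divergence Index values
#'
#' Each observed DI serves as a candidate decision threshold: a comparison
#' is called a change when its DI is strictly greater than the threshold.
#' Sensitivity is the fraction of change (C) comparisons above the
#' threshold, specificity (repeatability) the fraction of no-change (NC)
#' comparisons at or below it. Sentinel thresholds below the minimum and
#' above the maximum complete the curve from (100, 100) to (0, 0) in
#' (100 - specificity, sensitivity) space; the area under the curve is
#' computed by the trapezoidal rule and equals the probability of ranking a
#' random C comparison above a random NC comparison (ties counted half).
#'
#' @param di numeric DI values, percent.
#' @param labels `"C"` / `"NC"` for each value.
#' @return object of class `roc_result`: `curve` (data.frame: threshold,
#'   sensitivity, specificity, youden, all in percent except youden in
#'   [-1, 1]), `auc` in [0, 1], `optimal_threshold`, `sensitivity`,
#'   `specificity`, `accuracy` at the optimum, `n_C`, `n_NC`.
#' @export
roc_curve <- function(di, labels) {
  if (length(di) != length(labels)) stop("di and labels lengths differ")
  labels <- as.character(labels)
  if (!all(labels %in% c("C", "NC"))) stop("labels must be 'C' or 'NC'")
  if (any(!is.finite(di))) stop("non-finite DI values")
  n_c <- sum(labels == "C")
  n_nc <- sum(labels == "NC")
  if (n_c == 0L || n_nc == 0L)
    stop("need at least one C and one NC comparison")
  di_c <- di[labels == "C"]
  di_nc <- di[labels == "NC"]

  thr <- c(-Inf, sort(unique(di)), Inf)
  sens <- vapply(thr, function(t) 100 * mean(di_c > t), numeric(1))
  spec <- vapply(thr, function(t) 100 * mean(di_nc <= t), numeric(1))
  youden <- (sens + spec) / 100 - 1
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, youden = youden)

  # thresholds ascend => FPR descends; integrate over ascending FPR
  fpr <- rev(1 - spec / 100)
  tpr <- rev(sens / 100)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  finite <- is.finite(thr)
  j_f <- youden[finite]
  t_f <- thr[finite]
  best <- which(j_f == max(j_f))[1]   # ties: lowest threshold, favors sensitivity
  opt <- t_f[best]
  tp <- sum(di_c > opt); tn <- sum(di_nc <= opt)
  structure(list(curve = curve, auc = auc,
                 optimal_threshold = opt,
                 sensitivity = sens[finite][best],
                 specificity = spec[finite][best],
                 accuracy = 100 * (tp + tn) / (n_c + n_nc),
                 n_C = n_c, n_NC = n_nc),
            class = "roc_result")
}

#' Youden-optimal operating point of an ROC result
#'
#' The optimal threshold maximizes the Youden index
#' (sensitivity + specificity - 1); among ties the lowest threshold is
#' returned (the strict "DI > threshold" rule then favors sensitivity).
#'
#' @param roc a [roc_curve()] result.
#' @return list: `threshold`, `sensitivity`, `specificity`, `accuracy`
#'   (percent at the optimum).
#' @export
youden_optimum <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(threshold = roc$optimal_threshold, sensitivity = roc$sensitivity,
       specificity = roc$specificity, accuracy = roc$accuracy)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy and Youden index from true/false
#' positive and negative counts of a change/no-change decision.
#'
#' @param tp,fn true positives and false negatives (C comparisons).
#' @param tn,fp true negatives and false positives (NC comparisons).
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent) and
#'   `youden` (in [-1, 1]).
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn > 0, tn + fp > 0)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
       youden = (sens + spec) / 100 - 1)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d C + %d NC comparisons, AUC = %.3f\n",
              x$n_C, x$n_NC, x$auc))
  cat(sprintf("  Youden-optimal DI threshold %.3g%%: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$optimal_threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Plot an ROC curve
#'
#' Sensitivity versus 100 - specificity with the chance diagonal and the
#' Youden-optimal operating point.
#'
#' @param x a [roc_curve()] result.
#' @param ... passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  with(x$curve, {
    plot(100 - specificity, sensitivity, type = "s",
         xlab = "100 - specificity (%)", ylab = "sensitivity (%)",
         xlim = c(0, 100), ylim = c(0, 100), ...)
  })
  graphics::abline(0, 1, lty = 2, col = "grey")
  i <- which(x$curve$threshold == x$optimal_threshold)[1]
  graphics::points(100 - x$curve$specificity[i], x$curve$sensitivity[i],
                   pch = 19)
  invisible(x)
}
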