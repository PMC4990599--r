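# Confusion-matrix metrics and empirical ROC analysis. Scores act as
# "stimulants": higher values indicate the positive (malignant) class.

.as_positive <- function(labels, positive) {
  if (length(labels) == 0) stop("`labels` must be non-empty", call. = FALSE)
  if (is.logical(labels)) return(labels)
  as.character(labels) == positive
}

#' Confusion table at a cutoff
#'
#' Counts true/false positives and negatives when scores at or above the
#' cutoff (the `">="` convention; see [classify()]) are called positive.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Class labels, same length as `scores`; either logical
#'   (`TRUE` = positive) or character/factor matched against `positive`.
#' @param cutoff Decision threshold on the score scale.
#' @param positive Label of the positive class (default `"malignant"`).
#' @param equality `"ge"` (default) or `"gt"` boundary convention.
#' @return Object of class `"confusion_table"`: a list with integer
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_at_cutoff(c(90, 10), c("malignant", "benign"), cutoff = 23.5)
confusion_at_cutoff <- function(scores, labels, cutoff,
                                positive = "malignant",
                                equality = c("ge", "gt")) {
  equality <- match.arg(equality)
  if (length(scores) != length(labels) || length(scores) == 0) {
    stop("`scores` and `labels` must have equal, nonzero length",
         call. = FALSE)
  }
  pos <- .as_positive(labels, positive)
  called <- if (equality == "ge") scores >= cutoff else scores > cutoff
  structure(
    list(tp = sum(called & pos), fp = sum(called & !pos),
         tn = sum(!called & !pos), fn = sum(!called & pos)),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(call = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), PPV = TP/(TP+FP),
#' NPV = TN/(FN+TN), each expressed in percent. A metric whose denominator
#' is zero is reported as `NA` (undefined, never 0) with a warning.
#'
#' @param table A `"confusion_table"` from [confusion_at_cutoff()], or any
#'   list with counts `tp`, `fp`, `tn`, `fn`.
#' @return Named list `sensitivity`, `specificity`, `ppv`, `npv`, in
#'   percent.
#' @export
#' @examples
#' confusion_metrics(list(tp = 3, fn = 1, tn = 8, fp = 2))
confusion_metrics <- function(table) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: empty denominator", call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  with(table, list(
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, fp + tn, "specificity"),
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, fn + tn, "NPV")
  ))
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold through every distinct score value
#' (tied scores are grouped at one threshold) and records the resulting
#' (false-positive rate, true-positive rate) pairs, anchored at (0,0) and
#' (1,1).
#'
#' @inheritParams confusion_at_cutoff
#' @return Object of class `"roc_result"`: list with `points` (data frame
#'   `fpr`, `tpr`, `threshold`; the anchors carry `Inf`/`-Inf`
#'   thresholds), `auc` (trapezoidal area, see [roc_auc()]), `n_pos`,
#'   `n_neg`, and the original `scores` and positive-class indicator
#'   `pos`.
#' @export
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' roc$auc
roc_curve <- function(scores, labels, positive = "malignant") {
  if (length(scores) != length(labels) || length(scores) == 0) {
    stop("`scores` and `labels` must have equal, nonzero length",
         call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  pos <- .as_positive(labels, positive)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC analysis needs at least one subject of each class",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores at a single threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last_of_group] / n_pos
  fpr <- cumsum(!p)[last_of_group] / n_neg
  points <- data.frame(
    fpr = c(0, fpr), tpr = c(0, tpr),
    threshold = c(Inf, s[last_of_group])
  )
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- rbind(points, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  res <- structure(
    list(points = points, n_pos = n_pos, n_neg = n_neg,
         scores = scores, pos = pos),
    class = "roc_result"
  )
  res$auc <- roc_auc(res)
  res
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area under the curve from [roc_curve()]. With tied scores
#' grouped at one threshold this equals the Mann-Whitney U statistic
#' scaled by `n_pos * n_neg`, ties counting one half: the probability that
#' a random positive subject outscores a random negative one.
#'
#' @param roc A `"roc_result"` from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  pts <- roc$points
  sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("Empirical ROC curve:", x$n_pos, "positive /", x$n_neg,
      "negative subjects\n")
  cat(sprintf("  AUC = %.4f", x$auc))
  if (!is.null(x$se_auc)) {
    cat(sprintf("  (DeLong SE = %.4f, 95%% CI %.4f-%.4f)",
                x$se_auc, x$ci_auc[1], x$ci_auc[2]))
  }
  cat("\n")
  invisible(x)
}

#' ROC-derived cutoff maximizing Youden's J
#'
#' Evaluates every achievable dichotomization (candidate cutoffs are the
#' midpoints between consecutive distinct scores, plus the all-positive
#' cut at the minimum score) and returns the one maximizing
#' J = sensitivity + specificity - 1. Ties in J are broken toward the
#' higher cutoff, i.e. toward higher specificity. For perfectly separated
#' classes this returns the midpoint of the separating gap.
#'
#' @inheritParams confusion_at_cutoff
#' @return List with `cutoff`, `youden_j`, `sensitivity`, `specificity`
#'   (the last two in percent).
#' @export
#' @examples
#' select_cutoff(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))$cutoff  # 6
select_cutoff <- function(scores, labels, positive = "malignant") {
  pos <- .as_positive(labels, positive)
  if (sum(pos) == 0 || sum(!pos) == 0) {
    stop("cutoff selection needs both classes", call. = FALSE)
  }
  u <- sort(unique(scores))
  candidates <- if (length(u) == 1) u else c(u[1], (u[-1] + u[-length(u)]) / 2)
  best <- NULL
  for (cut in candidates) {
    called <- scores >= cut
    sens <- sum(called & pos) / sum(pos)
    spec <- sum(!called & !pos) / sum(!pos)
    j <- sens + spec - 1
    # strict > keeps the later (higher, more specific) candidate on ties
    if (is.null(best) || j >= best$youden_j) {
      if (is.null(best) || j > best$youden_j || cut > best$cutoff) {
        best <- list(cutoff = cut, youden_j = j,
                     sensitivity = 100 * sens, specificity = 100 * spec)
      }
    }
  }
  best
}
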