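# DeLong nonparametric AUC variance and paired AUC comparison via
# placement values (structural components), using the midrank formulation.

# Placement values: v10[i] = P-hat(score of positive i beats a random
# negative), v01[j] = P-hat(a random positive beats negative j); ties 1/2.
.delong_placements <- function(scores, pos) {
  m <- sum(pos)
  n <- sum(!pos)
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[pos], ties.method = "average")
  r_neg <- rank(scores[!pos], ties.method = "average")
  v10 <- (r_all[pos] - r_pos) / n
  v01 <- 1 - (r_all[!pos] - r_neg) / m
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong standard error and confidence interval for an AUC
#'
#' Nonparametric variance of the empirical AUC from the placement-value
#' (structural component) estimator: `var = S10/m + S01/n` where `S10`,
#' `S01` are the sample variances of the positive- and negative-subject
#' placement values. The confidence interval is Wald on the AUC scale,
#' truncated to `[0, 1]`.
#'
#' @inheritParams confusion_at_cutoff
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `auc`, `se_auc`, and `ci_auc` (length-2 vector).
#' @export
#' @examples
#' set.seed(1)
#' s <- c(rnorm(30, 1), rnorm(30))
#' delong_variance(s, rep(c(TRUE, FALSE), each = 30))
delong_variance <- function(scores, labels, positive = "malignant",
                            conf_level = 0.95) {
  pos <- .as_positive(labels, positive)
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("DeLong variance needs at least 2 subjects per class",
         call. = FALSE)
  }
  pl <- .delong_placements(scores, pos)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = pl$auc, se_auc = se, ci_auc = ci)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both markers must be measured on the same subjects; the test accounts
#' for the correlation between the two empirical AUCs through the
#' covariance of their placement values. Two-sided p-value from the
#' standard normal. The sign of `z` matches the sign of
#' `auc_a - auc_b`.
#'
#' @param scores_a,scores_b Scores of the two markers, aligned to the
#'   same subjects.
#' @inheritParams confusion_at_cutoff
#' @return Object of class `"auc_comparison"`: list with `auc_a`,
#'   `auc_b`, `z`, `p`.
#' @export
#' @examples
#' set.seed(1)
#' lab <- rep(c(TRUE, FALSE), each = 40)
#' a <- rnorm(80, ifelse(lab, 1, 0))
#' delong_compare(a, a + rnorm(80, sd = 0.2), lab)
delong_compare <- function(scores_a, scores_b, labels,
                           positive = "malignant") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("`scores_a`, `scores_b` and `labels` must be aligned to the ",
         "same subjects", call. = FALSE)
  }
  pos <- .as_positive(labels, positive)
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("DeLong comparison needs at least 2 subjects per class",
         call. = FALSE)
  }
  pa <- .delong_placements(scores_a, pos)
  pb <- .delong_placements(scores_b, pos)
  d <- pa$auc - pb$auc
  v <- (stats::var(pa$v10) + stats::var(pb$v10) -
          2 * stats::cov(pa$v10, pb$v10)) / pa$m +
       (stats::var(pa$v01) + stats::var(pb$v01) -
          2 * stats::cov(pa$v01, pb$v01)) / pa$n
  if (v <= 0 || d == 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired DeLong AUC comparison: %.4f vs %.4f  (z = %.3f, p = %.4g)\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Full ROC analysis with DeLong uncertainty
#'
#' Convenience wrapper combining [roc_curve()] and [delong_variance()].
#'
#' @inheritParams delong_variance
#' @return A `"roc_result"` with `se_auc` and `ci_auc` filled in.
#' @export
roc_analysis <- function(scores, labels, positive = "malignant",
                         conf_level = 0.95) {
  roc <- roc_curve(scores, labels, positive)
  dl <- delong_variance(scores, labels, positive, conf_level)
  roc$se_auc <- dl$se_auc
  roc$ci_auc <- dl$ci_auc
  roc
}
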