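# Scoring pipeline: predictive index -> logistic risk percent -> cutoff
# classification, for both the age-stratified and the standard variant.

.check_markers <- function(he4, ca125) {
  if (any(!is.finite(he4)) || any(he4 <= 0) ||
      any(!is.finite(ca125)) || any(ca125 <= 0)) {
    stop("HE4 and CA125 must be positive and finite (logarithms must exist)",
         call. = FALSE)
  }
  # Values below assay detection limits are legitimate study data and are
  # scored as-is, but flagged once so the caller can review them.
  n_low <- sum(he4 < 15) + sum(ca125 < 1)
  if (n_low > 0) {
    warning(n_low, " marker value(s) below typical assay detection limits ",
            "(HE4 < 15 pmol/l or CA125 < 1 U/ml); scored without clamping",
            call. = FALSE)
  }
  invisible(TRUE)
}

#' Predictive index from serum markers
#'
#' Computes `PI = A + w_he4 * ln(HE4) + w_ca125 * ln(CA125)` with natural
#' logarithms. Vectorized over the marker values.
#'
#' @param he4 Serum HE4 in pmol/l; positive.
#' @param ca125 Serum CA125 in U/ml; positive.
#' @param coefficients A coefficient set as returned by
#'   [roma_coefficients()], or any list/vector with elements `A`, `w_he4`,
#'   `w_ca125`.
#' @return Numeric vector of predictive-index values.
#' @export
#' @examples
#' predictive_index(46.7, 22.5, roma_coefficients("W5"))
predictive_index <- function(he4, ca125, coefficients) {
  .check_markers(he4, ca125)
  cf <- as.list(coefficients)
  if (is.null(cf$A) || is.null(cf$w_he4) || is.null(cf$w_ca125)) {
    stop("`coefficients` must supply A, w_he4 and w_ca125", call. = FALSE)
  }
  cf$A + cf$w_he4 * log(he4) + cf$w_ca125 * log(ca125)
}

#' Logistic risk transform to the 0--100 scale
#'
#' Maps a predictive index to `exp(PI) / (1 + exp(PI)) * 100`, the
#' standard logistic risk in percent. Strictly increasing and bounded in
#' (0, 100) over the clinically reachable index range; computed via
#' [stats::plogis()], so arbitrarily large `|PI|` never overflows
#' (beyond `|PI|` of about 36 the value saturates at the 0/100 limit of
#' double precision).
#'
#' @param pi Predictive index; finite numeric vector.
#' @return Risk in percent, strictly inside (0, 100).
#' @export
#' @examples
#' risk_percent(0)        # 50
#' risk_percent(log(3))   # 75
risk_percent <- function(pi) {
  if (!is.numeric(pi) || length(pi) == 0 || any(!is.finite(pi))) {
    stop("`pi` must be finite numeric", call. = FALSE)
  }
  100 * stats::plogis(pi)
}

#' Age-stratified ROMA risk score
#'
#' Scores patients with the age-interval coefficient sets: the age selects
#' one of the eight strata, whose published coefficients feed the
#' predictive index and the logistic transform. Menopausal status plays no
#' role. Vectorized over parallel vectors.
#'
#' @param age Age in years; positive.
#' @param he4,ca125 Serum markers (pmol/l, U/ml); positive.
#' @return A data frame with columns `stratum` (label used), `pi`, and
#'   `percent` (risk on the 0--100 scale).
#' @export
#' @examples
#' score_roma_p(age = 55, he4 = 46.7, ca125 = 22.5)
score_roma_p <- function(age, he4, ca125) {
  n <- length(age)
  if (length(he4) != n || length(ca125) != n) {
    stop("`age`, `he4` and `ca125` must have equal length", call. = FALSE)
  }
  idx <- age_stratum(age)
  .check_markers(he4, ca125)
  tab <- .roma_p_table
  pi <- tab$A[idx] + tab$w_he4[idx] * log(he4) + tab$w_ca125[idx] * log(ca125)
  data.frame(stratum = tab$label[idx], pi = pi, percent = risk_percent(pi),
             stringsAsFactors = FALSE)
}

#' Standard menopause-dichotomized ROMA risk score
#'
#' Premenopausal patients are scored with the youngest-stratum (W1)
#' coefficient triple and postmenopausal patients with the oldest-stratum
#' (W8) triple; these equal the two endpoint sets of the age-stratified
#' construction, so a premenopausal patient aged 20 or less (and a
#' postmenopausal patient aged 81 or more) receives the same score under
#' both variants.
#'
#' @param menopausal_status Character vector of `"pre"` or `"post"`;
#'   `"unknown"` is an error (use [score_roma_p()], which needs no status).
#' @param he4,ca125 Serum markers (pmol/l, U/ml); positive.
#' @return A data frame with columns `group` (`"pre"`/`"post"`), `pi`, and
#'   `percent`.
#' @export
#' @examples
#' score_roma(menopausal_status = "pre", he4 = 46.7, ca125 = 22.5)
score_roma <- function(menopausal_status, he4, ca125) {
  n <- length(menopausal_status)
  if (length(he4) != n || length(ca125) != n) {
    stop("`menopausal_status`, `he4` and `ca125` must have equal length",
         call. = FALSE)
  }
  if (!all(menopausal_status %in% c("pre", "post"))) {
    stop("standard ROMA requires menopausal_status \"pre\" or \"post\"; ",
         "for unknown status use score_roma_p(), which is age-based",
         call. = FALSE)
  }
  .check_markers(he4, ca125)
  idx <- ifelse(menopausal_status == "pre", 1L, 8L)
  tab <- .roma_p_table
  pi <- tab$A[idx] + tab$w_he4[idx] * log(he4) + tab$w_ca125[idx] * log(ca125)
  data.frame(group = menopausal_status, pi = pi,
             percent = risk_percent(pi), stringsAsFactors = FALSE)
}

#' Dichotomize risk scores at a cutoff
#'
#' A score equal to the cutoff is classified high risk by default (the
#' `">="` convention, which favors sensitivity at the boundary); set
#' `equality = "gt"` for the strict convention.
#'
#' @param percent Risk scores on the 0--100 scale.
#' @param cutoff Cutoff in percent, strictly inside (0, 100). Default
#'   cutoffs in this package: 23.5 for the age-stratified score on the
#'   whole population; 14.1 (pre) / 25 (post) for the standard score.
#' @param equality `"ge"` (default) or `"gt"`: whether a score exactly at
#'   the cutoff is high risk.
#' @return Factor with levels `"low_risk"`, `"high_risk"`.
#' @export
#' @examples
#' classify(c(5, 23.5, 96.4), cutoff = 23.5)
classify <- function(percent, cutoff, equality = c("ge", "gt")) {
  equality <- match.arg(equality)
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      !is.finite(cutoff) || cutoff <= 0 || cutoff >= 100) {
    stop("`cutoff` must be a single value strictly inside (0, 100)",
         call. = FALSE)
  }
  high <- if (equality == "ge") percent >= cutoff else percent > cutoff
  factor(ifelse(high, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Default cutoffs for the two ROMA variants
#'
#' The age-stratified score uses a single cutoff for the entire
#' population; the standard score uses separate pre- and post-menopausal
#' cutoffs.
#'
#' @return Named list: `roma_p` (23.5), `roma_pre` (14.1),
#'   `roma_post` (25).
#' @export
roma_cutoffs <- function() {
  list(roma_p = 23.5, roma_pre = 14.1, roma_post = 25)
}

#' Score a cohort with one or both ROMA variants
#'
#' Batch interface over a cohort data frame. Adds, per selected variant,
#' the predictive index, the risk percent, the stratum or group used, and
#' the cutoff classification.
#'
#' @param cohort Data frame with columns `age`, `he4`, `ca125` and, for
#'   the standard variant, `menopausal_status` (`"pre"`/`"post"`;
#'   `"unknown"` rows get `NA` standard-ROMA scores with a warning).
#' @param algorithm `"both"` (default), `"roma_p"` or `"roma"`.
#' @param cutoffs Named list as from [roma_cutoffs()].
#' @param equality Cutoff equality convention, see [classify()].
#' @return The input data frame with columns appended: `stratum`,
#'   `roma_p_pi`, `roma_p_percent`, `roma_p_class` and/or `roma_pi`,
#'   `roma_percent`, `roma_class`.
#' @export
#' @examples
#' cohort <- data.frame(age = c(35, 62), menopausal_status = c("pre", "post"),
#'                      he4 = c(40, 300), ca125 = c(20, 150))
#' roma_score(cohort)
roma_score <- function(cohort, algorithm = c("both", "roma_p", "roma"),
                       cutoffs = roma_cutoffs(), equality = "ge") {
  algorithm <- match.arg(algorithm)
  need <- c("age", "he4", "ca125")
  if (algorithm != "roma_p") need <- c(need, "menopausal_status")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- cohort
  if (algorithm %in% c("both", "roma_p")) {
    sp <- score_roma_p(cohort$age, cohort$he4, cohort$ca125)
    out$stratum <- sp$stratum
    out$roma_p_pi <- sp$pi
    out$roma_p_percent <- sp$percent
    out$roma_p_class <- classify(sp$percent, cutoffs$roma_p, equality)
  }
  if (algorithm %in% c("both", "roma")) {
    status <- as.character(cohort$menopausal_status)
    known <- status %in% c("pre", "post")
    if (!all(known)) {
      warning(sum(!known), " patient(s) with unknown menopausal status: ",
              "standard ROMA set to NA for them", call. = FALSE)
    }
    out$roma_pi <- out$roma_percent <- rep(NA_real_, nrow(cohort))
    out$roma_class <- factor(rep(NA_character_, nrow(cohort)),
                             levels = c("low_risk", "high_risk"))
    if (any(known)) {
      ss <- score_roma(status[known], cohort$he4[known], cohort$ca125[known])
      out$roma_pi[known] <- ss$pi
      out$roma_percent[known] <- ss$percent
      cut_i <- ifelse(status[known] == "pre", cutoffs$roma_pre,
                      cutoffs$roma_post)
      high <- if (equality == "ge") ss$percent >= cut_i else ss$percent > cut_i
      out$roma_class[known] <- ifelse(high, "high_risk", "low_risk")
    }
  }
  out
}
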