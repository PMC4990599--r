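# Published coefficient triples for the eight age strata. These are the
# printed constants; they are never re-derived at scoring time (the printed
# table mixes rounding and truncation, so interpolation only *verifies* it).
.roma_p_table <- data.frame(
  index   = 1:8,
  label   = paste0("W", 1:8),
  age_low = c(1, 21, 31, 41, 51, 61, 71, 81),
  age_high = c(20, 30, 40, 50, 60, 70, 80, Inf),
  A       = c(-12, -11.44, -10.88, -10.32, -9.77, -9.21, -8.65, -8.09),
  w_he4   = c(2.38, 2.19, 2.00, 1.81, 1.61, 1.42, 1.23, 1.04),
  w_ca125 = c(0.063, 0.158, 0.254, 0.349, 0.445, 0.541, 0.636, 0.732),
  stringsAsFactors = FALSE
)

#' Age strata and coefficient table for the age-stratified ROMA
#'
#' Returns the eight age intervals (W1--W8) with their intercept and
#' log-marker coefficients. The strata partition all positive ages:
#' W1 covers ages up to 20, W2--W7 are closed ten-year decades
#' (21--30, ..., 71--80) and W8 is open-ended from 81 upwards.
#'
#' @return A data frame with columns `index`, `label`, `age_low`,
#'   `age_high`, `A`, `w_he4`, `w_ca125`.
#' @export
#' @examples
#' roma_strata()
roma_strata <- function() {
  .roma_p_table
}

#' Map an age to its ROMA age stratum
#'
#' Fractional ages are floored to whole years before lookup, so age 20.9
#' falls in W1 and age 80.5 in W7. Vectorized.
#'
#' @param age Age in years; positive and finite.
#' @return Integer vector of stratum indices (1--8).
#' @export
#' @examples
#' age_stratum(c(18, 45, 81))  # 1, 4, 8
age_stratum <- function(age) {
  if (!is.numeric(age) || length(age) == 0) {
    stop("`age` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("all ages must be positive and finite", call. = FALSE)
  }
  a <- floor(age)
  idx <- ifelse(a <= 20, 1L, ifelse(a >= 81, 8L, (a - 21L) %/% 10L + 2L))
  as.integer(idx)
}

#' Coefficient set for an age stratum or menopausal group
#'
#' Returns the published intercept and log-marker weights. The standard
#' (menopause-dichotomized) ROMA uses the two endpoint sets: `"pre"` is
#' the W1 triple and `"post"` the W8 triple.
#'
#' @param stratum Stratum index 1--8, a label `"W1"`..`"W8"`, or a
#'   menopausal group `"pre"`/`"post"`.
#' @return A one-row data frame with columns `label`, `A`, `w_he4`,
#'   `w_ca125`.
#' @export
#' @examples
#' roma_coefficients(5)       # W5: A = -9.77, w_he4 = 1.61, w_ca125 = 0.445
#' roma_coefficients("pre")   # same as W1
roma_coefficients <- function(stratum) {
  if (length(stratum) != 1L) {
    stop("`stratum` must be a single index, label, or group", call. = FALSE)
  }
  if (is.character(stratum)) {
    key <- switch(stratum, pre = "W1", post = "W8", stratum)
    i <- match(key, .roma_p_table$label)
  } else {
    i <- match(as.integer(stratum), .roma_p_table$index)
  }
  if (is.na(i)) {
    stop("unknown stratum: ", stratum,
         " (expected 1..8, \"W1\"..\"W8\", \"pre\" or \"post\")",
         call. = FALSE)
  }
  .roma_p_table[i, c("label", "A", "w_he4", "w_ca125")]
}

#' Linear stepwise interpolation between two coefficient sets
#'
#' Constructs `n_strata` coefficient triples stepping component-wise from
#' the youngest-stratum endpoint to the oldest-stratum endpoint in
#' `n_strata - 1` equal increments. With the published endpoints and eight
#' strata this reconstruction matches the published coefficient table to
#' within 0.001 per component (the published values are rounded or
#' truncated to 2--3 decimals). It is a construction/verification tool;
#' scoring always uses the published constants via [roma_coefficients()].
#'
#' @param young Named numeric vector or list with elements `A`, `w_he4`,
#'   `w_ca125`: the youngest-stratum endpoint.
#' @param old Same structure: the oldest-stratum endpoint.
#' @param n_strata Number of strata to generate; at least 2.
#' @return A data frame with `n_strata` rows and columns `A`, `w_he4`,
#'   `w_ca125`.
#' @export
#' @examples
#' interpolate_coefficients(
#'   young = c(A = -12, w_he4 = 2.38, w_ca125 = 0.063),
#'   old   = c(A = -8.09, w_he4 = 1.04, w_ca125 = 0.732),
#'   n_strata = 8
#' )
interpolate_coefficients <- function(young, old, n_strata = 8L) {
  if (!is.numeric(n_strata) || length(n_strata) != 1L || n_strata < 2) {
    stop("`n_strata` must be a single integer >= 2", call. = FALSE)
  }
  comp <- c("A", "w_he4", "w_ca125")
  young <- unlist(young)[comp]
  old <- unlist(old)[comp]
  if (any(is.na(young)) || any(is.na(old))) {
    stop("endpoints must supply numeric A, w_he4 and w_ca125", call. = FALSE)
  }
  steps <- seq(0, 1, length.out = n_strata)
  out <- as.data.frame(
    lapply(comp, function(k) young[[k]] + steps * (old[[k]] - young[[k]]))
  )
  names(out) <- comp
  out
}
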