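# Seeded synthetic-cohort generator. Emulates the age and marker
# structure of a gynecological referral population: a benign majority
# skewed young, a malignant group skewed old, log-normal HE4/CA125 per
# (class, stratum) cell, and benign HE4 rising with age.

# Per-stratum marker calibration: medians and min-max ranges observed in
# a 413-patient referral cohort (162 malignant / 251 benign). Dispersion
# of the log-normal is set by matching the printed min-max to the central
# 99% mass: sdlog = (log(max) - log(min)) / (2 * qnorm(0.995)).
# The malignant W1 cell is empty (weight 0); the benign W8 cell has one
# patient and no printed marker row, so it reuses the W7 parameters.
.marker_calibration <- function() {
  z99 <- 2 * stats::qnorm(0.995)
  sdlog <- function(lo, hi) (log(hi) - log(lo)) / z99
  benign <- data.frame(
    class = "benign", stratum = 1:8,
    ca125_median = c(16, 28.1, 32.3, 21.6, 12.4, 15.9, 9.55, 9.55),
    ca125_sdlog = sdlog(c(4.1, 7.7, 7.1, 5.5, 3.2, 6.7, 6.3, 6.3),
                        c(274.8, 377, 191.5, 168.8, 82.1, 79.8, 52.7, 52.7)),
    he4_median = c(41.5, 45.5, 47.3, 44.5, 48.5, 63.8, 69.5, 69.5),
    he4_sdlog = sdlog(c(24.2, 26.3, 31.7, 17.8, 27.5, 47.1, 52, 52),
                      c(84.7, 80.4, 86.7, 74.2, 85.1, 206.5, 186, 186)),
    stringsAsFactors = FALSE
  )
  malignant <- data.frame(
    class = "malignant", stratum = 1:8,
    ca125_median = c(NA, 55.2, 403.6, 265.4, 500, 233.3, 839, 777.5),
    ca125_sdlog = c(NA, sdlog(c(27, 98.1, 14, 9, 9.8, 21, 66.9),
                              c(135.1, 1252, 4638.8, 5887, 7459.1, 5659,
                                3724))),
    he4_median = c(NA, 45.4, 95.4, 92.9, 439.3, 334.5, 658.4, 871.2),
    he4_sdlog = c(NA, sdlog(c(44.1, 15, 15, 12, 22, 37, 85.8),
                            c(103.9, 464.8, 1500, 1655, 9264, 8160, 4940))),
    stringsAsFactors = FALSE
  )
  rbind(benign, malignant)
}

#' Specification of a synthetic cohort
#'
#' Bundles the generative parameters: group sizes, per-stratum age
#' weights for each class, per-(class, stratum) log-normal marker
#' parameters, an optional extra age trend for benign HE4, and the RNG
#' seed.
#'
#' @param n_malignant,n_benign Group sizes (non-negative integers).
#' @param age_weights Named list with numeric vectors `malignant` and
#'   `benign` of length 8: per-stratum proportions (normalized
#'   internally; a zero weight empties the cell).
#' @param marker_params Data frame with columns `class`, `stratum`,
#'   `ca125_median`, `ca125_sdlog`, `he4_median`, `he4_sdlog`, one row
#'   per (class, stratum) cell with nonzero weight.
#' @param he4_age_drift Extra multiplicative trend of benign HE4 with
#'   age: the benign HE4 median in stratum k is multiplied by
#'   `(1 + he4_age_drift)^(k - 1)`. Default 0 because the default
#'   per-stratum medians already embed the observed age rise.
#' @param menopause_age Age at and above which status is `"post"`
#'   (default 51).
#' @param seed RNG seed used by [generate_cohort()]; `NULL` leaves the
#'   RNG state untouched.
#' @return Object of class `"cohort_spec"`.
#' @seealso [default_cohort_spec()] for the calibrated defaults.
#' @export
cohort_spec <- function(n_malignant, n_benign, age_weights, marker_params,
                        he4_age_drift = 0, menopause_age = 51,
                        seed = NULL) {
  stopifnot(n_malignant >= 0, n_benign >= 0)
  for (cl in c("malignant", "benign")) {
    w <- age_weights[[cl]]
    if (is.null(w) || length(w) != 8 || any(w < 0) || sum(w) <= 0) {
      stop("age_weights$", cl, " must be 8 non-negative proportions with ",
           "positive sum", call. = FALSE)
    }
    age_weights[[cl]] <- w / sum(w)
  }
  need <- c("class", "stratum", "ca125_median", "ca125_sdlog",
            "he4_median", "he4_sdlog")
  if (!all(need %in% names(marker_params))) {
    stop("marker_params must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  active <- !is.na(marker_params$he4_median)
  if (any(marker_params$he4_sdlog[active] <= 0, na.rm = TRUE) ||
      any(marker_params$ca125_sdlog[active] <= 0, na.rm = TRUE)) {
    stop("marker scale parameters must be positive", call. = FALSE)
  }
  structure(
    list(n_malignant = as.integer(n_malignant),
         n_benign = as.integer(n_benign),
         age_weights = age_weights, marker_params = marker_params,
         he4_age_drift = he4_age_drift, menopause_age = menopause_age,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Default synthetic-cohort specification
#'
#' Calibrated to the structure of a 413-patient referral cohort:
#' 162 malignant / 251 benign; stratum weights proportional to the
#' per-age-interval counts (malignant 0, 3, 7, 28, 47, 43, 25, 9;
#' benign 38, 55, 73, 48, 22, 10, 4, 1 for W1--W8); log-normal markers
#' with per-(class, stratum) medians (e.g. benign HE4 46.7 pmol/l and
#' malignant CA125 397.5 U/ml overall) whose benign-HE4 medians rise
#' roughly 40% or more from the youngest to the oldest strata.
#'
#' @inheritParams cohort_spec
#' @return A `"cohort_spec"`.
#' @export
#' @examples
#' spec <- default_cohort_spec(seed = 1)
#' cohort <- generate_cohort(spec)
#' table(cohort$label)
default_cohort_spec <- function(seed = NULL) {
  cohort_spec(
    n_malignant = 162L,
    n_benign = 251L,
    age_weights = list(
      malignant = c(0, 3, 7, 28, 47, 43, 25, 9),
      benign = c(38, 55, 73, 48, 22, 10, 4, 1)
    ),
    marker_params = .marker_calibration(),
    he4_age_drift = 0,
    menopause_age = 51,
    seed = seed
  )
}

# sampling bounds per stratum: open-ended W1 and W8 get finite limits
# compatible with the emulated cohort's age range (18-90)
.age_bounds <- cbind(low = c(16, 21, 31, 41, 51, 61, 71, 81),
                     high = c(21, 31, 41, 51, 61, 71, 81, 91))

#' Generate a synthetic cohort
#'
#' Draws a cohort deterministically for a fixed `spec$seed`: each
#' patient's stratum is sampled from the class's stratum weights, the age
#' uniformly within the stratum, and HE4/CA125 log-normally with the
#' (class, stratum) parameters. Menopausal status is `"post"` if and only
#' if age is at least `spec$menopause_age`.
#'
#' @param spec A `"cohort_spec"`, e.g. from [default_cohort_spec()].
#' @return Data frame with columns `id`, `age`, `menopausal_status`,
#'   `he4`, `ca125`, `label`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec", call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  one_class <- function(cl, n) {
    if (n == 0) return(NULL)
    w <- spec$age_weights[[cl]]
    mp <- spec$marker_params[spec$marker_params$class == cl, ]
    mp <- mp[order(mp$stratum), ]
    idx <- sample.int(8L, n, replace = TRUE, prob = w)
    if (any(is.na(mp$he4_median[idx]))) {
      stop("marker parameters missing for a (", cl, ", stratum) cell with ",
           "positive weight", call. = FALSE)
    }
    age <- stats::runif(n, .age_bounds[idx, "low"], .age_bounds[idx, "high"])
    he4_mu <- log(mp$he4_median[idx])
    if (cl == "benign" && spec$he4_age_drift != 0) {
      he4_mu <- he4_mu + (idx - 1) * log1p(spec$he4_age_drift)
    }
    data.frame(
      age = age,
      menopausal_status = ifelse(age >= spec$menopause_age, "post", "pre"),
      he4 = stats::rlnorm(n, he4_mu, mp$he4_sdlog[idx]),
      ca125 = stats::rlnorm(n, log(mp$ca125_median[idx]),
                            mp$ca125_sdlog[idx]),
      label = cl,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_class("malignant", spec$n_malignant),
               one_class("benign", spec$n_benign))
  if (is.null(out)) {
    stop("cohort spec generates no patients", call. = FALSE)
  }
  out <- cbind(id = sprintf("P%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
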