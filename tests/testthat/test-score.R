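test_that("predictive index is the linear log-marker combination", {
  expect_equal(suppressWarnings(
    predictive_index(exp(1), 1, list(A = 0, w_he4 = 1, w_ca125 = 1))), 1)
  expect_equal(predictive_index(123, 456, list(A = 0, w_he4 = 0,
                                               w_ca125 = 0)), 0)
  # benign-group median markers under the W5 coefficients, by direct
  # arithmetic
  expect_equal(predictive_index(46.7, 22.5, roma_coefficients("W5")),
               -9.77 + 1.61 * log(46.7) + 0.445 * log(22.5))
  expect_error(predictive_index(-1, 10, roma_coefficients(1)), "positive")
  expect_error(predictive_index(10, 0, roma_coefficients(1)), "positive")
  expect_error(suppressWarnings(predictive_index(10, 10, list(A = 1))),
               "coefficients")
})

test_that("logistic transform hits its landmarks and stays stable", {
  expect_identical(risk_percent(0), 50)
  expect_equal(risk_percent(log(3)), 75)
  # no overflow at extreme indices: finite values pinned to the limits
  # (beyond |pi| of about 36 the logistic saturates in double precision)
  extremes <- risk_percent(c(-700, 700))
  expect_true(all(is.finite(extremes)))
  expect_gt(extremes[1], 0)
  expect_lte(extremes[2], 100)
  expect_equal(extremes, c(0, 100), tolerance = 1e-12)
  # strictly increasing over a wide grid
  grid <- risk_percent(seq(-30, 30, length.out = 500))
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid > 0 & grid < 100))
  expect_error(risk_percent(Inf), "finite")
  expect_error(risk_percent(NA_real_), "finite")
})

test_that("age-stratified scoring composes stratum lookup, index and logistic", {
  s <- score_roma_p(55, 46.7, 22.5)
  expect_equal(s$stratum, "W5")
  pi_manual <- predictive_index(46.7, 22.5, roma_coefficients("W5"))
  expect_equal(s$pi, pi_manual)
  expect_equal(s$percent, risk_percent(pi_manual))
  # monotone in each marker
  expect_gt(score_roma_p(55, 2 * 46.7, 22.5)$percent, s$percent)
  expect_gt(score_roma_p(55, 46.7, 2 * 22.5)$percent, s$percent)
  # stratum dependence: same markers, different ages, different scores
  expect_false(score_roma_p(19, 100, 50)$percent ==
                 score_roma_p(85, 100, 50)$percent)
})

test_that("scores stay strictly inside (0, 100) and rise with each marker", {
  he4 <- exp(seq(log(5), log(5000), length.out = 100))
  ca125 <- exp(seq(log(1), log(8000), length.out = 100))
  for (k in 1:8) {
    cf <- roma_coefficients(k)
    # the grid deliberately dips below the assay detection limits
    fix_ca <- risk_percent(suppressWarnings(
      predictive_index(he4, rep(35, 100), cf)))
    fix_he <- risk_percent(suppressWarnings(
      predictive_index(rep(60, 100), ca125, cf)))
    expect_true(all(diff(fix_ca) > 0), info = paste("he4 monotone, stratum", k))
    expect_true(all(diff(fix_he) > 0), info = paste("ca125 monotone, stratum", k))
    expect_true(all(c(fix_ca, fix_he) > 0 & c(fix_ca, fix_he) < 100))
  }
})

test_that("standard scorer uses the endpoint triples and demands a status", {
  pre <- score_roma("pre", 46.7, 22.5)
  expect_equal(pre$pi, -12 + 2.38 * log(46.7) + 0.063 * log(22.5))
  post <- score_roma("post", 46.7, 22.5)
  expect_false(pre$percent == post$percent)
  expect_error(score_roma("unknown", 46.7, 22.5), "pre.*post|status")
  # endpoint agreement with the age-stratified scorer
  expect_equal(score_roma("pre", 80, 40)$percent,
               score_roma_p(19, 80, 40)$percent)
  expect_equal(score_roma("post", 80, 40)$percent,
               score_roma_p(85, 80, 40)$percent)
})

test_that("cutoff classification follows the >= convention and validates", {
  cl <- classify(c(5, 23.5, 96.4), cutoff = 23.5)
  expect_equal(as.character(cl), c("low_risk", "high_risk", "high_risk"))
  expect_equal(as.character(classify(23.5, 23.5, equality = "gt")),
               "low_risk")
  expect_error(classify(50, 0), "cutoff")
  expect_error(classify(50, 100), "cutoff")
})

test_that("batch scoring augments the cohort and handles unknown status", {
  cohort <- data.frame(
    age = c(35, 62, 48),
    menopausal_status = c("pre", "post", "unknown"),
    he4 = c(40, 300, 55), ca125 = c(20, 150, 30)
  )
  expect_warning(scored <- roma_score(cohort), "unknown menopausal status")
  expect_true(all(c("stratum", "roma_p_pi", "roma_p_percent", "roma_p_class",
                    "roma_pi", "roma_percent", "roma_class") %in%
                    names(scored)))
  expect_true(is.na(scored$roma_percent[3]))
  expect_false(anyNA(scored$roma_p_percent))
  expect_equal(scored$roma_p_percent[1],
               score_roma_p(35, 40, 20)$percent)
  expect_error(roma_score(cohort[, -1]), "missing column")
})

test_that("sub-detection marker values are flagged but scored unclamped", {
  expect_warning(s <- score_roma_p(30, 12, 20), "detection")
  expect_equal(s$pi, suppressWarnings(
    predictive_index(12, 20, roma_coefficients(2))))
})
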