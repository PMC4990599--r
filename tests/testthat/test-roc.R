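test_that("confusion counts match an explicit counting loop", {
  tab <- confusion_at_cutoff(c(90, 10), c("malignant", "benign"), 23.5)
  expect_equal(unclass(tab)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  # all positive above cutoff leaves no negatives anywhere
  all_pos <- confusion_at_cutoff(c(80, 95), c(TRUE, TRUE), 23.5)
  expect_equal(all_pos$fp + all_pos$tn, 0L)
  set.seed(11)
  for (rep in 1:5) {
    scores <- round(runif(100, 0, 100), 1)
    pos <- runif(100) < 0.4
    cutoff <- runif(1, 0, 100)
    got <- confusion_at_cutoff(scores, pos, cutoff)
    want <- loop_confusion(scores, pos, cutoff)
    expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]), want)
  }
  expect_error(confusion_at_cutoff(1:3, c(TRUE, FALSE), 1), "equal")
})

test_that("metrics follow their contingency-table definitions", {
  perfect <- confusion_metrics(list(tp = 10, fn = 0, tn = 5, fp = 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  m <- confusion_metrics(list(tp = 3, fn = 1, tn = 8, fp = 2))
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 80)
  expect_equal(m$ppv, 60)
  expect_equal(m$npv, 100 * 8 / 9)
  # undefined, not zero, on an empty class
  expect_warning(u <- confusion_metrics(list(tp = 0, fn = 0, tn = 3, fp = 1)),
                 "sensitivity undefined")
  expect_true(is.na(u$sensitivity))
  expect_false(is.na(u$specificity))
  # duplicating the data leaves every rate unchanged
  m2 <- confusion_metrics(list(tp = 6, fn = 2, tn = 16, fp = 4))
  expect_equal(m, m2)
})

test_that("empirical ROC curve is anchored, monotone and tie-grouped", {
  roc <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points[nrow(roc$points), c("fpr", "tpr")],
               data.frame(fpr = 1, tpr = 1), ignore_attr = TRUE)
  # perfect separation passes through (0, 1)
  expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 1))
  expect_equal(roc$auc, 1)
  # fully tied scores collapse to the diagonal: AUC one half
  expect_equal(roc_curve(rep(7, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "each class")
  set.seed(21)
  for (rep in 1:20) {
    inst <- random_instance(sample(2:15, 1), sample(2:15, 1),
                            ties = rep %% 2 == 0)
    pts <- roc_curve(inst$scores, inst$pos)$points
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  }
})

test_that("trapezoidal AUC equals the exhaustive pair-count statistic", {
  set.seed(31)
  for (rep in 1:50) {
    inst <- random_instance(sample(2:15, 1), sample(2:15, 1),
                            ties = rep %% 2 == 0)
    auc <- roc_curve(inst$scores, inst$pos)$auc
    expect_equal(auc, pair_count_auc(inst$scores, inst$pos),
                 tolerance = 1e-12)
    # reversing the score orientation mirrors the AUC
    expect_equal(roc_curve(-inst$scores, inst$pos)$auc, 1 - auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (rep in 1:10) {
    inst <- random_instance(20, 25, ties = rep %% 2 == 0)
    ours <- roc_curve(inst$scores, inst$pos)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = inst$pos, predictor = inst$scores,
      direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("selected cutoff maximizes Youden's J", {
  # perfect separation: midpoint of the separating gap
  sel <- select_cutoff(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sel$cutoff, 6)
  expect_equal(sel$youden_j, 1)
  # useless marker: J is zero
  expect_equal(select_cutoff(rep(3, 8), rep(c(TRUE, FALSE), 4))$youden_j, 0)
  set.seed(51)
  for (rep in 1:30) {
    inst <- random_instance(sample(3:20, 1), sample(3:20, 1),
                            ties = rep %% 2 == 0)
    sel <- select_cutoff(inst$scores, inst$pos)
    expect_equal(sel$youden_j, best_youden_j(inst$scores, inst$pos),
                 tolerance = 1e-12)
    # the reported operating point reproduces J
    expect_equal(sel$youden_j,
                 (sel$sensitivity + sel$specificity) / 100 - 1,
                 tolerance = 1e-12)
  }
})
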