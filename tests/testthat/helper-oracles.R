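# Independent brute-force oracles used across the diagnostics tests.

# AUC as the exhaustive pair-count U-statistic: fraction of
# (positive, negative) pairs where the positive outscores the negative,
# ties counting one half.
pair_count_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

# Confusion counts by explicit looping (>= convention).
loop_confusion <- function(scores, pos, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    called <- scores[i] >= cutoff
    if (called && pos[i]) tp <- tp + 1L
    if (called && !pos[i]) fp <- fp + 1L
    if (!called && !pos[i]) tn <- tn + 1L
    if (!called && pos[i]) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Best achievable Youden J over an exhaustive sweep of every distinct
# score as a >= threshold (plus the all-positive cut).
best_youden_j <- function(scores, pos) {
  thresholds <- sort(unique(scores))
  best <- -Inf
  for (t in thresholds) {
    called <- scores >= t
    j <- sum(called & pos) / sum(pos) + sum(!called & !pos) / sum(!pos) - 1
    best <- max(best, j)
  }
  best
}

# Small labeled random instance for diagnostics tests.
random_instance <- function(n_pos, n_neg, ties = FALSE) {
  draw <- function(n, shift) {
    if (ties) sample(0:10, n, replace = TRUE) + shift
    else rnorm(n, shift)
  }
  list(scores = c(draw(n_pos, 1), draw(n_neg, 0)),
       pos = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}
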