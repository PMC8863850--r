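test_that("AUC handles perfect separation, partial concordance and ties", {
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.4, 0.3),
                           c("positive", "positive", "negative", "negative"))$auc, 1)
  ## 1 concordant of 2 pairs (brute-force enumeration)
  expect_equal(roc_and_auc(c(0.9, 0.2, 0.5),
                           c("positive", "positive", "negative"))$auc, 0.5)
  expect_equal(roc_and_auc(rep(0.4, 6),
                           rep(c("positive", "negative"), 3))$auc, 0.5)
  expect_error(roc_and_auc(1:3, rep("positive", 3)), "one class")
})

test_that("trapezoidal AUC equals brute-force Mann-Whitney concordance on small score sets", {
  set.seed(21)
  for (n_pos in 2:5) for (n_neg in 2:5) {
    for (rep in 1:3) {
      ## draws from a coarse grid so ties occur often
      scores <- sample(seq(0, 1, by = 0.25), n_pos + n_neg, replace = TRUE)
      labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
      roc <- roc_and_auc(scores, labels)
      expect_equal(roc$auc, oracle_auc_pairs(scores, labels), tolerance = 1e-9)
      expect_true(all(diff(roc$sensitivity) <= 1e-12))   # non-increasing in threshold
    }
  }
})

test_that("AUC is complementary under score negation for tie-free scores", {
  set.seed(22)
  scores <- sample(seq_len(100), 30)   # distinct
  labels <- rep(c("positive", "negative"), c(10, 20))
  a <- roc_and_auc(scores, labels)$auc
  b <- roc_and_auc(-scores, labels)$auc
  expect_equal(a + b, 1, tolerance = 1e-12)
})

test_that("the package ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- runif(60)
  labels <- sample(c("negative", "positive"), 60, replace = TRUE)
  expect_equal(roc_and_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("negative", "positive"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the balanced cutoff equalizes sensitivity and specificity with a low tie rule", {
  roc <- roc_and_auc(c(0.1, 0.2, 0.6, 0.5, 0.8, 0.9),
                     c("negative", "negative", "negative",
                       "positive", "positive", "positive"))
  cut <- balanced_cutoff(roc)
  expect_gt(cut, 0.5); expect_lte(cut, 0.6)
  i <- which(roc$thresholds == cut)
  expect_equal(roc$sensitivity[i], 2 / 3)
  expect_equal(roc$specificity[i], 2 / 3)
  ## exhaustive sweep oracle: no threshold does better
  sweep_d <- abs(roc$sensitivity - roc$specificity)
  expect_equal(min(sweep_d[is.finite(roc$thresholds)]),
               abs(roc$sensitivity[i] - roc$specificity[i]))

  ## perfect separation: the lowest threshold attaining balance is returned
  roc2 <- roc_and_auc(c(0.3, 0.4, 0.8, 0.9),
                      c("negative", "negative", "positive", "positive"))
  expect_equal(balanced_cutoff(roc2), 0.8)
  expect_equal(default_decision_cutoff(), 0.7)
})

test_that("stratification reproduces per-tier rates and guards empty tiers", {
  fx <- tier_count_fixture(rbind(c(418, 0), c(43, 5), c(39, 29), c(5, 9)))
  st <- stratify(fx$scores, fx$labels)
  expect_equal(st$n_negative, c(418, 43, 39, 5))
  expect_equal(st$n_positive, c(0, 5, 29, 9))
  expect_equal(round(st$lnm_pct, 1), c(0.0, 10.4, 42.6, 64.3))
  expect_equal(sum(st$n_negative) + sum(st$n_positive), length(fx$scores))

  empty <- stratify(c(0.1, 0.95), c("negative", "positive"))
  expect_true(is.na(empty$lnm_pct[2]))   # empty tier: NA, not 0
  expect_equal(empty$lnm_pct[c(1, 4)], c(0, 100))

  ## conservation at an arbitrary tier map
  set.seed(30)
  sc <- runif(200); lb <- sample(c("negative", "positive"), 200, TRUE)
  st2 <- stratify(sc, lb, tier_map = c(lo = 0, mid = 0.33, hi = 0.66))
  expect_equal(sum(st2$n_negative + st2$n_positive), 200L)
})

test_that("risk tiers use half-open intervals with the top tier closed", {
  tiers <- risk_tier(c(0, 0.699, 0.7, 0.8, 0.899, 0.9, 1))
  expect_equal(as.character(tiers),
               c("very-low", "very-low", "low", "moderate", "moderate",
                 "high", "high"))
  expect_error(risk_tier(1.5), "0, 1")
})

test_that("pooled Student t works from raw samples and printed summaries", {
  x <- c(5.1, 4.9, 5.3, 5.0); y <- c(6.2, 6.0, 6.4, 6.1)
  ours <- two_group_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  ## identical groups: t = 0, p = 1
  same <- two_group_t(mean1 = 2, sd1 = 1, n1 = 10, mean2 = 2, sd2 = 1, n2 = 10)
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  ## swapping the groups flips t, not p
  ab <- two_group_t(mean1 = 3, sd1 = 1, n1 = 8, mean2 = 2, sd2 = 1.5, n2 = 12)
  ba <- two_group_t(mean1 = 2, sd1 = 1.5, n1 = 12, mean2 = 3, sd2 = 1, n2 = 8)
  expect_equal(ab$t, -ba$t); expect_equal(ab$p, ba$p)

  expect_error(two_group_t(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 1, sd2 = 0, n2 = 5),
               "zero pooled variance")
  expect_error(two_group_t(1, 1:3), "n >= 2")
})

test_that("the tile-proportion summary row is overwhelmingly significant", {
  res <- two_group_t(mean1 = 50.18, sd1 = 25.95, n1 = 505,
                     mean2 = 23.49, sd2 = 15.32, n2 = 43)
  expect_lt(res$p, 1e-5)
})

test_that("Fisher exact p matches hypergeometric enumeration and OR conventions hold", {
  flat <- fisher_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$odds_ratio, 1); expect_equal(flat$p, 1)

  ## rectum vs non-rectum by LNM in the training set
  rectum <- fisher_or(matrix(c(24, 19, 174, 331), 2, byrow = TRUE))
  expect_lt(rectum$p, 0.01); expect_gt(rectum$p, 0.005)

  ## doubling all cells leaves the odds ratio unchanged
  t1 <- fisher_or(matrix(c(3, 7, 5, 9), 2))
  t2 <- fisher_or(matrix(c(6, 14, 10, 18), 2))
  expect_equal(t1$odds_ratio, t2$odds_ratio)

  ## zero-cell tables get the continuity-corrected OR, flagged
  zc <- fisher_or(matrix(c(0, 5, 6, 4), 2, byrow = TRUE))
  expect_true(zc$corrected)
  expect_equal(zc$odds_ratio, (0.5 * 4.5) / (5.5 * 6.5))

  set.seed(31)
  for (rep in 1:25) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_or(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_error(fisher_or(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(fisher_or(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("cohort prevalence is the positive fraction", {
  expect_equal(prevalence(rep(c("positive", "negative"), c(61, 726))), 61 / 787)
})
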