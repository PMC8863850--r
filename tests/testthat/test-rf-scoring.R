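## Feature table with a controllable class signal, for fast ensemble tests.
fake_features <- function(n_neg, n_pos, signal = 1, seed = 1L) {
  set.seed(seed)
  n <- n_neg + n_pos
  lab <- rep(c("negative", "positive"), c(n_neg, n_pos))
  X <- matrix(rnorm(n * 18L), n, 18L)
  X[lab == "positive", 10L] <- X[lab == "positive", 10L] + signal  # pct_met slot
  colnames(X) <- feature_names()
  data.frame(case_id = sprintf("f%04d", seq_len(n)), lnm_label = lab, X,
             check.names = FALSE)
}

test_that("oversampling equalizes class counts without touching the majority", {
  ft <- fake_features(505L, 43L)
  bal <- oversample_balance(ft, seed = 2L)
  expect_equal(as.vector(table(bal$lnm_label)), c(505L, 505L))
  expect_equal(sort(bal$case_id[bal$lnm_label == "negative"]),
               sort(ft$case_id[ft$lnm_label == "negative"]))
  expect_true(all(bal$case_id[bal$lnm_label == "positive"] %in%
                    ft$case_id[ft$lnm_label == "positive"]))

  even <- fake_features(50L, 50L)
  expect_identical(oversample_balance(even, seed = 1L), even)

  expect_error(oversample_balance(data.frame(lnm_label = rep("negative", 5))),
               "both LNM classes")
})

test_that("with-replacement draws guarantee the count, not coverage", {
  ft <- fake_features(10L, 3L)
  bal <- oversample_balance(ft, seed = 7L)
  pos <- bal$case_id[bal$lnm_label == "positive"]
  expect_length(pos, 10L)
  ## sampled with replacement: duplicates must occur when 3 ids fill 10 slots
  expect_lte(length(unique(pos)), 3L)
  expect_identical(oversample_balance(ft, seed = 7L), bal)
})

test_that("ensemble training retains the top-k forests sorted by selection AUC", {
  ft <- fake_features(80L, 20L, signal = 1.5)
  ens <- train_rf_ensemble(ft, n_candidates = 30L, top_k = 5L, master_seed = 3L)
  expect_length(ens$members, 5L)
  expect_length(ens$candidate_aucs, 30L)
  expect_true(all(diff(ens$member_aucs) <= 0))
  expect_equal(ens$member_aucs, sort(ens$candidate_aucs, decreasing = TRUE)[1:5])
  expect_error(train_rf_ensemble(ft, n_candidates = 5L, top_k = 10L), "top_k")
  ## reproducibility: the master seed fixes the whole sweep
  ens2 <- train_rf_ensemble(ft, n_candidates = 30L, top_k = 5L, master_seed = 3L)
  expect_equal(ens$candidate_aucs, ens2$candidate_aucs)
  expect_equal(ens$member_seeds, ens2$member_seeds)
})

test_that("a 1-of-1 ensemble collapses to its single forest's probability", {
  ft <- fake_features(40L, 15L, signal = 1)
  ens <- train_rf_ensemble(ft, n_candidates = 1L, top_k = 1L, master_seed = 5L)
  sc <- rf_score(ens, ft)
  probs <- attr(sc, "member_probs")
  expect_equal(ncol(probs), 1L)
  expect_equal(sc$rf_score, probs[, 1L])
})

test_that("the RF score is the member maximum, bounded and above the member mean", {
  ft <- fake_features(80L, 20L, signal = 1, seed = 4L)
  ens <- train_rf_ensemble(ft, n_candidates = 12L, top_k = 4L, master_seed = 1L)
  new <- fake_features(70L, 30L, signal = 1, seed = 9L)   # 100 unseen cases
  sc <- rf_score(ens, new)
  probs <- attr(sc, "member_probs")
  expect_equal(sc$rf_score, apply(probs, 1L, max))
  expect_true(all(sc$rf_score >= 0 & sc$rf_score <= 1))
  expect_true(all(sc$rf_score >= rowMeans(probs)))
  expect_s3_class(sc$risk_tier, "factor")
  expect_error(rf_score(ens, new[, 1:5]), "schema")
})

test_that("label-shuffled data gives chance-level out-of-bag selection AUC", {
  ft <- fake_features(100L, 100L, signal = 2, seed = 6L)
  set.seed(8)
  ft$lnm_label <- sample(ft$lnm_label)
  ens <- train_rf_ensemble(ft, n_candidates = 20L, top_k = 5L,
                           master_seed = 2L, selection = "oob")
  expect_lt(abs(mean(ens$candidate_aucs) - 0.5), 0.1)
})

test_that("hyperparameter tuning reports the surface and breaks ties toward smaller models", {
  ft_tr <- fake_features(60L, 20L, signal = 1.2, seed = 2L)
  ft_va <- fake_features(30L, 10L, signal = 1.2, seed = 3L)
  single <- tune_hyperparameters(ft_tr, ft_va, depth_grid = 6L, trees_grid = 60L)
  expect_equal(unname(single$best), c(6L, 60L))
  expect_equal(nrow(single$surface), 1L)

  tuned <- tune_hyperparameters(ft_tr, ft_va, depth_grid = c(3L, 6L, 9L),
                                trees_grid = c(20L, 60L), seed = 4L)
  expect_equal(nrow(tuned$surface), 6L)
  expect_true(all(c("auc_train", "auc_valid") %in% names(tuned$surface)))
  best_row <- tuned$surface[tuned$surface$depth == tuned$best[["depth"]] &
                              tuned$surface$trees == tuned$best[["trees"]], ]
  expect_equal(best_row$auc_valid, max(tuned$surface$auc_valid))
})

test_that("training-optimal depth tends to exceed validation-optimal depth", {
  hits <- 0L
  for (s in 1:3) {
    ft <- fake_features(90L, 30L, signal = 0.8, seed = s)
    tr <- seq_len(nrow(ft)) %% 3 != 0
    tuned <- tune_hyperparameters(ft[tr, ], ft[!tr, ],
                                  depth_grid = c(2L, 4L, 8L, 12L),
                                  trees_grid = 40L, seed = s)
    s_tr <- tuned$surface[order(-tuned$surface$auc_train, tuned$surface$depth), ]
    s_va <- tuned$surface[order(-tuned$surface$auc_valid, tuned$surface$depth), ]
    if (s_va$depth[1L] <= s_tr$depth[1L]) hits <- hits + 1L
  }
  expect_gte(hits, 2L)   # overfitting direction in at least half the repeats
})

test_that("feature importance averages to a unit-sum table that finds planted signal", {
  ## only the pct_met slot separates the classes; all else is noise
  ft <- fake_features(80L, 40L, signal = 3, seed = 5L)
  ens <- train_rf_ensemble(ft, n_candidates = 10L, top_k = 3L, master_seed = 6L)
  imp <- feature_importance(ens)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-6)
  expect_equal(imp$feature[1L], "pct_met")

  ## with every other feature held constant, forests can split only on the
  ## informative one, which then carries all the importance
  ft_one <- ft
  ft_one[, setdiff(feature_names(), "pct_met")] <- 1
  ens_one <- train_rf_ensemble(ft_one, n_candidates = 4L, top_k = 2L,
                               master_seed = 1L)
  imp_one <- feature_importance(ens_one)
  expect_equal(imp_one$feature[1L], "pct_met")
  expect_equal(imp_one$importance[1L], 1, tolerance = 1e-9)

  ## all-noise features: no runaway importance at a large tree count
  ft0 <- fake_features(100L, 100L, signal = 0, seed = 7L)
  ens0 <- train_rf_ensemble(ft0, n_candidates = 1L, top_k = 1L,
                            n_trees = 200L, master_seed = 8L)
  imp0 <- feature_importance(ens0)
  expect_lt(max(imp0$importance), 3 * min(imp0$importance))
})

test_that("ensembles round-trip through the serialized directory", {
  ft <- fake_features(40L, 15L, signal = 1, seed = 2L)
  ens <- train_rf_ensemble(ft, n_candidates = 6L, top_k = 2L, master_seed = 9L)
  d <- withr::local_tempdir()
  save_ensemble(ens, d)
  back <- load_ensemble(d)
  expect_equal(back$member_aucs, ens$member_aucs)
  expect_equal(rf_score(back, ft)$rf_score, rf_score(ens, ft)$rf_score)
})
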