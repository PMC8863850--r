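#' @importFrom ranger ranger importance
NULL

## Mann-Whitney AUC (tie-corrected) used internally for forest selection;
## identical to the trapezoidal ROC integral (asserted in the test suite).
auc_mw <- function(scores, labels) {
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_tf("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Oversample the minority class to balance a training table
#'
#' LNM-positive cases are roughly tenfold rarer than negatives; before
#' forest fitting the minority class is redrawn with replacement until the
#' class counts are equal. The majority class is untouched. With
#' replacement, individual minority cases may be duplicated or absent —
#' only the count is guaranteed.
#'
#' @param features data.frame with an `lnm_label` column
#'   ("negative"/"positive").
#' @param seed RNG seed.
#' @return row-balanced data.frame.
#' @export
oversample_balance <- function(features, seed = 1L) {
  tab <- table(features$lnm_label)
  if (length(tab) < 2L || any(tab == 0L)) {
    stop_tf("both LNM classes must be present for balancing")
  }
  if (tab[[1L]] == tab[[2L]]) return(features)
  minority <- names(tab)[which.min(tab)]
  n_target <- max(tab)
  set.seed(seed)
  min_idx <- which(features$lnm_label == minority)
  take <- sample(min_idx, n_target, replace = TRUE)
  out <- rbind(features[features$lnm_label != minority, , drop = FALSE],
               features[take, , drop = FALSE])
  rownames(out) <- NULL
  out
}

fit_member <- function(balanced, depth, n_trees, seed) {
  ranger::ranger(
    x = balanced[, feature_names(), drop = FALSE],
    y = factor(balanced$lnm_label, levels = c("negative", "positive")),
    num.trees = n_trees, max.depth = depth,
    probability = TRUE, importance = "impurity", seed = seed,
    num.threads = 1L)
}

member_prob <- function(member, features) {
  predict(member, data = features[, feature_names(), drop = FALSE],
          num.threads = 1L)$predictions[, "positive"]
}

#' Train the oversampled random-forest ensemble
#'
#' Fits `n_candidates` random forests on the oversampled (class-balanced)
#' training table, differing only by seed, scores each candidate by AUC,
#' and retains the `top_k` by AUC (ties broken by seed order). Selection
#' AUC is computed on the original unbalanced training cases by default —
#' scoring on the oversampled table would let duplicated positives inflate
#' it — with out-of-bag selection available behind `selection = "oob"`.
#'
#' @param features training table from [assemble_features_cohort()]
#'   (case_id, lnm_label, 18 feature columns).
#' @param n_candidates candidate forests (default 500).
#' @param top_k members retained (default 20).
#' @param depth maximum tree depth (default 6).
#' @param n_trees trees per forest (default 60).
#' @param master_seed seed governing oversampling and all member seeds.
#' @param selection `"train"` (AUC on unbalanced training cases, default)
#'   or `"oob"` (out-of-bag AUC on the balanced table).
#' @return an `rf_ensemble`: members sorted by selection AUC (descending),
#'   their seeds and AUCs, all candidate AUCs, hyperparameters and the
#'   feature schema.
#' @export
train_rf_ensemble <- function(features, n_candidates = 500L, top_k = 20L,
                              depth = 6L, n_trees = 60L, master_seed = 1L,
                              selection = c("train", "oob")) {
  selection <- match.arg(selection)
  if (top_k > n_candidates) stop_tf("top_k (%d) exceeds n_candidates (%d)", top_k, n_candidates)
  missing_cols <- setdiff(feature_names(), names(features))
  if (length(missing_cols)) stop_tf("missing feature columns: %s", paste(missing_cols, collapse = ", "))
  seeds <- derive_seeds(master_seed, n_candidates + 1L)
  balanced <- oversample_balance(features, seed = seeds[1L])
  member_seeds <- seeds[-1L]
  labels <- features$lnm_label
  bal_labels <- balanced$lnm_label
  fits <- vector("list", n_candidates)
  aucs <- numeric(n_candidates)
  for (i in seq_len(n_candidates)) {
    fits[[i]] <- fit_member(balanced, depth, n_trees, member_seeds[i])
    aucs[i] <- if (selection == "train") {
      auc_mw(member_prob(fits[[i]], features), labels)
    } else {
      oob <- fits[[i]]$predictions[, "positive"]
      ok <- !is.na(oob)
      auc_mw(oob[ok], bal_labels[ok])
    }
  }
  ord <- order(-aucs, seq_along(aucs))[seq_len(top_k)]
  structure(list(
    members = fits[ord],
    member_seeds = member_seeds[ord],
    member_aucs = aucs[ord],
    candidate_aucs = aucs,
    hyperparameters = list(depth = depth, n_trees = n_trees,
                           n_candidates = n_candidates, top_k = top_k),
    selection = selection,
    master_seed = master_seed,
    feature_schema = feature_names()),
    class = "rf_ensemble")
}

#' Score cases with a trained RF ensemble
#'
#' Each retained forest returns a metastatic probability in [0, 1]; the
#' case's RF score is the maximum over members, and the score is binned
#' into a risk tier (see [risk_tier()]).
#'
#' @param ensemble an `rf_ensemble`.
#' @param features data.frame with the 18 feature columns (and optionally
#'   `case_id`).
#' @param tier_map tier boundaries, see [risk_tier()].
#' @return an `rf_score_result` data.frame: `case_id`, `rf_score`,
#'   `risk_tier`, with the per-member probability matrix in attribute
#'   `member_probs`.
#' @export
rf_score <- function(ensemble, features, tier_map = default_tier_map()) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  if (!all(ensemble$feature_schema %in% names(features))) {
    stop_tf("feature schema mismatch between ensemble and input")
  }
  probs <- vapply(ensemble$members, member_prob, numeric(nrow(features)),
                  features = features)
  probs <- matrix(probs, nrow = nrow(features))
  score <- apply(probs, 1L, max)
  out <- data.frame(
    case_id = features$case_id %||% sprintf("case_%d", seq_len(nrow(features))),
    rf_score = score,
    risk_tier = risk_tier(score, tier_map),
    stringsAsFactors = FALSE)
  attr(out, "member_probs") <- probs
  class(out) <- c("rf_score_result", "data.frame")
  out
}

#' Tune forest depth and tree count on a train/validation split
#'
#' Fits one seeded forest per grid cell on the oversampled training table
#' and records AUC on both the (unbalanced) training cases and the
#' validation cases. The best pair is chosen by validation AUC with ties
#' broken toward smaller depth, then fewer trees.
#'
#' @param train_features,valid_features feature tables.
#' @param depth_grid candidate depths (default 3:10).
#' @param trees_grid candidate tree counts (default 20,40,60,80,100).
#' @param seed RNG seed.
#' @return list with `surface` (depth, trees, auc_train, auc_valid) and
#'   `best` (named vector depth, trees).
#' @export
tune_hyperparameters <- function(train_features, valid_features,
                                 depth_grid = 3:10,
                                 trees_grid = c(20L, 40L, 60L, 80L, 100L),
                                 seed = 1L) {
  if (!length(depth_grid) || !length(trees_grid)) stop_tf("empty tuning grid")
  seeds <- derive_seeds(seed, 2L)
  balanced <- oversample_balance(train_features, seed = seeds[1L])
  grid <- expand.grid(depth = depth_grid, trees = trees_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_member(balanced, grid$depth[i], grid$trees[i], seeds[2L])
    c(auc_train = auc_mw(member_prob(fit, train_features), train_features$lnm_label),
      auc_valid = auc_mw(member_prob(fit, valid_features), valid_features$lnm_label))
  })
  surface <- cbind(grid, do.call(rbind, res))
  ord <- order(-surface$auc_valid, surface$depth, surface$trees)
  best <- surface[ord[1L], c("depth", "trees")]
  list(surface = surface, best = c(depth = best$depth, trees = best$trees))
}

#' Averaged feature importance of the ensemble
#'
#' Impurity-decrease importances averaged over the retained members and
#' normalized to sum to 1.
#'
#' @param ensemble an `rf_ensemble`.
#' @return data.frame with `feature` and `importance`, sorted descending.
#' @export
feature_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  imp <- rowMeans(vapply(ensemble$members,
                         function(m) ranger::importance(m)[ensemble$feature_schema],
                         numeric(length(ensemble$feature_schema))))
  imp <- imp / sum(imp)
  out <- data.frame(feature = ensemble$feature_schema, importance = unname(imp))
  out[order(-out$importance), ]
}

#' Save / load an RF ensemble as a directory
#'
#' Members are serialized individually with a manifest JSON recording
#' seeds, selection AUCs, hyperparameters and the feature schema.
#'
#' @param ensemble an `rf_ensemble`.
#' @param dir target directory.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[i]], file.path(dir, sprintf("member_%03d.rds", i)))
  }
  manifest <- ensemble[c("member_seeds", "member_aucs", "candidate_aucs",
                         "hyperparameters", "selection", "master_seed",
                         "feature_schema")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.rds$", full.names = TRUE))
  members <- lapply(files, readRDS)
  structure(c(list(members = members), manifest), class = "rf_ensemble")
}
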