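#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end flow. All numeric
#' pipeline constants (tile size, gray threshold, probability cutoffs,
#' group boundaries, tier map, candidate/top-k counts, depth, trees) live
#' here, never hard-coded in stage logic.
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "features", "rf", "score", "stratify", "map")` in
#'   dependency order. When "simulate" is disabled, `cases.csv`/`tiles.csv`
#'   already present in `out_dir` are used, so externally supplied tile
#'   probabilities flow through identically.
#' @param split_frac fraction of cases in the training split (stratified by
#'   label; default 0.7).
#' @param cancer_cutoff scoring cutoff on `p_cancer` (default 0.5).
#' @param met_cutoff metastatic split point on `p_met` (default 0.5).
#' @param boundary group-boundary convention, see [assign_group()].
#' @param n_candidates,top_k,depth,n_trees RF ensemble hyperparameters
#'   (defaults 500, 20, 6, 60).
#' @param tier_map risk-tier map, see [default_tier_map()].
#' @param n_maps number of per-case slide maps rendered (default 2).
#' @param seed master seed for split and ensemble.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       stages = c("simulate", "features", "rf", "score",
                                  "stratify", "map"),
                       split_frac = 0.7, cancer_cutoff = 0.5,
                       met_cutoff = 0.5, boundary = "extreme",
                       n_candidates = 500L, top_k = 20L,
                       depth = 6L, n_trees = 60L,
                       tier_map = default_tier_map(),
                       n_maps = 2L, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

## Stratified-by-label train/validation split.
split_cases <- function(labels, frac, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    train[sample(idx, round(frac * length(idx)))] <- TRUE
  }
  train
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order: simulate a cohort (or
#' load supplied probabilities), assemble case features, train the
#' oversampled RF ensemble on a stratified training split, score all
#' cases, stratify scores into risk tiers with ROC/AUC per split, and
#' render per-case probability maps. Every artifact is written under
#' `config$out_dir` and hashed into a JSON run manifest; a rerun with the
#' same config reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return (invisibly) the run manifest: per-stage outputs, counts, file
#'   hashes and the seeds used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 2L)
  manifest <- list(seed = config$seed, stages = list())
  on <- function(s) s %in% config$stages

  if (on("simulate")) {
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, config$out_dir)
    ## re-read from disk so downstream stages see exactly what a run fed
    ## with externally supplied CSVs would see
    cohort <- read_cohort(config$out_dir)
  } else {
    if (!file.exists(file.path(config$out_dir, "tiles.csv"))) {
      stop_tf("stage 'features' needs cases.csv/tiles.csv in %s (simulate disabled)",
              config$out_dir)
    }
    cohort <- read_cohort(config$out_dir)
  }
  manifest$stages$simulate <- list(n_cases = nrow(cohort$cases),
                                   n_tiles = nrow(cohort$tiles))

  features <- NULL
  if (on("features")) {
    features <- assemble_features_cohort(cohort, config$cancer_cutoff,
                                         config$met_cutoff, config$boundary)
    write_features(features, file.path(config$out_dir, "features.csv"))
    manifest$stages$features <- list(n_cases = nrow(features),
                                     excluded = attr(features, "excluded"))
  }

  ensemble <- NULL; train_idx <- NULL
  if (on("rf")) {
    train_idx <- split_cases(features$lnm_label, config$split_frac, seeds[1L])
    ensemble <- train_rf_ensemble(features[train_idx, ],
                                  n_candidates = config$n_candidates,
                                  top_k = config$top_k,
                                  depth = config$depth,
                                  n_trees = config$n_trees,
                                  master_seed = seeds[2L])
    save_ensemble(ensemble, file.path(config$out_dir, "ensemble"))
    manifest$stages$rf <- list(n_train = sum(train_idx),
                               n_valid = sum(!train_idx),
                               top_member_auc = max(ensemble$member_aucs))
  }

  scores <- NULL
  if (on("score")) {
    scores <- rf_score(ensemble, features, config$tier_map)
    scores$split <- ifelse(train_idx, "training", "validation")
    scores$lnm_label <- features$lnm_label
    write.csv(as.data.frame(scores)[, c("case_id", "rf_score", "risk_tier",
                                        "split", "lnm_label")],
              file.path(config$out_dir, "scores.csv"), row.names = FALSE)
    manifest$stages$score <- list(n_scored = nrow(scores))
  }

  if (on("stratify")) {
    for (sp in c("training", "validation")) {
      sub <- scores[scores$split == sp, ]
      strat <- stratify(sub$rf_score, sub$lnm_label, config$tier_map)
      roc <- roc_and_auc(sub$rf_score, sub$lnm_label)
      write_evaluation(strat, roc, file.path(config$out_dir, sp))
      manifest$stages$stratify[[sp]] <- list(auc = roc$auc,
                                             balanced_cutoff = balanced_cutoff(roc))
    }
  }

  if (on("map")) {
    ids <- head(cohort$cases$case_id, config$n_maps)
    for (id in ids) {
      tl <- cohort$tiles[cohort$tiles$case_id == id, ]
      n_cols <- ceiling(sqrt(nrow(tl)))
      grid <- data.frame(row = (seq_len(nrow(tl)) - 1L) %/% n_cols,
                         col = (seq_len(nrow(tl)) - 1L) %% n_cols)
      man <- data.frame(slide_id = id, row = grid$row, col = grid$col,
                        kept = TRUE)
      rec <- data.frame(row = grid$row, col = grid$col, p_met = tl$p_met,
                        predicted_label = ifelse(tl$p_cancer > config$cancer_cutoff,
                                                 "cancer", "non_tumoral_mucosa"))
      write_map(render_map(man, rec),
                file.path(config$out_dir, sprintf("map_%s.png", id)))
    }
    manifest$stages$map <- list(rendered = as.list(ids))
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_manifest\\.json$", files)]
  hashes <- tools::md5sum(files)
  manifest$files <- as.list(stats::setNames(unname(hashes),
                                            sub(paste0(config$out_dir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
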