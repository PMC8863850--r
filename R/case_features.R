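#' Names of the 18 case-level features
#'
#' The feature vector consumed by the random-forest ensemble: tumor
#' location code; total cancer-tile count; counts of metastatic- and
#' non-metastatic-predicted tiles; counts of probability groups A--E;
#' percentages of metastatic/non-metastatic tiles; mean cancer-class
#' probability; mean metastatic probability of metastatic-predicted tiles
#' and mean non-metastatic probability of non-metastatic-predicted tiles;
#' standard deviations of those three probabilities; and the probability
#' score summary. The enumeration resolves the group-C count as the 18th
#' slot, completing the A--E partition.
#'
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  c("location_code", "n_cancer_tiles", "n_met_tiles", "n_nonmet_tiles",
    "n_groupA", "n_groupB", "n_groupC", "n_groupD", "n_groupE",
    "pct_met", "pct_nonmet", "mean_p_cancer",
    "mean_p_met_of_met_tiles", "mean_p_nonmet_of_nonmet_tiles",
    "sd_p_cancer", "sd_p_met", "sd_p_nonmet", "probability_score_summary")
}

#' Encode a tumor site as its 3-level location group
#'
#' Sites are grouped as (1) cecum, ascending and transverse colon, (2)
#' descending and sigmoid colon, (3) rectum, entered into the model as one
#' ordinal feature.
#'
#' @param site character vector of site names.
#' @return integer vector of location codes in {1, 2, 3}.
#' @export
encode_location <- function(site) {
  map <- c(cecum = 1L, ascending = 1L, transverse = 1L,
           descending = 2L, sigmoid = 2L, rectum = 3L)
  code <- map[tolower(site)]
  if (anyNA(code)) {
    stop_tf("unknown tumor site(s): %s",
            paste(unique(site[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

#' Probability score summary of a case
#'
#' The per-case sum over tiles of cancer-class probability times
#' metastatic probability.
#'
#' @param p_cancer,p_met parallel numeric vectors for one case's tiles.
#' @return non-negative scalar; 0 with a warning for an empty tile set.
#' @export
probability_score_summary <- function(p_cancer, p_met) {
  stopifnot(length(p_cancer) == length(p_met))
  if (length(p_cancer) == 0L) {
    warning("empty tile set: probability score summary is 0")
    return(0)
  }
  sum(p_cancer * p_met)
}

sd0 <- function(x) if (length(x) <= 1L) 0 else sd(x)
mean0 <- function(x) if (length(x) == 0L) 0 else mean(x)

#' Assemble the 18-parameter feature vector for one case
#'
#' Takes the case's tile records after the scoring cancer-probability
#' cutoff (`p_cancer` > 0.5 upstream) and computes the feature vector.
#' Tiles are split into metastatic- vs non-metastatic-predicted at
#' `p_met > met_cutoff` (default 0.5). Standard deviations use the sample
#' (n-1) convention; a single tile yields sd 0.
#'
#' @param case one-row data.frame (or list) with `case_id` and
#'   `location_group`.
#' @param tiles data.frame of the case's tiles with `p_cancer`, `p_met`.
#' @param met_cutoff metastatic split point on `p_met`.
#' @param boundary group-boundary convention, see [assign_group()].
#' @return named numeric vector of length 18 (see [feature_names()]).
#' @export
assemble_features <- function(case, tiles, met_cutoff = 0.5,
                              boundary = "extreme") {
  if (nrow(tiles) == 0L) {
    stop(errorCondition(
      sprintf("case %s has no cancer tile and is excluded", case$case_id),
      class = c("tileforest_excluded_case", "error")))
  }
  met <- tiles$p_met > met_cutoff
  grp <- table(assign_group(tiles$p_met, boundary))
  n <- nrow(tiles)
  v <- c(
    location_code = as.numeric(case$location_group),
    n_cancer_tiles = n,
    n_met_tiles = sum(met),
    n_nonmet_tiles = sum(!met),
    n_groupA = as.numeric(grp[["A"]]), n_groupB = as.numeric(grp[["B"]]),
    n_groupC = as.numeric(grp[["C"]]), n_groupD = as.numeric(grp[["D"]]),
    n_groupE = as.numeric(grp[["E"]]),
    pct_met = 100 * sum(met) / n,
    pct_nonmet = 100 * sum(!met) / n,
    mean_p_cancer = mean(tiles$p_cancer),
    mean_p_met_of_met_tiles = mean0(tiles$p_met[met]),
    mean_p_nonmet_of_nonmet_tiles = mean0(1 - tiles$p_met[!met]),
    sd_p_cancer = sd0(tiles$p_cancer),
    sd_p_met = sd0(tiles$p_met[met]),
    sd_p_nonmet = sd0(1 - tiles$p_met[!met]),
    probability_score_summary = sum(tiles$p_cancer * tiles$p_met)
  )
  stopifnot(identical(names(v), feature_names()))
  v
}

#' Assemble case feature vectors for a whole cohort
#'
#' Applies the scoring cancer-probability cutoff (strict `p_cancer` >
#' `cancer_cutoff`), drops cases left with no cancer tile (flagging them as
#' excluded), and computes the 18 features per remaining case.
#'
#' @param cohort a `synthetic_cohort`, or a list with `cases` and `tiles`
#'   data.frames in the shared schema.
#' @param cancer_cutoff scoring cutoff on `p_cancer` (default 0.5).
#' @param met_cutoff metastatic split point on `p_met` (default 0.5).
#' @param boundary group-boundary convention, see [assign_group()].
#' @return data.frame with `case_id`, `lnm_label`, the 18 feature columns,
#'   and attribute `excluded` (case ids with no cancer tile).
#' @export
assemble_features_cohort <- function(cohort, cancer_cutoff = 0.5,
                                     met_cutoff = 0.5, boundary = "extreme") {
  tiles <- select_cancer_tiles(cohort$tiles, cancer_cutoff)
  dt <- data.table::as.data.table(tiles)
  grp <- assign_group(dt$p_met, boundary)
  dt[, met := p_met > met_cutoff]
  for (g in levels(grp)) dt[, (paste0("is", g)) := grp == g]
  ft <- dt[, {
    n <- .N
    pm_met <- p_met[met]; pm_non <- 1 - p_met[!met]
    list(
      n_cancer_tiles = as.numeric(n),
      n_met_tiles = as.numeric(sum(met)),
      n_nonmet_tiles = as.numeric(sum(!met)),
      n_groupA = as.numeric(sum(isA)), n_groupB = as.numeric(sum(isB)),
      n_groupC = as.numeric(sum(isC)), n_groupD = as.numeric(sum(isD)),
      n_groupE = as.numeric(sum(isE)),
      pct_met = 100 * sum(met) / n,
      pct_nonmet = 100 * sum(!met) / n,
      mean_p_cancer = mean(p_cancer),
      mean_p_met_of_met_tiles = mean0(pm_met),
      mean_p_nonmet_of_nonmet_tiles = mean0(pm_non),
      sd_p_cancer = sd0(p_cancer),
      sd_p_met = sd0(pm_met),
      sd_p_nonmet = sd0(pm_non),
      probability_score_summary = sum(p_cancer * p_met)
    )
  }, by = case_id]
  cases <- cohort$cases
  out <- merge(cases, as.data.frame(ft), by = "case_id", sort = TRUE)
  out$location_code <- as.numeric(out$location_group)
  out <- out[, c("case_id", "lnm_label", feature_names())]
  rownames(out) <- NULL
  attr(out, "excluded") <- setdiff(cases$case_id, ft$case_id)
  out
}

#' Write case features as CSV with a JSON schema sidecar
#'
#' @param features data.frame from [assemble_features_cohort()].
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = 1L, n_features = 18L, features = feature_names(),
         excluded = attr(features, "excluded") %||% character()),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
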