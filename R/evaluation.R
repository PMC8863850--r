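#' ROC curve and AUC
#'
#' Builds the ROC curve over all observed score thresholds (decision rule:
#' predict positive when score >= threshold) and integrates it by the
#' trapezoidal rule. With ties handled through the threshold set, the
#' integral equals the tie-corrected Mann-Whitney concordance probability.
#'
#' @param scores numeric scores.
#' @param labels parallel labels, "negative"/"positive" (or a factor with
#'   those levels).
#' @return a `roc_data` list: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `n_positive`, `n_negative`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_tf("AUC undefined: only one class present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores[!pos] < t) / n0, 0)
  fpr <- 1 - spec
  ## trapezoid over the curve, traversed from (1,1) down to (0,0)
  auc <- sum(diff(-fpr) * (head(sens, -1L) + sens[-1L]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_positive = n1, n_negative = n0),
            class = "roc_data")
}

#' Balanced-error-rate cutoff of a ROC curve
#'
#' The threshold minimizing |sensitivity - specificity|; among ties the
#' lowest finite threshold is returned. This operating point is the
#' package's accuracy-reporting cutoff; on the clinical model it sits at an
#' RF score of 0.70, which is also the default decision cutoff exposed by
#' [default_decision_cutoff()].
#'
#' @param roc a `roc_data` from [roc_and_auc()].
#' @return scalar threshold.
#' @export
balanced_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_data"))
  finite <- is.finite(roc$thresholds)
  d <- abs(roc$sensitivity - roc$specificity)[finite]
  thr <- roc$thresholds[finite]
  thr[which.min(d)]
}

#' Default case-level decision cutoff on the RF score
#'
#' @return 0.70, the balanced operating point of the clinical model.
#' @export
default_decision_cutoff <- function() 0.70

#' Risk-tier map for RF scores
#'
#' Tiers partition [0, 1] with half-open intervals, the top tier closed:
#' [0, 0.7) very-low, [0.7, 0.8) low, [0.8, 0.9) moderate, [0.9, 1] high.
#'
#' @return named numeric vector of tier lower bounds.
#' @export
default_tier_map <- function() {
  c("very-low" = 0, "low" = 0.7, "moderate" = 0.8, "high" = 0.9)
}

#' Assign risk tiers to RF scores
#'
#' @param score numeric vector in [0, 1].
#' @param tier_map named vector of tier lower bounds (see
#'   [default_tier_map()]).
#' @return factor of tier names, ordered from lowest to highest risk.
#' @export
risk_tier <- function(score, tier_map = default_tier_map()) {
  if (any(score < 0 | score > 1)) stop_tf("scores must lie in [0, 1]")
  tier_map <- sort(tier_map)
  idx <- findInterval(score, unname(tier_map))
  factor(names(tier_map)[idx], levels = names(tier_map))
}

#' Stratify cases into risk tiers
#'
#' Per-tier LNM-negative/positive counts and the LNM percentage
#' (positives / tier size x 100). Empty tiers report an NA percentage, not
#' 0.
#'
#' @param scores numeric RF scores in [0, 1].
#' @param labels parallel labels, "negative"/"positive".
#' @param tier_map tier lower bounds (see [default_tier_map()]).
#' @return a `stratification_table` data.frame: `tier`, `lower`, `upper`,
#'   `n_negative`, `n_positive`, `lnm_pct`.
#' @export
stratify <- function(scores, labels, tier_map = default_tier_map()) {
  labels <- as.character(labels)
  tier <- risk_tier(scores, tier_map)
  tier_map <- sort(tier_map)
  neg <- as.vector(table(tier[labels == "negative"]))
  pos <- as.vector(table(tier[labels == "positive"]))
  tot <- neg + pos
  out <- data.frame(
    tier = names(tier_map),
    lower = unname(tier_map),
    upper = c(unname(tier_map)[-1L], 1),
    n_negative = neg, n_positive = pos,
    lnm_pct = ifelse(tot == 0L, NA_real_, 100 * pos / tot),
    stringsAsFactors = FALSE)
  class(out) <- c("stratification_table", "data.frame")
  out
}

#' Cohort prevalence of the positive label
#'
#' @param labels character/factor labels, "negative"/"positive".
#' @return fraction of positive cases.
#' @export
prevalence <- function(labels) {
  labels <- as.character(labels)
  mean(labels == "positive")
}

#' Pooled-variance Student t test
#'
#' Two-sided Student t with the pooled-variance estimator, computable
#' either from raw samples or from (mean, sd, n) summaries — the form
#' needed to test printed summary rows.
#'
#' @param x,y raw numeric samples (ignored when summaries are given).
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
two_group_t <- function(x = NULL, y = NULL,
                        mean1 = NULL, sd1 = NULL, n1 = NULL,
                        mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2L || length(y) < 2L) stop_tf("need n >= 2 per group")
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2L || n2 < 2L) stop_tf("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_tf("degenerate test: zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fisher exact test and odds ratio for a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (tables with point
#' probability at most that of the observed table), and the sample odds
#' ratio ad/bc. If any cell is zero the Haldane-Anscombe correction (+0.5
#' to every cell) is applied to the odds ratio, flagged in the result; the
#' p-value is always computed on the uncorrected counts.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or the four counts
#'   a, b, c, d (row-wise).
#' @return list with `odds_ratio`, `p`, `corrected` (logical).
#' @export
fisher_or <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) stop_tf("counts must be non-negative integers")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop_tf("degenerate table: a margin is zero")
  }
  p <- stats::fisher.test(tab)$p.value
  corrected <- any(tab == 0L)
  ct <- if (corrected) tab + 0.5 else tab
  list(odds_ratio = (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1]),
       p = p, corrected = corrected)
}

#' Write a stratification table and ROC curve as CSV
#'
#' @param strat a `stratification_table`.
#' @param roc a `roc_data`.
#' @param dir output directory.
#' @export
write_evaluation <- function(strat, roc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(strat), file.path(dir, "stratification.csv"),
            row.names = FALSE)
  write.csv(data.frame(threshold = roc$thresholds,
                       sensitivity = roc$sensitivity,
                       specificity = roc$specificity),
            file.path(dir, "roc.csv"), row.names = FALSE)
  invisible(dir)
}
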