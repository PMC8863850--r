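## Independent brute-force oracles used to check the package's operations.
## These deliberately recompute everything naively and share no code with
## the implementation.

## AUC as the Mann-Whitney concordance probability by explicit pair
## enumeration (ties count 1/2).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

## Two-sided Fisher exact p by hypergeometric enumeration over all tables
## with the observed margins; tables with point probability <= observed
## (within a relative epsilon, as the usual convention) are summed.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Naive recomputation of the 18 case features straight from a tile list.
oracle_case_features <- function(location_group, p_cancer, p_met,
                                 met_cutoff = 0.5) {
  n <- length(p_met)
  grp <- character(n)
  for (i in seq_len(n)) {
    p <- p_met[i]
    grp[i] <- if (p < 0.1) "A" else if (p <= 0.2) "B" else if (p < 0.8) "C" else if (p <= 0.9) "D" else "E"
  }
  met <- p_met > met_cutoff
  sdn <- function(x) if (length(x) <= 1) 0 else sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  mn <- function(x) if (length(x)) sum(x) / length(x) else 0
  c(location_code = location_group,
    n_cancer_tiles = n,
    n_met_tiles = sum(met), n_nonmet_tiles = sum(!met),
    n_groupA = sum(grp == "A"), n_groupB = sum(grp == "B"),
    n_groupC = sum(grp == "C"), n_groupD = sum(grp == "D"),
    n_groupE = sum(grp == "E"),
    pct_met = 100 * sum(met) / n, pct_nonmet = 100 * sum(!met) / n,
    mean_p_cancer = mn(p_cancer),
    mean_p_met_of_met_tiles = mn(p_met[met]),
    mean_p_nonmet_of_nonmet_tiles = mn(1 - p_met[!met]),
    sd_p_cancer = sdn(p_cancer),
    sd_p_met = sdn(p_met[met]),
    sd_p_nonmet = sdn(1 - p_met[!met]),
    probability_score_summary = sum(p_cancer * p_met))
}

## Small, fast cohort configuration for module tests.
small_cohort_config <- function(seed = 1L, n_cases = 120L, ...) {
  cohort_config(n_cases = n_cases, tiles_meanlog = log(40), tiles_sdlog = 0.5,
                seed = seed, ...)
}

## Scores/labels realizing given per-tier (negative, positive) counts,
## using tier midpoints.
tier_count_fixture <- function(counts) {
  mids <- c(0.35, 0.75, 0.85, 0.95)
  scores <- labels <- NULL
  for (i in seq_len(nrow(counts))) {
    scores <- c(scores, rep(mids[i], sum(counts[i, ])))
    labels <- c(labels, rep(c("negative", "positive"), counts[i, ]))
  }
  list(scores = scores, labels = labels)
}
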