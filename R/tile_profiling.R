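#' Select cancer tiles by cancer-class probability
#'
#' Keeps records whose `p_cancer` strictly exceeds the cutoff. Two cutoffs
#' are used in the pipeline: 0.8 when selecting high-confidence tiles to
#' train the LNM tile classifier, and 0.5 when selecting the tiles that
#' enter case scoring. Order is preserved; an empty result is allowed.
#'
#' @param records data.frame with a `p_cancer` column.
#' @param cutoff strict lower cutoff (default 0.5).
#' @return the filtered subset of `records`.
#' @export
select_cancer_tiles <- function(records, cutoff = 0.5) {
  stopifnot("p_cancer" %in% names(records))
  out <- records[records$p_cancer > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign metastatic-probability groups A--E
#'
#' Partitions the metastatic probability `p_met` into the five reporting
#' groups: A, confident non-metastatic (non-metastatic probability > 0.9,
#' i.e. `p_met` < 0.1); B, non-metastatic probability between 0.8 and 0.9;
#' C, neither probability reaches 0.8 (the unconfident middle); D,
#' metastatic probability between 0.8 and 0.9; E, metastatic probability
#' > 0.9.
#'
#' Boundary ties at 0.1/0.2/0.8/0.9 are not fixed by the group definitions;
#' with the default `boundary = "extreme"` the closed boundaries belong to
#' the more extreme informative groups (B and D: `0.1 <= p <= 0.2` is B,
#' `0.8 <= p <= 0.9` is D). `boundary = "central"` flips the four ties into
#' A/C/C/E for sensitivity analysis.
#'
#' @param p_met numeric vector of metastatic probabilities in [0, 1].
#' @param boundary `"extreme"` (default) or `"central"` tie convention.
#' @return factor with levels A--E.
#' @export
assign_group <- function(p_met, boundary = c("extreme", "central")) {
  boundary <- match.arg(boundary)
  if (any(is.na(p_met)) || any(p_met < 0 | p_met > 1)) {
    stop_tf("p_met must lie in [0, 1]")
  }
  g <- if (boundary == "extreme") {
    ifelse(p_met < 0.1, "A",
    ifelse(p_met <= 0.2, "B",
    ifelse(p_met < 0.8, "C",
    ifelse(p_met <= 0.9, "D", "E"))))
  } else {
    ifelse(p_met <= 0.1, "A",
    ifelse(p_met < 0.2, "B",
    ifelse(p_met <= 0.8, "C",
    ifelse(p_met < 0.9, "D", "E"))))
  }
  factor(g, levels = c("A", "B", "C", "D", "E"))
}

#' Tile-probability histogram profile by LNM class
#'
#' Bins the metastatic probabilities of tile records into fixed-width bins
#' (default width 0.01) separately for tiles of LNM-negative and
#' LNM-positive cases, and reports the modal bin of each class — the
#' per-class "most frequent tile probability".
#'
#' @param records data.frame with `p_met` and `lnm_label`
#'   ("negative"/"positive").
#' @param bin_width histogram bin width in probability units.
#' @return a `probability_profile`: list with `bins` (data.frame:
#'   `bin_lo`, `bin_hi`, `n_negative`, `n_positive`) and `modes` (named
#'   numeric vector of modal-bin lower edges per class).
#' @export
build_profile <- function(records, bin_width = 0.01) {
  stopifnot(nrow(records) > 0L, all(c("p_met", "lnm_label") %in% names(records)))
  n_bins <- ceiling(1 / bin_width)
  ## half-open bins [lo, hi), last bin closed at 1
  idx <- pmin(floor(records$p_met / bin_width) + 1L, n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  counts <- function(cls) tabulate(idx[records$lnm_label == cls], n_bins)
  bins <- data.frame(bin_lo = lo, bin_hi = pmin(lo + bin_width, 1),
                     n_negative = counts("negative"),
                     n_positive = counts("positive"))
  modes <- c(negative = if (any(bins$n_negative > 0)) lo[which.max(bins$n_negative)] else NA_real_,
             positive = if (any(bins$n_positive > 0)) lo[which.max(bins$n_positive)] else NA_real_)
  structure(list(bins = bins, modes = modes, bin_width = bin_width),
            class = "probability_profile")
}

#' Write a probability profile as CSV
#'
#' @param profile a `probability_profile`.
#' @param path output CSV path.
#' @export
write_profile <- function(profile, path) {
  write.csv(profile$bins, path, row.names = FALSE)
  invisible(path)
}
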