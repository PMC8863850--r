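---
title: "tileforest: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tileforest: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tileforest` predicts lymph-node metastasis (LNM) of T1 colorectal cancer
at the case level from tile-level image probabilities. This vignette
documents the model, every tunable parameter that matters, the synthetic
data the package tests itself on, and the design choices made where the
procedure was genuinely under-determined.

## The two-stage model

**Stage 1 — tiles.** A slide raster is tessellated into non-overlapping
squares of `tile_size = 299` px (273 µm at the default scale of 273/299
µm/px, overridable per slide). Partial edge strips are dropped: squares
cannot cover a remainder, and padding would fabricate tissue. A tile
enters analysis only if the minimum of its 8-bit gray conversion is at
most `threshold = 110` — one sufficiently dark pixel proxies one nucleated
cell. Gray conversion uses the standard luminance weights
(0.299, 0.587, 0.114) so results are bit-stable across image readers.
Whether a minimum of exactly 110 keeps or rejects a tile is not fixed by
the rule's usual phrasing; we keep it (≤, boundary inclusive) since a
pixel at the threshold is exactly as dark as the rule demands.

Two tile classifiers act on kept tiles. Classifier #1 assigns
probabilities over 10 tissue classes; its cancer-class probability
p(cancer) gates everything downstream. Classifier #2 is trained on tiles
with p(cancer) > 0.8 — strictly, following the stated cutoff wording —
each weakly labeled with its case's LNM outcome, and emits a per-tile
metastatic probability p~met~. Cases in which no cancer tile is detected
cannot be scored and are flagged as excluded between the classification
and feature stages.

**Stage 2 — cases.** Cancer tiles for scoring are those with
p(cancer) > 0.5 (strict). Each case is summarized into 18 features:
location group (ordinal 1/2/3 — one-hot encoding would break the
18-parameter arithmetic), counts of cancer/met/non-met tiles, counts of
probability groups A–E, met/non-met percentages, mean p(cancer), mean
p~met~ of met-predicted tiles and mean p~nonmet~ of non-met-predicted
tiles, the three corresponding standard deviations, and the probability
score summary PSS = Σ p(cancer)·p~met~. The most direct reading of the
published parameter list enumerates 17 items; we resolve the 18th slot as
the group-C count, which completes the A–E partition. The feature order is
data-driven (`feature_names()`), so an alternative enumeration is a
one-line change.

Groups are defined on p~met~: A < 0.1, B [0.1, 0.2], C (0.2, 0.8),
D [0.8, 0.9], E > 0.9. The four boundary ties are not fixed by the group
definitions; the default assigns them to the informative extreme groups
(B/D closed), which keeps the A↔E/B↔D mirror symmetry exact, and
`boundary = "central"` flips them for sensitivity analysis. The met /
non-met split point for counting is p~met~ > 0.5 (the split is nowhere
stated; it is configurable). "Summarized for case" in the PSS definition
is read as a sum — a mean is already represented by other features —
and is likewise configurable.

The case model oversamples LNM-positive cases with replacement to class
parity (the clinical imbalance is ~10:1), fits `n_candidates = 500`
random forests of `n_trees = 60` trees with `depth = 6` differing only by
seed, keeps the `top_k = 20` by selection AUC, and scores a case by the
**maximum** member probability. Selection AUC is computed on the original
unbalanced training cases, not the oversampled table — duplicated
positives would otherwise inflate it; out-of-bag selection is available
(`selection = "oob"`). Ties in the top-k are broken by seed order, and
the default tuning grid is depth 3–10 × trees {20, 40, 60, 80, 100} with
validation ties broken toward the smaller model. Scores map to risk tiers
[0, 0.7) very-low, [0.7, 0.8) low, [0.8, 0.9) moderate, [0.9, 1] high
(half-open, top tier closed — the published tier notation carries no tie
rule). The balanced-error cutoff (threshold where sensitivity equals
specificity, ties to the lower threshold) is the accuracy-reporting
operating point; the clinical model's published operating point, 0.70, is
exposed as `default_decision_cutoff()`.

## Reference tile classifier

The heavy pretrained convolutional backbone used clinically is a
pluggable alternative behind `classify_tiles()`, not a dependency. The
reference model is a single-hidden-layer network (default 32 units)
trained by minibatch SGD (learning rate 0.02, batch 32, momentum 0.9,
weight decay 1e-4, per-epoch learning-rate decay 0.98, 120 epochs) on a
tile representation built from the block-averaged image at
`input_px = 24`: the *sorted* pixel values (the gray-level distribution
as order statistics, invariant to where texture elements happen to sit)
plus horizontal/vertical gradient energies. Features are standardized
with a floor of 0.01 on the per-feature scale so near-constant features
(e.g. the blank background class) cannot blow up. The weights returned
are those with the lowest training loss seen across epochs, so a late
SGD bounce out of a good optimum cannot degrade the fit; cross-entropy
loss and accuracy are logged per epoch. Train/validation splits for
classifier #2 are stratified by case, never by tile, to avoid leakage.
A single run seed fixes initialization and data order, so training is
exactly reproducible.

## Synthetic data: what it emulates, and what it does not

`generate_cohort()` draws case labels at `prevalence = 0.078`, the
published cohort rate, and tumor locations from the published 3-group
frequencies (negatives 193/138/174, positives 10/9/24 — rectal
enrichment among positives). Per-tile metastatic probabilities follow a
two-level hierarchy: a case-level mean drawn around the class-conditional
mode (0.53 LNM-negative, 0.73 LNM-positive — the published modal tile
probabilities of the training set), then truncated-normal tile draws
around that mean. Truncated normals (not betas, truncation by
resampling) match the approximately normal probability histograms
observed per class. Tiles per case are log-normal (meanlog 6.7, sdlog
0.7, mean ≈ 1040 — consistent with ~840k scored tiles over ~780 cases),
and p(cancer) ~ Beta(6, 1.5), skewed toward 1 as expected for tiles that
already passed a cancer filter.

Two spreads are not published and are package choices, made once: the
within-case tile sd is 0.12, which reproduces the heavy group-C mass of
the probability profiles, and the between-case sd of the case mean is
0.08, which produces case-feature spreads on the scale of the published
summary table and a training-AUC regime comparable to the clinical
model's. These are calibration knobs of the generator, not measured
values.

The texture generator (`generate_tissue_tiles()`) renders each of the 10
tissue classes as a flat background with darker procedural disk blobs
plus pixel noise. Classes are separable by construction; no attempt is
made at nuclear or glandular morphology, stain variation, or scanner
artifacts. Consequently, passing classifier tests demonstrate that the
training harness and contracts work — they say nothing about accuracy on
real H&E tiles, and the published clinical accuracies (0.980 / 0.920 /
0.740) and AUCs (0.971 / 0.760) are not reproducible without the
clinical cohort.

## Numerical choices and degenerate inputs

* AUC is the trapezoidal integral of the ROC over all observed
  thresholds (rule: positive when score ≥ t), which equals tie-corrected
  Mann–Whitney concordance; the test suite asserts equality against pair
  enumeration and against an independent ROC implementation.
* The Fisher exact p is two-sided by hypergeometric enumeration (tables
  with point probability ≤ observed — conventions differ, this is the
  common one). The odds ratio is the sample ad/bc; zero cells get the
  Haldane–Anscombe +0.5 correction, flagged, while p is always computed
  on uncorrected counts. The Student t is the pooled-variance form and
  accepts (mean, sd, n) summaries so printed table rows can be tested.
* Standard deviations of case features use the sample (n−1) convention;
  a single tile yields sd 0. Empty met / non-met subsets yield mean 0 by
  convention. An empty tile set yields PSS 0 with a warning; a case with
  zero cancer tiles raises a classed excluded-case condition.
* Empty risk tiers report an NA percentage, never 0.
* Tile grids are 0-based, row-major, with half-open pixel intervals;
  the tiling is an exact partition of the cropped ⌊W/s⌋×⌊H/s⌋ grid.
* Slide maps draw metastatic-predicted cancer tiles on a red ramp and
  the rest of the cancer tiles on a green ramp, brightness linear in the
  winning probability from 0.25 at p = 0.5 (darkest visible shade, so
  direction stays readable — the published figures do not specify the
  transfer function) to 1.0; non-tumor tiles are fixed gray and rejected
  tiles keep the background color.

## Problem sizes used in the tests

The packaged checks run the full pipeline at 600 cases (≈ 0.6 M tiles)
over 5 seeds for signal recovery (held-out AUC ≥ 0.80) with
label-shuffled nulls asserted at chance level on the mean over seeds —
an individual 180-case held-out split holds only ~14 positives, giving a
null-AUC standard deviation of ~0.08 by the Mann–Whitney variance
formula, so the per-seed value is too noisy to test a ±0.1 band fairly.
The texture classifier check uses 100 tiles per class at 96 px (the
generator's per-area blob densities make 299-px tiles equivalent but
slower to render) and requires ≥ 0.90 held-out accuracy. Property suites
(feature conservation vs a naive oracle, AUC vs pair enumeration, Fisher
vs enumeration, group partition/symmetry) run at 1000 random cases and
all small score-set shapes.

## Known limitations

* The reference classifier is a texture-statistics model; swap in a CNN
  behind `classify_tiles()` for real histology.
* Forest candidates differ by seed only; bagging/feature-subsampling
  randomness is inherited from the forest implementation.
* The max-over-members RF score is deliberately anti-conservative (it
  was chosen clinically to suppress false negatives); calibrated
  probabilities are out of scope.
* Pyramidal WSI formats are supported only through level-0 rasters
  supplied as PNG/TIFF matrices; no native pyramid reader is bundled.
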