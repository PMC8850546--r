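---
title: "Methods: window encoding, feature ranking and score fusion for serine phosphosite prediction"
author: "phosfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window encoding, feature ranking and score fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfuse)
```

## The prediction problem

Serine phosphorylation is among the most common post-translational
modifications in eukaryotes, and the local sequence context of a serine
carries much of the signal that determines whether a kinase will
phosphorylate it. `phosfuse` frames site prediction as binary classification
of peptide windows: every serine in an annotated protein is a candidate
site, experimentally annotated phosphoserines are positives, and — following
standard practice in the phosphoproteomics literature — all remaining
serines in the same proteins are treated as negatives. This "rest are
negatives" convention is imperfect (some negatives are merely unobserved
positives) and is one reason evaluation focuses on ranking metrics and a
controlled false-positive-rate operating point rather than raw accuracy.

## Windows

Each candidate site is represented by a (2w+1)-mer peptide centered on the
serine; the default half-width is `w = 12` (25-mers), a window size in the
middle of the range this family of predictors typically uses and large
enough for the per-position enrichment statistics (below) to show flanking
signal. Sites within `w` of a terminus are padded with the gap symbol `O`,
treated as a 21st residue letter throughout, so that every window has
identical length and the positional encodings stay aligned. Windows are
never discarded for being near a terminus — doing so would silently change
the class counts. Windows containing ambiguity codes (B, J, U, X, Z) are
excluded with a warning because the encoders are defined over the fixed
21-letter alphabet.

Coordinates are 1-based in every file format and user-facing structure;
0-based arithmetic is internal only.

## Class balance

Phosphosite corpora are heavily imbalanced (tens of thousands of negative
serines against a few thousand positives). `subsample_ratio()` builds
training sets at a controlled 1:r ratio by keeping all positives and
sampling `r * n1` negatives uniformly without replacement; the default
workflow uses 1:2, which keeps training tractable while retaining a
representative negative sample. Train/test separation is done at the
protein level (`split_proteins()`), never at the window level, so windows
from one protein cannot straddle the split.

## The three encoders

* **CKSAAP** (composition of k-spaced amino acid pairs): for every gap
  `k = 0..5` and every ordered pair over the 21-letter alphabet, the count
  of positions `i` with `pep[i] = a`, `pep[i+k+1] = b`, normalized by the
  number of k-spaced pairs in the window, `L - k - 1`. This yields
  `441 * 6 = 2646` features for a 25-mer; each per-k block of 441 features
  sums to exactly 1, which the tests assert. The normalizer `L - k - 1` was
  chosen over alternatives (window length, constant) precisely because it
  makes each block a proper composition — a testable property. The central
  serine participates in pair counting (the encoder acts on the whole
  fragment), and pairs involving the padding symbol are counted: terminal
  proximity is real signal.
* **Binary** (positional one-hot): each of the 2w flanking positions
  contributes a 21-long one-hot block; the invariant central serine is
  skipped, giving `21 * 24 = 504` features for a 25-mer.
* **AAC** (amino acid composition): relative frequency of the 20 standard
  residues over the flanks only, gap symbol excluded from numerator and
  denominator; an all-gap flank (impossible for real sequences, possible
  for degenerate input) returns a zero vector with a warning rather than
  0/0.

Feature names are stable and self-describing (`k2|RS`, `p-3|R`, `aac|P`)
so that selected-feature lists stored in a model are portable across
sessions.

## Feature ranking

Features are ranked by the two-group Kruskal-Wallis H statistic (mid-ranks
for ties, standard tie correction, chi-square p with 1 df). With two groups
this is equivalent to a Wilcoxon rank-sum test up to the approximation; it
is used purely as a ranking device, so no multiple-testing correction is
applied. The implementation is vectorized over matrix columns for speed and
is checked against `stats::kruskal.test` column-by-column in the test
suite. Ranking is by H descending with ties broken by original column
index, making selection fully deterministic. Defaults keep the top 1500 of
2646 CKSAAP features and 400 of 504 binary features; AAC's 20 features pass
through unselected. A constant feature gets `H = 0, p = 1` rather than an
error, since encoder matrices routinely contain all-zero columns.

## Classifier backends and fusion

One classifier per encoder, sharing a `[0, 1]` probability-like score
contract:

* **RF** — probability random forest (`ranger`), 500 trees by default,
  seeded and single-threaded for reproducibility.
* **ADA** — discrete AdaBoost over depth-1 `rpart` stumps (100 rounds by
  default); the additive margin is mapped through the logistic link
  `1 / (1 + e^{-2F})`.
* **SVM** — RBF-kernel `e1071::svm` with Platt-calibrated probabilities,
  so its scores live on the same scale as the tree ensembles.

The fused score is the convex combination

```
fused = w1 * score_CKSAAP + w2 * score_Binary + w3 * score_AAC,  w1+w2+w3 = 1
```

with weights proportional to each encoder's standalone performance, so the
strongest encoder (typically CKSAAP or binary) dominates without silencing
the others. The default performance measure is an internal resampling AUC:
for random forests the out-of-bag predictions provide this estimate at no
extra cost; for the other families an internal 3-fold CV is run inside the
training set. Training-set AUC and fully manual weights are available as
alternatives (`weights = "train"` / `"manual"`), since reasonable
implementations differ on this point; internal-resampling weights are the
default because training-set AUC saturates near 1 for flexible learners and
stops discriminating between encoders.

## Evaluation at a fixed false positive rate

Reported operating-point metrics (TPR, TNR, FNR, ACC, MCR, MCC) are
computed at the smallest threshold whose empirical FPR does not exceed a
cap, 0.20 by default. Prediction is strict (`score > threshold`), and tied
scores are grouped all-or-none so the cap is never exceeded — a
conservative choice that keeps TNR at least `1 - cap` by construction. MCC
is defined as 0 when a confusion-matrix margin is empty. The ROC curve is
swept over all distinct scores with tie grouping; AUC uses the trapezoid
rule and pAUC is the unnormalized trapezoid area over FPR in `[0, cap]`
with linear interpolation at the cap, so a perfect classifier attains
`pAUC = cap` and `pAUC(cap = 1) = AUC`. Unnormalized pAUC was chosen over
McClish standardization because its value is directly interpretable
against the cap.

`kfold_cv()` runs the full pipeline — encoding, Kruskal-Wallis selection,
backend training, weight derivation — inside each of k label-stratified
folds, refit on the k-1 training folds only. Feature selection inside the
fold is essential: selecting on the full matrix before CV leaks the
held-out labels into the feature set and inflates every metric. The
chance-level calibration test (signal-free generator data must give CV AUC
statistically indistinguishable from 0.5) guards exactly this failure
mode.

## Two-sample logo statistics

`tsl_test()` compares, for every flank offset and residue, the frequency
of that residue between positive and negative windows, using either a
two-proportion test on counts (normal approximation on the pooled
proportion; the default, and the more accurate choice for proportions) or
a Welch t-test on the 0/1 indicators. Cells are marked enriched/depleted
at a per-cell alpha of 0.05 with no multiple-testing correction — the
output is a diagnostic logo, not an inference; the padding symbol is
tested too (terminal proximity is informative) and can be masked. The
logo matrix export feeds standard logo-rendering tools; rendering itself
is out of scope.

## The synthetic proteome generator

Real phosphosite corpora require external downloads and redundancy
reduction, so the package carries a generator that emulates the *shape* of
such data: proteins of uniform random length 200-600, i.i.d. residues with
serine planted at rate 0.08, 10% of serines designated positive, and two
kinds of planted flank signal in positive windows —

* positional enrichment: by default arginine at offset -3, proline at +1
  and leucine at +4, each at probability 0.35 against a 0.05 uniform
  background (loosely evoking basophilic and proline-directed kinase
  motifs). The planting rule draws the enriched residue with exactly the
  configured probability, so empirical frequencies converge to the
  configuration — a law-of-large-numbers test asserts this.
* pair-composition signal: one k-spaced ordered pair (`KE` at k = 1, `GD`
  at k = 3) written at a random in-window offset with probability 0.75 per
  positive window. Because the offset is random, this signal is visible to
  the pair-composition encoder but only weakly to the positional one,
  which is what the encoder-ablation test exploits.

Pair injection happens before positional planting so positional
frequencies take precedence on overlap; planting never overwrites a
designated positive center, and the serine inventory is recomputed after
planting so site tables always match the emitted sequences. Effect sizes
were fixed once so that the fused random-forest 5-fold CV AUC on the
default corpus sits near 0.9 — a realistic regime for this class of
predictor — with the positional probability held at 0.35 and the pair
probability calibrated to 0.75.

What the generator does **not** emulate: realistic amino-acid background
composition, kinase-family motif structure, homology between proteins, or
label noise from unobserved positives. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers the kinds of signal its
encoders are designed for, not that any particular real-proteome accuracy
will be achieved.

## Problem sizes and numerical choices

The default synthetic study uses 300 proteins (~960 positive windows,
1:2 ratio, ~2900 training windows), 5-fold CV, random forests of 500
trees — sizes chosen so a full CV run completes in about two minutes on a
single core while keeping per-fold class counts in the hundreds. Smaller
corpora are used for chance-calibration runs where only the null level
matters. All randomness flows through explicit integer seeds; fold
assignment, negative subsampling, forest growth and the generator are each
deterministic given theirs. Ties in ranking and selection break toward the
lower column index; thresholds under the FPR cap group tied scores; the
KW tie correction handles constant features by returning `H = 0` instead
of dividing by zero.

## Known limitations

* The negative class is defined by absence of annotation; real corpora
  carry label noise the synthetic generator does not model.
* The AdaBoost backend fits stumps through `rpart` per round and is the
  slowest family at high feature counts; it is intended for moderate
  feature budgets.
* Exact-duplicate filtering (`dedup_exact()`) is not a substitute for
  similarity-based redundancy reduction; users should cluster their
  sequences (e.g. at 30% identity) upstream if over-optimistic evaluation
  is a concern.
* The two-proportion normal approximation in `tsl_test()` is inaccurate
  for very rare residues at small n; such cells are usually forced to
  `ns` anyway.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_proteome(generator_config(seed = 1))
ws  <- subsample_ratio(extract_windows(sim$proteins), ratio = 2, seed = 1)
cv  <- kfold_cv(ws, k = 5, seed = 1, family = "RF")
cv
tsl <- tsl_test(ws)
head(tsl[tsl$direction == "enriched", ], 10)
```
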