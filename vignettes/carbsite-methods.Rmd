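---
title: "Methods and modelling choices in carbsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in carbsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbsite)
```

`carbsite` predicts protein carbonylation sites — an irreversible oxidative
modification of K, R, T and P side chains — from the sequence context of a
candidate residue. This vignette documents the model, every place where a
methodological convention had to be fixed, and why each choice was made.
The user-facing walkthrough lives in the README; this document is the
reference for anyone auditing or extending the method.

## Problem framing

Prediction is residue-type specific: a model is trained per residue type
(K, R, T or P) because the local sequence preferences around, say, a
carbonylated lysine differ from those around a carbonylated proline. A
candidate site is represented by a window of `2n + 1` residues centred on
it, with `n` treated as a tunable half-width in 5..13. Positions that fall
outside the protein are padded with the dummy residue `X`, which every
encoder treats as "no information" (zero physicochemical block, skipped in
distances, a 21st alphabet state in counts).

## Dataset preparation

Three rules define the negative class (`enumerate_candidates()`):

1. same residue type as the positives,
2. not itself annotated as a positive site,
3. located in a protein that carries at least one annotation from a source
   that assayed this residue type (so unassayed proteins or proteins only
   covered by studies of other residue types cannot contribute
   false "negatives").

Windows are then deduplicated by a greedy 30% identity filter
(`reduce_redundancy()`): windows are visited in a deterministic order and
kept only if their positional identity to every kept window is at most the
threshold. An in-package greedy filter replaces external clustering tools so
that the pipeline has no system dependencies; the test suite checks it
against a brute-force re-implementation.

**Deduplication scale.** Identity filtering is performed on ±13 windows
(`dedup_n = 13`) regardless of the working half-width, and the working-`n`
windows are cut from the surviving sites afterwards. At small `n` the
windows are so short that chance identity between unrelated sites routinely
exceeds 30% (four matches in eleven positions), and filtering at working
width would discard most of the positive class at `n = 5` while keeping it
at `n = 13` — making the dataset size a function of the sweep parameter.
Fixing the deduplication scale at the maximum half-width keeps the retained
site set constant across the sweep, which is the behaviour a width sweep
needs to be interpretable.

Negatives are sampled (seeded, `sample_negatives()`) at about six times the
positive count: enough to preserve the class imbalance the weighted SVM is
designed for, small enough to keep the quadratic-cost encoders tractable.

## Feature encoders

At half-width `n` the four families contribute
`2n + n(2n−1) + 2 + 5 + 16n` candidate features
(`candidate_dimension()`; 566 at `n = 13`).

### Position-specific propensities

From the training windows (centre excluded), class-wise count matrices are
accumulated for single residues per flank position (21 × 2n) and for
ordered residue pairs over all position pairs p < q (441 × n(2n−1)). The
propensity score of cell (i, j) is the positive-minus-negative count
difference divided by a per-column standard deviation.

**Scaling convention.** The divisor is the population standard deviation of
column j of the *difference* matrix, floored at 1e-6 so that columns with
no class contrast score zero rather than dividing by zero. Scaling by the
positive-count column instead is available as `sigma_mode = "positive"`,
and raw counts can be replaced by per-class relative frequencies
(`frequency_mode = "relative"`); the defaults are what the shipped pipeline
uses, and the alternatives exist so the sensitivity of results to this
convention can be measured rather than argued about.

### Increments of k-mer diversity

For a count vector over a state space, `D = N log N − Σ nᵢ log nᵢ`
(`diversity_measure()`), and the increment of diversity between two sources
is `ID(X, Y) = D(X+Y) − D(X) − D(Y)` — non-negative, symmetric, and small
when the sources are compositionally similar. Each window yields two
features (k = 1 over 21 states, k = 2 over 441 states): the increment
against the negative training pool minus the increment against the positive
pool, so larger values mean "more positive-like".

**k-mer convention.** The centre residue is excluded by concatenating the
two flanks before counting, so one 2-mer spans the seam between the
upstream and downstream flank. The alternative (counting flanks separately)
discards one pair observation per window; with only 441 states informing
two features, the difference is negligible, and the concatenated form keeps
the count vector a function of a single string.

### KNN scores

The distance between two equal-length windows is one minus the mean
BLOSUM62 similarity over aligned positions, with the similarity min-max
normalized to [0, 1] by the matrix's global range (−4, 11); positions
involving `X` are skipped, and all-`X` comparisons default to distance 1.
For k in {11, 21, 31, 41, 51} the feature is the fraction of positive
windows among the k nearest training references. Training windows are
scored leave-one-out: a window never counts itself as a neighbour
(`exclude_self` in `assemble_features()`), which the test suite verifies as
an anti-leakage property. Ties at equal distance resolve by a deterministic
reference ordering (window string, then protein id, then position) so
results are platform-independent.

### Physicochemical profile (HQI8)

Eight consensus AAindex indices — electric property, hydrophobicity,
alpha/turn propensity, volume, two composition indices, beta propensity and
a contact energy — are min-max normalized over the 20 standard residues and
looked up per flank position (8 × 2n features). `X` contributes a zero
block. Index values are taken from the `seqinr` AAindex table rather than
transcribed by hand; the accessions are recorded in `HQI8_ACCESSIONS`.

## Feature selection

Features are discretized into three bins at mean ± population sd (constant
columns collapse to one bin) and ranked by the greedy mutual-information
difference (MID) form of mRMR: the first feature maximizes MI with the
label; each next feature maximizes relevance minus its mean MI with the
already-selected set. Mutual information is the plug-in estimate in natural
logarithms. Ties break toward the smaller feature index, making rankings
deterministic.

Incremental feature selection then evaluates ranking prefixes: for each
prefix size k, a stratified cross-validation is run and the mean per-fold
MCC recorded; the chosen dimension is the curve's argmax (smallest k on
ties). "Average MCC" is deliberately the per-fold mean — the selection
criterion should reward consistency across folds — while the headline
evaluation metrics use the spliced convention described below.

## Classifier and evaluation

The classifier is an RBF-kernel soft-margin SVM (`e1071`, the libsvm
engine) with cost 1, gamma `1/d`, and the positive class weighted by the
negative:positive count ratio, so the imbalanced training set does not
collapse sensitivity. Features are min-max scaled with parameters learned
on the training rows only. Probability calibration is enabled; its internal
shuffling is seeded, so training is reproducible.

Cross-validation is stratified k-fold (round-robin within class, seeded).
Critically, **every fold rebuilds the complete encoder context** —
propensity matrices, diversity pools, KNN references — from its own
training partition, because the encoders are themselves fit to data and
would otherwise leak the held-out labels. Held-out probabilities from all
folds are spliced into a single vector; accuracy, MCC and the ROC/AUC are
computed once on that vector (per-fold metrics are also reported). MCC is
defined as 0 when any confusion marginal is zero; AUC uses the
Mann–Whitney midrank statistic, which the tests pin against brute-force
pair counting and against `pROC`.

## Synthetic data generator

Restricted site annotations cannot be redistributed, so the package ships a
deterministic generator (`generate_fixture()`) that emulates the
statistical structure the analyses of real carbonylation data report:
flanks of positive sites are enriched for R/K/P/T with stronger enrichment
upstream than downstream, and a hydrophobic band sits at offsets −6..−2;
negative candidates of the target residue type arise from the background
composition of the same proteins. Default sizes mirror a realistic
K-type training scale (266 positives, a candidate pool supporting ~6x
negatives).

One generator subtlety is load-bearing: planted flanks never draw the
site's *own* residue type (the draw distribution zeroes it and
renormalizes, and the enrichment set excludes it). Otherwise the enriched
flanks of positive sites would be salted with target-type residues, and
those residues — being unannotated — would enter the candidate-negative
pool carrying positive-like context, destroying the very class contrast the
generator is documented to produce. With the exclusion in place, every
candidate negative sits in background-composition context as intended.

The generator's signal strength bounds what any classifier can achieve: at
the default boosts the Bayes-optimal AUC of the planted signal is roughly
0.88 for ±5 windows and 0.96 for ±10 windows (computable from the
generator's likelihood ratio). End-to-end tests that assert a high AUC
therefore run at `n = 10`; asserting, say, AUC > 0.9 at `n = 5` would test
an impossibility.

## Scope and limitations

- The propensity scaling and the k-mer seam convention are fixed choices
  among defensible alternatives; both are surfaced as configuration
  switches so their effect is measurable.
- The greedy identity filter is order-dependent by construction (as greedy
  clustering always is); the order is fixed and documented, not arbitrary.
- Plug-in mutual information is biased upward on small samples; since mRMR
  only compares features under the same estimator, the bias shifts scores,
  not (materially) the ordering.
- The curated human carbonylation benchmark used by two acceptance tests is
  not redistributable and must be supplied by the user under
  `inst/extdata/data_s2/` (residue-typed `training_*.tsv` /
  `testing_*.tsv` window tables readable by `read_windows_tsv()`).
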