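# carbsite

Residue-type-specific prediction of human protein carbonylation sites from
primary sequence.

Carbonylation is an irreversible oxidative post-translational modification
that predominantly hits lysine (K), arginine (R), threonine (T) and proline
(P) side chains. It marks proteins for degradation and accumulates in aging
and oxidative-stress-related disease, and it cannot be called from sequence
motifs alone: the signal lives in the composition and physicochemistry of the
residues flanking a candidate site. `carbsite` implements a full supervised
pipeline that learns that flanking signal, one model per residue type.

## Method

For each residue type, every annotated site becomes a positive example and
every other residue of the same type in the annotated proteins becomes a
candidate negative. Candidate windows of `2n + 1` residues (half-width `n`
between 5 and 13, dummy residue `X` padding protein ends) are deduplicated by
a greedy 30% sequence-identity filter, and negatives are sampled at ~6x the
positive count to keep training tractable while preserving the imbalance.

Each window is encoded by four feature families (566 candidate features at
`n = 13`):

1. **Position-specific propensities** (`2n` + `n(2n-1)` features): lookup
   matrices of class-difference counts of single residues per position and of
   residue pairs per position pair, each column scaled by its standard
   deviation.
2. **Increments of k-mer diversity** (2 features): for k = 1 and k = 2, how
   much more the window's k-mer counts resemble the positive pool than the
   negative pool, under the diversity statistic `D = N log N − Σ nᵢ log nᵢ`.
3. **KNN scores** (5 features): the fraction of positive training windows
   among the k nearest neighbours (k = 11, 21, 31, 41, 51) under a normalized
   BLOSUM62 distance, with leave-one-out exclusion for training windows.
4. **Physicochemical profile** (`16n` features): eight consensus AAindex
   properties (HQI8: charge, hydrophobicity, structural propensities, volume,
   composition, contact energy), min-max normalized, per flanking position.

Features are ranked by minimum-redundancy–maximum-relevance (mRMR, mutual
information difference scheme on 3-bin discretized features) and pruned by
incremental feature selection (IFS): the retained dimension is the peak of
the cross-validated mean Matthews correlation coefficient over ranking
prefixes. The classifier is a class-weighted RBF support vector machine
(positive class weighted by the negative:positive ratio) with calibrated
probability outputs. Evaluation uses stratified 10-fold cross-validation in
which every fold rebuilds the encoder tables from its own training partition
(no leakage), and the held-out probabilities of all folds are spliced into
one vector before computing Sp/Sn/Acc/MCC and the ROC AUC.

The package also ships the supporting analyses (per-position composition
t-tests, hydrophobicity profiles, feature-family distributions of selected
features), `ggplot2` autoplots for evaluations and IFS curves, tidyverse-style
`tidy()`/`glance()` methods, a deterministic synthetic-data generator for
end-to-end testing, and a command-line interface.

## Worked example

The synthetic generator plants an upstream-skewed R/P/T enrichment and a
hydrophobic band upstream of each positive site, so the pipeline can be
exercised end to end without restricted data. Everything below is actual
output.

```r
library(carbsite)

# 1. synthetic data with a planted carbonylation-like signal
fx <- generate_fixture(fixture_config(
  n_proteins = 60L, length_range = c(150L, 250L), n_positive = 80L, seed = 42
))

# 2. residue-specific dataset: candidate enumeration, redundancy
#    reduction, ~6x negative sampling, +/-7 windows
ds <- prepare_dataset(fx$proteins, fx$annotations, residue = "K", n = 7, seed = 42)
table(ds$label)
#> negative positive
#>      338       80

# 3. rank candidate features (mRMR) and choose a dimension (IFS)
ctx <- build_encoder_context(ds)
x   <- assemble_features(ds, ctx, exclude_self = TRUE)
rk  <- mrmr_rank(x, ds$label, max_rank = 40)
head(rk, 5)
#> # A tibble: 5 × 5
#>    rank feature name             relevance  score
#>   <int>   <int> <chr>                <dbl>  <dbl>
#> 1     1     107 div_k2               0.340 0.340
#> 2     2      76 psp_pair_p-2_p+6     0.206 0.0746
#> 3     3      27 psp_pair_p-7_p+7     0.233 0.102
#> 4     4      21 psp_pair_p-7_p+1     0.184 0.0941
#> 5     5      31 psp_pair_p-6_p-2     0.243 0.110

ifs <- ifs_select(ds, rk, k_values = c(1:10, 15, 20, 30, 40), folds = 5, seed = 42)
ifs
#> <carb_ifs> chosen dimension 10 (peak mean MCC 0.3559) over 14 evaluated sizes

# 4. spliced-probability cross-validation at the chosen dimension
ev <- cross_validate(ds, features = ifs$chosen_features, folds = 5, seed = 42)
ev
#> <carb_eval> 418 windows (80 pos / 338 neg)
#>   Sp 0.8609  Sn 0.5000  Acc 0.7919  MCC 0.3498  AUC 0.7643

# 5. final model + scoring candidate sites
model <- carb_train(ds, selection = "top_k", k = ifs$chosen_dimension, seed = 42)
model
#> <carb_model> residue K, n = 7, 10 selected features, positive weight 4.225

predict_probability(model, ds[1:5, ])
#> # A tibble: 5 × 5
#>   protein_id position residue probability call
#>   <chr>         <int> <chr>         <dbl> <lgl>
#> 1 FIXP029          17 K             0.988 TRUE
#> 2 FIXP019          83 K             0.969 TRUE
#> 3 FIXP022          15 K             0.985 TRUE
#> 4 FIXP031          50 K             0.998 TRUE
#> 5 FIXP028          80 K             0.972 TRUE
```

`autoplot(ev)` draws the ROC curve, `autoplot(ifs)` the IFS curve;
`save_model()` / `load_model()` archive a model with its full encoder
context, and `carb_predict_fasta()` scans every residue of the model's type
in a query FASTA.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "carbsite.R", package = "carbsite"))')" \
  fixture --seed 2 --out-dir demo_fixture
# train / predict / evaluate / rank analogously; see the usage line.
```

## Tests and reproduction

The test suite contains independent oracles (brute-force AUC/MCC/mutual
information, exhaustive greedy mRMR, brute-force redundancy filtering),
hand-computed worked examples for every encoder, property-based fuzz tests,
and an acceptance suite:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "carbsite", load_package = "installed")'
```

Two acceptance blocks exercise a curated human carbonylation benchmark
(residue-typed training/testing windows expected under
`inst/extdata/data_s2/`). That archive is not redistributable and is not
bundled, so those two blocks fail with a clear message on a bare checkout;
every other test passes without external data.

The deterministic acceptance evidence is reproduced with:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which recomputes the candidate feature dimension at `n = 13` (566 =
351 propensity + 2 diversity + 5 KNN + 208 physicochemical features) from the
installed package and writes it as JSON.

Methodological choices and their rationale (propensity scaling, diversity
k-mer conventions, deduplication scale, generator design) are documented in
`vignettes/carbsite-methods.Rmd`.
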