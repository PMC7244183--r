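---
title: "Taxon properties from co-occurrence embeddings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxon properties from co-occurrence embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

taxaprop learns low-dimensional *properties* of amplicon sequence variants
(ASVs) from how they co-occur across microbiome samples, and uses those
properties as a compact, transferable feature space for host-phenotype
classification and for interpretation against metabolic pathway annotations
and phylogeny. This vignette explains the model, the parameters that matter,
the synthetic data used to validate each stage, and the numerical and design
choices behind the implementation.

## The model

### Co-occurrence as the signal

A sample-by-ASV count table is reduced to presence/absence; two ASVs
*co-occur* when they are detected in the same sample. Aggregating over all
samples gives a symmetric matrix `X` where `X[i, j]` counts the samples
containing both ASVs, with the diagonal set to zero (self-pairs carry no
relational information). Per-ASV occurrence counts `occ[i]` define the
conditional co-occurrence probability `P(j|i) = X[i, j] / occ[i]`, which is
asymmetric in general and exposed for exploratory analysis.

One reading of "binary co-occurrence data" would binarize `X` itself; we
keep the graded shared-sample counts because the embedding objective's
weighting function is designed for counts, and per-sample presence/absence
already supplies the binary notion of detection. `build_cooccurrence(...,
binarize = TRUE)` (and the CLI flag `--binarize`) preserves the alternative
reading for sensitivity analyses.

Before counting, tables are filtered the way amplicon surveys usually are:
samples under a minimum read total are dropped first, then ASVs present in
fewer than `ceiling(fraction * n_samples)` of the remaining samples.
Typical settings are a 5,000-read floor with a 0.07% prevalence floor for
large crowdsourced gut datasets, and a 10,000-read floor with no prevalence
filter for smaller clinical cohorts; both are plain arguments to
`filter_table()`.

### The embedding objective

Properties are learned with the GloVe weighted least-squares factorization:
find per-ASV main vectors `w_i`, context vectors `w~_j` and biases such that

```
sum over ordered pairs (i, j), X[i,j] > 0 of
  f(X[i,j]) * (w_i . w~_j + b_i + b~_j - log X[i,j])^2
```

is minimal, with `f(x) = (x / x_max)^alpha` capped at 1. Two ASVs that are
detected with similar partner sets at similar rates end up close in the
learned space, including "synonym" pairs that rarely co-occur directly but
share neighborhoods. Each embedding dimension is a *property*: a latent axis
summarizing co-occurrence behavior, later interpretable through its pathway
correlations.

The cited method fixes only the objective family, so the standard choices
are adopted and exposed in `glove_config()`:

| parameter | default | role |
|---|---|---|
| `n_properties` | 100 | embedding dimension; sweeps of 50/100/250/500/750 are conventional, 100 is a robust middle for 16S gut data |
| `x_max` | 100 | count at which pair weight saturates at 1 |
| `alpha` | 0.75 | sub-linear growth of the weight for rare pairs |
| `learning_rate` | 0.05 | initial AdaGrad step |
| `n_epochs` | 50 | passes over the nonzero pairs |
| `init_scale` | `0.5/dim` | half-width of the uniform initialization |
| `seed` | 1 | drives initialization and per-epoch pair shuffling |

Optimization is AdaGrad stochastic descent over the nonzero unordered pairs,
each visited in both directions per epoch (the matrix is symmetric), in a
seeded shuffled order; the kernel is C++ but draws all randomness from R's
RNG, so a fixed `(X, config)` reproduces bitwise-identical models. The full
objective is recorded after every epoch (`loss_history`,
`autoplot(model)`), and a non-finite loss aborts with the offending epoch
rather than returning garbage. `glove_objective()`/`glove_gradient()`
evaluate the loss and its exact gradient at arbitrary parameters in plain R;
the test suite uses them for finite-difference verification and for a
monotone full-batch descent check, keeping the verification path independent
of the training kernel.

The final embedding is `w + w~` per ASV (`finalize_vectors(mode = "sum")`,
the canonical choice for a symmetric matrix); `mode = "main"` keeps `w`
alone since nothing in the application pins the convention. When an
embedding is trained for later classifier evaluation, `embed_table(...,
train_fraction = 0.85)` restricts co-occurrence counting to a seeded 85%
sample subset so held-out samples never inform the space.

### Projection, normalization, matching

A query table is projected by a plain dot product: sample property value =
abundance-weighted sum of its ASVs' property values. Abundances are first
stabilized with the inverse hyperbolic sine, `asinh(x) = log(x + sqrt(x^2 +
1))`, which tracks `log(2x)` closely for large counts but is defined and
equal to 0 at 0 — no pseudocount needed. Projection of raw counts stays
available (`--raw` in the CLI) because the training-side choice is not
dictated by the method.

Query ASVs must be identified with embedding ASVs before projection. The
matcher aligns each query against candidate references sharing an exact
11-mer, using local (Smith–Waterman) alignment with match +1 / mismatch -2
via Biostrings, reports identity = matches / alignment length, and converts
scores to Karlin–Altschul e-values (K = 0.41, lambda = 1.28, search space =
query length x total reference length). A hit must reach the identity
threshold (99% by convention; 97% and 100% are the usual sensitivity
settings) *and* beat the e-value ceiling (1e-29). The identity bound is
closed (`>=`), otherwise the 100% setting could never match anything.
Unmatched queries are dropped, matched ones renamed to their embedding ASV;
ties break by higher identity, lower e-value, then lexicographic reference
ID so results are deterministic.

PCA (`pca_transform()`) provides the standard ordination baseline at
matching dimensionality, retaining the rotation matrix so PCA components
can be pushed through the same interpretation machinery as properties.

### Classification

`tune_and_train()` grid-searches a random forest over number of trees, depth
and positive-class weight by cross-validated AUROC or AUPR, then refits the
best triple; 10-fold CV is the within-dataset default, 3-fold the
deploy-once convention (both just `rf_config(cv_folds = ...)`). Metadata
covariates append as extra features (100 properties + 13 covariates = 113
features), with missing values imputed as column medians. Splits are seeded,
stratified, and — crucial for longitudinal cohorts — grouped so that all
timepoints of a patient land on one side. Deployment evaluation keeps the
forest's default 0.5 threshold; a model that predicts no positives reports
precision = recall = 0 by convention. AUROC uses the midrank identity
(constant scores give exactly 0.5); AUPR integrates precision over recall
steps with ties handled as blocks (no pre-installed R package provides
PR-AUC, so it is implemented here).

### Interpretation

*Pathway correlations.* Property columns are standardized to mean 0 /
variance 1 over the ASVs shared with the pathway table, then Pearson-
correlated with each binary pathway column (standardization makes property
and PCA spaces comparable; Spearman is available since the estimator is
otherwise unpinned). Significance of each property's maximum absolute
correlation comes from jointly permuting the pathway table's rows 10,000
times; `p = (#{null >= observed} + 1) / (N + 1)`, Benjamini–Hochberg
adjusted across properties. The add-one convention is deliberate: the
attainable floor at 10,000 permutations is 1/10001 ≈ 9.999e-5, and a
reported minimum p at exactly that value is how a permutation test says
"beyond every null draw" without claiming zero. "All significantly
correlated pathways per property" needs a per-pathway cutoff the method
leaves open; we use each property's own null 95th percentile of maximum
correlations, a conservative bar that reuses the same null.

*Variance explained.* Per property, OLS of property values on all pathway
columns; `r^2 = 1 - RSS/TSS`. Under pure noise `r^2` concentrates near
`p/(n-1)`, which the tests verify; zero-variance properties report `NA`.

*Mantel test.* Property-by-property correlation distances (1 - Pearson r)
are computed twice — between property columns over ASVs, and between their
pathway-correlation vectors — and compared by a Mantel test: Pearson
correlation of lower-triangle entries, null from jointly permuting
rows/columns of the second matrix, one-sided add-one p. The permutation
engine is in-package for exact control of these conventions; vegan's
implementation serves as an independent cross-check in the tests.

*Association score.* To read direction of association out of the forest,
depth-2 trees (at most 3 split variables each) are trained across CV folds
and backtraced: every root-to-leaf path ending in a majority-case leaf adds
+1 to a split variable when the path took the greater-than branch and -1
for the less-or-equal branch, accumulated over all trees of all folds.
Properties with |score| >= 8 of consistent sign across datasets count as
consistently predictive, and a pathway significantly correlated with at
least 2 of them is flagged important; both thresholds are parameters, since
the counting rule is stated slightly differently in different places in the
method tradition this follows. The depth-2 reading of "split on 3
variables" is the default; `mode = "mtry_three"` keeps the alternative
(3 candidate features per split, unlimited depth). One caveat the
implementation makes explicit: on trees where one child is already terminal
at depth 1, the path census is not exactly antisymmetric under label
inversion — sign recovery is exact in practice (verified over 100 seeds),
numeric equality of mirrored scores is not guaranteed, and
`case_class = "0"` re-scores identical forests in the opposite orientation.

### Phylogeny comparison

`property_tree()` clusters ASVs agglomeratively (cosine distance, average
linkage by default) and emits the dendrogram as a rooted ultrametric
`phylo`: leaf branch = parent merge height, internal branch = difference of
merge heights. This conversion is spelled out because branch-score
distances are meaningless without a branch-length convention (note that
ape's `as.phylo.hclust` halves heights, which would silently rescale all
branch scores). ASVs are sorted by ID before clustering so duplicate rows
(distance 0) merge deterministically.

Tree similarity uses the branch score (Kuhner–Felsenstein; squared
branch-length differences over the union of bipartitions, square-rooted)
and the symmetric Robinson–Foulds count, both delegated to phangorn behind
validated wrappers and cross-checked in the tests against brute-force
bipartition dictionaries. The null shuffles the phylogeny's leaf labels
(geometry fixed, labels move) 1,000 times; because *small* distances mean
*similar* trees, the p-value is the lower-tail add-one count.

## The synthetic data generator

Real 16S cohorts cannot ship with a package, so every stage is validated on
communities with controlled latent structure (`synth_config()` and the
`generate_*` functions):

- Each sample activates each of `n_blocks` latent communities independently
  with probability 0.4 — overlapping communities, not clean clusters.
- ASVs of an active block are present with probability 0.9, all others with
  0.05 (`within/between_block_presence_prob`); counts given presence follow
  a truncated log-series (`theta = 0.95`), the classic heavy-tailed
  amplicon abundance shape.
- The pathway table follows the blocks with tunable fidelity: 1 reproduces
  block indicators, 0.5 is exactly independent — the calibration case for
  the permutation test.
- Labels are Bernoulli draws of a logistic model on the *continuous* latent
  activity of a designated disease block (the realized fraction of that
  block's ASVs present in the sample, standardized), with
  `label_effect_size` the log-odds per SD and `label_noise` extra Gaussian
  log-odds noise. The continuous latent score matters: a purely binary
  activation indicator caps attainable AUROC near 0.72 at effect size 2,
  which would make classifier-recovery checks uninformative about the
  pipeline rather than about the data.
- The phylogeny coalesces each block early and joins blocks on a long
  backbone; `tree_leakage` reassigns each ASV's tree position with the
  given probability (0 = perfect clades, 1 = topology unrelated to blocks).

All generators are pure functions of `(config, seed)`; stage sub-seeds are
fixed offsets of the config seed.

What the generator does **not** emulate: sequencing-depth variation and its
detection bias (absence in a shallow sample is treated like absence in a
deep one — a known limitation of presence-based co-occurrence), chimeras
and sequencing error, compositionality of relative abundances, phylogenetic
correlation of presence within blocks, and realistic pathway co-linearity.
Passing the synthetic checks therefore demonstrates that the machinery is
correct and calibrated, not that properties learned from any particular
real cohort are biologically meaningful.

## Verification design and problem sizes

The test suite asserts, among others: exact equality of co-occurrence
counting with a brute-force pair census; finite-difference agreement of the
embedding gradient (relative error < 1e-4) and monotone full-batch descent;
bitwise seed-reproducibility of training; recovery of two-block structure
(within-block mean cosine above between-block) in at least 95 of 100 seeded
runs at 500 samples x 300 ASVs with embedding dimension 10 over 10 epochs —
sizes chosen to make one run take well under a second while leaving the
recovery margin wide; property-space classifiers reaching test AUROC > 0.8
on disease-block labels (effect 2.0, noise 0.5, 800 samples, 25 properties)
with label-permuted controls straddling 0.5; binomial-band calibration of
the permutation tests under the null; the exact 1/(N+1) p-value floor; tree
distances equal to brute-force bipartition computations; association-score
sign recovery in 100/100 seeds; and an end-to-end CLI pipeline run.
`scripts/acceptance.R` recomputes the same headline quantities from scratch
at slightly larger replicate counts and writes them as JSON.

## Known limitations

- The embedding is transductive: an ASV absent from the co-occurrence data
  has no vector, and query ASVs are admitted only through sequence identity
  to an embedded ASV.
- Read-depth differences are ignored by presence/absence co-occurrence;
  deeper samples detect more taxa and thus inflate co-occurrence for their
  residents.
- Depth-2 association trees trade resolution for interpretability; scores
  are a vote census, not effect sizes, and their scale grows with trees and
  folds.
- The permutation tests permute ASVs as exchangeable units; phylogenetic
  autocorrelation among ASVs would make them anticonservative on real data.
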