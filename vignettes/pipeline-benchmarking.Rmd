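---
title: "Benchmarking multi-step pipelines with pipegrid: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multi-step pipelines with pipegrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipegrid)
```

pipegrid evaluates every combination of per-step parameter alternatives of a
linear analysis pipeline, sharing the computation of identical pipeline
prefixes and collecting evaluations and wall times on the fly. This vignette
is the package's account of how that works and why it is built the way it
is: the execution model and its guarantees, the synthetic data model that
makes the shipped single-cell RNA-seq suite testable, each module's tunable
parameters with their defaults, and the numerical conventions and design
choices made where more than one reasonable option existed.

## The execution model

A pipeline is an ordered list of steps. Each step owns a disjoint set of
named parameters, an operation `function(state, args)` returning the next
state, and optionally an evaluator (state → named list of scalar metrics)
and an aggregator. Given a named list of alternatives per parameter,
`enumerate_combinations()` builds the Cartesian product in lexicographic
order — parameters ordered by step, later parameters varying fastest — with
an optional subset filter (a predicate on the label vector or a named list
of allowed labels).

The combinations are organized as a *prefix tree*: a node at depth *j* is a
distinct assignment of all parameters of steps 1..*j*, and leaves correspond
one-to-one to combinations. `run_pipeline()` walks this tree depth-first,
executing each node's operation exactly once. Three engine-level guarantees
follow from this design and are asserted by the test suite:

* **Execution-count law.** For a full Cartesian plan, the number of
  executions at step *j* equals the product of alternative counts of steps
  up to *j*; for alternatives (2, 3, 2) that is (2, 6, 12) executions versus
  (12, 12, 12) for a naive runner.
* **Memory contract.** Depth-first traversal keeps at most one live
  intermediate state per tree depth (the recursion stack); intermediates are
  never written to disk.
* **Oracle equivalence.** Per-node seeds are derived by a stable string hash
  of (global seed, dataset id, prefix), not from execution order, so the
  prefix-sharing runner and `run_pipeline_naive()` — a deliberately naive
  full re-execution, kept in the package as an independent oracle — produce
  identical payloads, statuses and tables for any seeded pipeline. Wall
  times are excluded from such comparisons, being measurements rather than
  computation results.

A failing operation marks its node `error`; all descendants are recorded as
`skipped` while sibling subtrees proceed. A failing evaluator is recorded on
the node without stopping anything. A dataset that fails the pipeline's
initiator produces error records for that dataset only.

**Resumability.** With `resume_log`, every completed node is appended as one
JSON line keyed by (dataset, prefix). On a rerun against a partial log,
subtrees whose nodes are all recorded are skipped entirely; a recorded node
with unrecorded descendants is re-executed to regenerate its state (states
are never persisted), but its logged payload and timing are reused, so the
final tables are identical to an uninterrupted run. Payload numbers are
serialized at 17 significant digits so the JSON round trip is exact.

**Parallelism.** `n_workers > 1` parallelizes over datasets with forked
workers; within-dataset traversal stays serial because splitting a subtree
across workers would destroy prefix sharing. Records are keyed, so merging
is order-independent.

**Aggregation.** `aggregate_results()` emits one long-format table per step
(one row per dataset × combination, one column per parameter and per
metric), a per-node timing table and an error table; `merge_results()`
row-concatenates runs over disjoint datasets. `export_report()` writes these
as CSV together with variants × datasets metric matrices in raw and
MAD-centered form.

## The synthetic data model

Every evaluation module needs data with known answers. `simulate_dataset()`
draws, per gene, a baseline mean from a log-uniform range (default
e^−2 to e^2, giving means ~0.14–7.4, a realistic dynamic range for UMI
data); a fraction `frac_de_genes` (default 0.2) of genes is assigned one
subpopulation in which its mean is multiplied by e^±logFC with logFC uniform
on `de_logfc_range` (default [1, 2], natural log). Counts are negative
binomial with a single dispersion shared across genes (default 0.5,
size = 2) — the simplest error model that still exercises every metric —
scaled by log-normal per-cell library factors (sd 0.3 on the log scale).

Doublets (probability `doublet_rate`, default 0.05) are entrywise sums of
two freshly drawn parent cells from *different* subpopulations, each with
its own library factor; both parent labels are recorded. Homotypic doublets
are deliberately not simulated by default: a same-type doublet is, at the
level of gene counts, nearly a larger singlet, and detecting them is not
what doublet callers are for — the test suite constructs them explicitly to
demonstrate precisely that blindness. Low-quality cells (probability
`lowq_rate` among singlets) have their non-mitochondrial counts binomially
thinned with keep probability 1/`lowq_mito_inflation` (default 1/5): the
mitochondrial share rises *and* the library shrinks, which mirrors how
degraded cells actually present, rather than adding mitochondrial counts. A
`hierarchical` option derives subpopulation means along a random tree of
perturbations, producing pairs of closely related subpopulations; it is off
by default.

What the generator does **not** emulate: gene–gene correlation beyond
subpopulation structure, per-gene dispersion trends, batch effects, ambient
RNA, or UMI-vs-read error profiles. Tests passing on this generator
demonstrate the correctness and internal consistency of the methods, not
their ranking on real tissues.

Datasets round-trip losslessly through `write_dataset()`/`read_dataset()`
(Matrix Market counts, TSV gene metadata, CSV cell metadata; doubles
formatted with `%.17g`).

## QC metrics and filter sets

`compute_cell_qc()` produces the five per-cell metrics the filter sets use:
log10 total counts, log10 detected features (count > 0), the fraction of
counts in the cell's 20 highest-count genes, `featcount_dist` (the residual
from an ordinary least-squares fit of log-features on log-counts across all
cells — a robust-regression variant is available, OLS is the default), and
the mitochondrial count fraction. Percentage-type metrics are stored as
fractions in [0, 1]; the absolute mitochondrial floor of 0.08 is read on
that scale. Zero-count cells get −Inf log metrics and are always removed.

Outlier calls use the median ± n·MAD with the 1.4826 consistency constant
(configurable). When the MAD is exactly zero the scale falls back to a small
epsilon (1e−8 × max(1, |median|)), so values truly distinct from the median
are still flagged while constant vectors yield none.

The four sets follow fixed rules. `default` excludes a cell flagged on at
least two of: log-counts (>2.5 or <5 MADs), log-features (>2.5 or <5),
top-20 fraction (two-sided 5), `featcount_dist` (two-sided 5),
mitochondrial fraction (>2.5 MADs **and** >0.08 — a conjunction). `stringent`
uses the same thresholds but excludes on any single criterion, which makes
default-excluded ⊆ stringent-excluded a provable nesting (property-tested).
`lenient` needs two criteria at 5 MADs (mitochondrial: >3 MADs and >0.08).
`veryStringent` excludes on any single two-sided 2-MAD outlier among
log-counts, log-features, mitochondrial fraction and top-20 fraction; no
absolute mitochondrial floor is applied there, as none is part of that
set's definition. When a dataset carries no mitochondrial annotation the
mitochondrial criterion is skipped with a warning.

`clusterwise_filter()` first groups cells with `quick_cluster()` (below) and
applies the chosen set within each cluster, leaving clusters of fewer than
3 cells untouched; this protects subpopulations with systematically smaller
libraries from wholesale removal. `pca_outlier_filter()` standardizes the
QC covariates ("all", or the selected four), computes robust Mahalanobis
distances from a minimum-covariance-determinant estimate and cuts at the
chi-squared 0.999 quantile; a singular covariance falls back to the union of
per-axis two-sided 3-MAD outliers, with a warning.

`quick_cluster()` — log-normalize, top 1000 variable genes, 10-component
PCA, SNN graph (k = 10), modularity clustering, small clusters merged into
the nearest centroid — is one self-contained routine shared by cluster-wise
filtering and the doublet generator, so both operate on the same notion of
"cluster".

## Doublet identification

`generate_artificial_doublets()` sums the raw counts of two cells drawn
from different clusters (the cluster *pair* is drawn uniformly over distinct
pairs, then one cell from each). Counts are summed without rescaling because
a real doublet is the union of two transcript pools; the artificial:real
ratio defaults to 1:1. An option adds meta-cell "triplets" (cluster mean
profile, rounded, plus a sampled cell), one quarter of the artificial count.
With a single cluster the generator degrades to uniform random pairs with a
warning.

`score_doublets()` embeds real and artificial cells jointly
(log-normalization on combined totals, top 1000 variable genes, PCA to
`n_pcs` = 10) and scores each real cell by the proportion of artificials
among its k = 10 exact nearest neighbors, renormalized for the realized
artificial:real ratio so that 0.5 means "neighborhood composition equals
global composition"; scores of 0 and 1 mean no and all artificial
neighbors.

`call_doublets()` turns scores into calls around the expected doublet rate:
candidate call counts range over (`expected_rate` ± `rate_uncertainty`) × n,
and within that band the count at the steepest drop of the sorted score
curve is chosen (the threshold is the midpoint of that gap). With zero
uncertainty this reduces to calling exactly round(rate × n) cells; constant
scores fall back to the same count in index order, with a warning. ROC
curves and AUROC (`doublet_roc()`) use the trapezoidal rule and are verified
in the tests against a Mann–Whitney pairwise-count oracle and an established
ROC implementation.

## Processing stages

* `lognormalize()`: counts per cell scaled to `scale_target` (default
  10,000) then `log1p`.
* `scale_features()`: optional per-gene OLS regression on per-cell
  covariates (residuals taken in one QR pass), then centering and unit
  variance; genes with numerically zero variance (below 1e−10 relative to
  the matrix scale) are set to zero rather than amplified.
* `rank_features()`: mean expression, variance, trend-standardized variance
  (loess of log variance on log mean, values standardized by the fitted sd
  and clipped at √n before the variance is taken), or binomial deviance
  computed on raw counts under a constant-proportion null with 0·ln 0 = 0 —
  the criterion that treats each cell's count as a binomial draw from its
  total. Ties are broken by gene order, deterministically.
* `pca_embed()`: exact truncated SVD of the gene-centered matrix. The
  weighted embedding (default) multiplies cell scores by the singular
  values, so component variances differ — the convention whose impact the
  clustering benchmark is designed to expose; the unweighted variant
  returns unit-norm component scores. Component signs are fixed by making
  the largest-magnitude gene loading positive, so results are reproducible
  to the digit.
* `build_neighbor_graph()`: exact brute-force k-nearest neighbors (ties
  broken by index), then `knn` (union-symmetrized edges, similarity weights
  1/(1+d)), `snn_jaccard` (Jaccard overlap of self-inclusive neighborhoods,
  computed by sparse cross-product) or `snn_rank` (weight k − r/2 with r
  the smallest rank sum of any shared neighbor — the exact weighting of
  rank-based SNN builders is not standardized, so this formula is our
  documented choice). The `exact` flag is part of the interface; only the
  exact backend is bundled, and an approximate search can be registered.
* `cluster_graph()`: pluggable community detection — resolution-
  parameterized modularity (multilevel), random-walk (walktrap), greedy
  modularity — seeded for determinism. The number of clusters grows with
  the resolution parameter approximately, not provably monotonically; the
  test asserts the empirical trend on a fixed toy graph.

The shipped default pipeline wires these as: doublet removal → `default`
filter → log-normalization → top-2000 variable features → scaling → PCA →
SNN + modularity clustering, with the customary dimension grid
{5, 10, 15, 20, 30, 50} and resolution grid 0.005–4 exposed by
`default_scrna_alternatives()`. Truth-based evaluators attach to filtering
(cell counts, residual low-quality fraction), reduction (truth
dimensionality, elbow, silhouette, PC1–library-size association) and
clustering (ARI, MI, cluster count, matched F1), computed on non-doublet
cells against the known labels.

## Evaluation metrics

ARI uses the Hubert–Arabie pair-counting form; MI is reported in nats,
unnormalized (NMI is available as an option but is not a headline metric).
Per-class precision/recall/F1 come from a one-to-one Hungarian assignment of
clusters to classes maximizing total matched cells, with rectangular tables
padded by zero-overlap dummies; an unmatched class scores F1 = 0, and
`mean_F1` is the unweighted mean over true classes. The assignment solver is
an O(n³) augmenting-path implementation, exhaustively verified against
permutation search for tables up to 6×6. Matching total overlap (rather
than, say, summed F1) is the standard Hungarian usage and keeps the
objective interpretable as "cells correctly placed".

`ari_at_true_k()` reduces a resolution sweep to the *maximum* ARI among
members that reach the true cluster number, returning missing when none
does (rendered as a gray cell in heatmaps). Taking the maximum reflects the
question the sweep answers — can this variant be coerced into the right
granularity, and how good is it then — where the sweep itself is part of
the variant. Silhouettes are Euclidean, averaged per true class, with
singleton-class cells scored 0. `misclassification_rates()` calls a cell
misclassified in one clustering when its cluster's matched class differs
from its true class (cells of unmatched clusters count as misclassified),
averages over clusterings, and subtracts the per-subpopulation median so
that systematic subpopulation difficulty cancels; the adjusted rates have
per-subpopulation median zero by construction.

## Truth-based intermediate metrics

`variance_explained()` is the one-way between/total sum-of-squares ratio per
gene or per component (zero-variance rows score 0) — identical to the R² of
a linear model on the subpopulation factor, which the tests assert
explicitly. `covariate_correlation_adjusted()` correlates the residuals of
component ∼ subpopulation with a technical covariate; its square is the
"variance explained after accounting for the biology" reading. Numerically
constant residuals (a component fully determined by subpopulations) return
0 rather than the correlation of rounding noise.

`deviance_explained()` fits, per gene, negative binomial log-link models
with the log library size as an offset: full (offset + population) and
reduced (offset only), and reports (dev_reduced − dev_full)/dev_reduced
clipped at zero. The dispersion is estimated once by maximum likelihood
under the **full** design and held fixed for both fits. Estimating it under
the reduced design was considered and rejected: for a marker gene the
reduced model's misfit inflates the dispersion estimate, absorbing exactly
the signal being measured (a gene expressed in one population then caps
around 0.8 explained instead of approaching 1). A shared dispersion keeps
the two fits strictly nested either way. Genes whose NB fit fails fall back
to Poisson and are listed in an attribute. Whether library size should be an
offset or a free coefficient is genuinely ambiguous; both are implemented
(`library_size = "offset"` is the default, as the offset form is the
standard way to express "per library-size" rates in a GLM).

`cumulative_explained_topk()` divides the explained signal captured by a
ranking's top k genes by that of the best possible top k, giving curves in
[0, 1] that equal 1 exactly for the oracle ranking.

## Dimensionality estimators

`farthest_point()` returns the scree-curve point farthest (perpendicular
distance) from the chord joining the first and last points, ties to the
smallest index; `elbow_dims()` applies it to the variance-explained curve of
the first min(50, rank) components. The rule is invariant to jointly
rescaling both axes.

`jackstraw_pvalues()` permutes a small fraction of genes (default 1%, 100
rounds), recomputes the PCA, and pools the permuted genes' squared
gene–component correlations into a per-component null. The per-component
p-value is a one-sided Kolmogorov–Smirnov test (asymptotic exp(−2nD₊²)) of
the observed genes' empirical p-values against uniformity. A pooled rank
test of the raw statistics was tried first and rejected for lack of power:
the majority of genes carry no signal for any given component, and their
bulk ranks drown the enriched tail that the KS statistic sees directly. On
pure-noise matrices the p-values are uniform; on planted two-component data,
components 1–2 reach p ≈ 1e−33 while later components stay near 1.
`jackstraw_dims()` applies the farthest-point rule to the log10 p-values —
looking for the drop in significance rather than thresholding.

`mcv_split()` implements molecular cross-validation's count splitting: every
count y becomes A ∼ Binomial(y, 0.5), B = y − A, entrywise and
independently, so A + B reproduces the input exactly (non-integer counts
are rounded up first). `mcv_dims()` log-normalizes both halves identically,
fits the PCA basis on half A, and scores the rank-k *reconstruction of A*
against half B (centered on A's means — the prediction convention), taking
the k minimizing the mean squared error, with k = 0 (mean-only) as the
baseline. Scoring A's reconstruction, rather than projecting B through the
basis, is essential: projecting B removes variance along any direction, so
that error is monotone decreasing in k and cannot select a finite rank,
whereas components fitted to A's noise genuinely disagree with B's
independent noise and turn the curve upward past the true rank. Because
each half keeps only half the molecules, the estimate can run one low;
multi-split averaging is available.

## Reporting

`mad_center_transform()` makes metric heatmaps comparable across datasets:
entries are centered on their column (dataset) median, the centered
deviations are pooled matrix-wide into a single MAD (constant 1.4826), and
each value maps to sign(d)·sqrt(|d|/MAD). Column medians stay at zero,
equal color differences mean the same number of pooled MADs everywhere, and
missing entries (true cluster number never reached) stay missing.
`sqrt_silhouette_transform()` is the matching sign-preserving square root
for silhouette panels. Raw values are always written alongside transformed
ones.

## Problem sizes and limitations

The test suite and the acceptance script run at deliberately modest scale —
hundreds of genes and 500–2000 cells per dataset, 10–25 permutations or
splits where resampling is involved — chosen so the full suite completes in
a few minutes on a single core while every assertion still has clear
statistical margin; all thresholds were fixed from the generator's stated
conditions, not tuned to runs. Known limitations: the engine handles
strictly linear pipelines (no branching DAGs); neighbor search is exact
brute force, appropriate for thousands of cells, with approximate backends
left to the registry; the doublet scorer follows the published *principles*
of cluster-informed artificial-doublet detection rather than reproducing
any specific tool bit-for-bit; and conclusions drawn from the synthetic
generator transfer to real data only to the extent that subpopulation
structure, library-size variation and degradation are the dominant effects.
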