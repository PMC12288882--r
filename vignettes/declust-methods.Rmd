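---
title: "Cluster-based deconvolution of spatial transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based deconvolution of spatial transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declust)
```

## The problem

Spots on RNA-capture spatial transcriptomics (ST) arrays such as 10x
Visium are ~55 µm across and typically capture mRNA from one to ten
cells of mixed type. Estimating the cell-type composition of each spot
(deconvolution) from a reference of annotated scRNA-seq profiles is hard
at the single-spot level because individual spots are sparse and noisy.
`declust` takes a cluster-based route: spots are first grouped into
spatially coherent, transcriptionally similar clusters; deconvolution is
performed once per cluster on the aggregated (pseudo-bulk) profile,
where the signal is far stronger; and the cluster-level proportions are
propagated back to the member spots.

The approach trades spot-level granularity for robustness. It is
appropriate when the tissue is organized into domains that are larger
than a spot (cortical layers, tumor regions, stromal bands) and
inappropriate for salt-and-pepper mixtures, where a cluster-constant
estimate cannot track spot-to-spot variation.

## The pipeline

### Shared gene space

Both inputs are reduced to their top `top_n_genes` (default 5000) most
variable genes — variance computed on log1p library-size-normalized
expression — and the intersection of the two selections is kept. The
shared genes are ordered lexicographically so that every downstream
matrix is reproducible regardless of input file ordering. Whether
variance is computed on the raw or normalized scale is configurable
(`vargenes_on`); the normalized scale is the default because raw-scale
variance is dominated by library size.

### Spatial clustering of spots

1. **Hierarchical clustering.** Ward-linkage agglomeration (squared
   Euclidean merge cost `(|A||B|/(|A|+|B|)) ||centroid_A - centroid_B||²`,
   computed by `stats::hclust(method = "ward.D2")` on Euclidean
   distances) on the normalized expression yields nested partitions.
   The number of initial clusters is chosen by the elbow of the
   within-cluster sum of squares (WCSS) curve. Because the partitions
   are nested, the curve is non-increasing by construction.

   *Automating the elbow.* We take the candidate count maximizing the
   discrete second difference of **log** WCSS. On the raw scale the
   second difference is dominated by the largest absolute drop, which
   for any structure whose first merge gap dominates selects two
   clusters regardless of the true count (for three equidistant
   well-separated blobs the raw criterion provably picks 2). The log
   curve measures *relative* flattening and recovers planted counts
   reliably; it is the same criterion, made scale-free. A flat curve
   falls back to the smallest candidate with a warning.

2. **DBSCAN spatial sub-clustering.** Within each initial cluster,
   DBSCAN on the spot coordinates (array-grid units) with `eps = 4` and
   `min_pts = 8` splits the cluster into spatially dense sub-clusters;
   spots in no dense region become noise. These two values are
   expressed in Visium array units, which is why the readers use
   `array_row`/`array_col` as the coordinate system; plain `x,y`
   coordinate files are taken as-is. The DBSCAN implementation is the
   standard neighborhood-expansion algorithm, written here (and verified
   in the test suite against an independent union-find formulation on
   hundreds of random instances).

3. **Seed selection.** Sub-clusters holding less than `frac_threshold`
   (default 5%) of *all* spots in the dataset contribute no seeds — the
   threshold is interpreted dataset-wide, following the phrase "total
   spots", and is configurable. From each qualifying sub-cluster,
   `floor(seed_frac × n_eligible)` spots (default 50%, rounded down) are
   sampled without replacement from its non-boundary members. A
   *boundary* spot is one with fewer than the full complement of
   `neighbor_k = 8` spatial neighbors within `neighbor_radius = 2` grid
   units; the k-nearest-within-radius definition covers both square
   lattices and hex-packed Visium rows, where literal 8-adjacency is
   ill-defined.

4. **Seeded region growing (SRG).** Labeled regions grow outward from
   the seeds. A sequentially sorted list (SSL) holds unlabeled spatial
   neighbors of the labeled region, keyed by the Euclidean distance
   between the spot's normalized expression and the running mean profile
   of the adjacent region (region means update incrementally as spots
   join; SSL entries keep the minimum distance seen at push time). Each
   iteration pops the minimum-distance spot — ties broken by spot index
   for determinism — and assigns the unanimous label of its labeled
   neighbors, or, if neighbors disagree, the label of the
   expression-nearest adjacent region. DBSCAN noise spots enter SRG
   unlabeled and are re-assigned by expression and spatial context,
   which is the mechanism that corrects spots mis-assigned by the purely
   transcriptional initial clustering. Spots spatially disconnected from
   every seed are assigned post hoc to the expression-nearest region
   with a warning. Seeds never change label. Final clusters are
   relabeled 1..h by decreasing size, and clusters smaller than
   `min_cluster_size = 3` are merged into the expression-nearest cluster
   because pseudo-bulk regression on two spots is unstable.

5. **Pseudo-bulk.** Cluster profiles are the *mean* linear-scale
   expression of member spots (configurable to sum). The mean keeps the
   response commensurate with per-cell reference profiles and, because
   the estimator renormalizes proportions, the choice does not affect
   the estimates — only the conditioning of the diagnostics.

### Marker genes (two-statistic selection)

For each cell type and gene, two statistics are computed on log1p
library-size-normalized reference expression:

* **T1 (up-regulation)** — a Welch-type one-sided t statistic of the
  target type's mean minus the complement's mean. The exact "robust"
  variant is realized as Welch's unequal-variance t with a variance
  floor equal to `var_floor_frac = 1%` of the gene's global variance;
  the floor prevents infinite statistics on zero-variance,
  dropout-heavy genes while leaving ordinary genes untouched. One-sided
  orientation means markers must be *high* in their type.
* **T2 (homogeneity of the rest)** — a Cochran's-Q-style heterogeneity
  chi-square over the per-type means of the remaining types,
  `Q = Σ w_c (m_c − m̄_w)²` with inverse-squared-standard-error weights,
  referred to a chi-square with (number of remaining types − 1) degrees
  of freedom. Remaining types with fewer than two cells are excluded
  and the degrees of freedom reduced.

A gene qualifies for a type when T1's p-value is below `alpha1 = 0.05`
and T2's p-value is above `alpha2 = 0.05`; qualifying genes are ranked
by descending T1 (ties by gene id) and the top `t_markers = 10` kept. A
type with no qualifying genes falls back to the top `t` by T1 alone with
a warning. A gene may serve several types if it qualifies for each; the
regression uses all reference columns jointly, so exclusivity is not
required. Note the joint rule forfeits about `alpha2` of true markers to
T2's null rejection rate by construction — recovery of planted markers
therefore plateaus near 95%, not 100%.

The reference matrix has one row per cell type and one column per
selected marker (union over types); entries are mean *linear-scale*
expression over the type's cells. Tests run on the log scale where their
distributional assumptions behave; the mixing model is linear, so the
design matrix is built on the linear scale.

### Deconvolution

For each cluster profile `x` the estimator is literally: solve the
unconstrained least-squares system `x ≈ Ẑᵀ y`, clip negative
coefficients to zero, renormalize to sum 1. This clip-and-renormalize
recipe is the default; it is *not* guaranteed to minimize the residual
under the non-negativity constraint, and a true NNLS solve
(Lawson–Hanson, `pracma::lsqnonneg`) is available via
`deconv_method = "nnls"` for comparison — never substituted silently.
The least-squares solve uses QR factorization rather than the explicit
inverse of the normal equations; on well-conditioned inputs the two
agree to 1e-10 (asserted in the tests), and QR degrades gracefully as
conditioning worsens. A rank-deficient reference aborts with the names
of collinear cell-type pairs (profile correlation > 0.999). Rows whose
coefficients are all clipped to zero fall back to uniform proportions
with a warning. Because of the final renormalization, estimates are
invariant to positive scaling of the response, which also absorbs the
scale difference between multi-cell spot aggregates and per-cell
reference means.

Spot-level proportions are the cluster-level rows copied to member
spots.

## Simulators and the synthetic fixture

`simulate_spot` draws cell counts from a multinomial with a fixed total
(default `cells_per_spot = 10`, within the range observed on Visium
arrays), samples that many cells of each type uniformly *with
replacement* from the reference, and sums their linear counts. With-
replacement sampling is the deliberate choice: reference pools can be
tiny (a rare type may have only a handful of cells) and sampling without
replacement would exhaust them; the flag is configurable. The recorded
truth is the realized mixture `counts / cells_per_spot`, an exact
bookkeeping identity.

`simulate_lr_enriched` adds ligand–receptor co-enrichment: in designated
clusters, the two named cell types are sampled only from cells whose
ligand *and* receptor expression sit at or above the 0.75 quantile
(type-7 interpolation, ties pass via ≥, so constant genes pass all
cells). Cluster labels, cluster-level proportions, and LR pairs are
inputs — they come from upstream spatial-domain, bulk-deconvolution and
LR-inference tools that this package does not reimplement.

`make_fixture` builds a fully synthetic benchmark: a reference with
negative-binomial baseline counts (`nb_mu = 2`, `nb_size = 2`, i.e.
baseline SD 2 — moderate overdispersion typical of UMI counts at this
depth) and `markers_per_type = 10` planted markers per type at
`effect_size = 4` fold-change, which at these baseline parameters is a
3-SD shift; plus a square spot lattice partitioned into four contiguous
quadrant domains, each dominated by one cell type at
`dominant_prop = 0.85` with the remainder split evenly.

Two consequences of the realized-truth convention deserve emphasis:

* **The multinomial noise floor.** Against realized truth, the per-type
  MSE of *any* estimator that is constant within a domain is bounded
  below by the mean of `p(1−p)/cells_per_spot` over spots. At 0.85
  dominance and 10 cells per spot that floor is ≈ 0.0067; the pipeline's
  measured per-type MSE of ≈ 0.007–0.009 is therefore nearly all
  irreducible sampling noise, and the floor — not the method — is what a
  larger `cells_per_spot` or purer domains would lower. The default
  domain purity emulates fairly pure tissue domains, which is the regime
  the cluster-based strategy targets.
* **What passing tests do and do not show.** The fixture has clean
  blocks, markers with identical baseline in all other types, and no
  batch effects, platform noise, spatial expression gradients within a
  domain, or mismatched reference. Success here validates the
  machinery — clustering recovery, estimator algebra, bookkeeping — not
  performance on real tissue.

## Evaluation machinery

Simulation metrics are the per-spot RMSE over cell types and the
per-type MSE over spots (the same quantity without the root).

The cross-validation harness for real data, where ground truth is
unavailable, scores how well a deconvolution preserves spatial
structure. Cluster labels — and the shared gene space — are fixed once
from the full data *before* folds are drawn, since fold stratification
is defined within clusters. Spots are dealt round-robin into 10 folds
within each cluster after a seeded shuffle, and a greedy swap pass then
reduces same-fold spatial adjacency (perfect non-adjacency is infeasible
on dense lattices; the residual violation count is reported). For each
fold: pseudo-bulk, deconvolution and spot expansion use training spots
only; test-spot proportions are the renormalized mean of their training
neighbors' proportions (nearest training spot if no neighbor); the
test-spot expression is reconstructed as the proportion-weighted sum of
cell-type mean profiles; and reconstruction is scored against the
observed expression on the library-size-normalized log scale (the
observed spot aggregates ~10 cells while the reconstruction is on the
per-cell scale, so raw-scale RMSE would measure library size, not fit).

Per-spot metrics are RMSE, the Pearson correlation, and the Spearman
coefficient computed by the rank-difference formula
`1 − 6Σd²/(g(g²−1))` with midranks for ties — exactly the Pearson
correlation of ranks when all ranks are distinct, and only then; the
package keeps the rank-difference form deliberately and documents the
tie caveat. Constant rows have undefined correlations and are excluded
from the summary medians with a warning.

*Leakage semantics.* Everything downstream of the fixed labels and gene
space depends only on training-spot expression. The well-defined
invariant — verified in the tests — is that perturbing a fold's spot
expression leaves that fold's own predictions byte-identical. Other
folds legitimately use the perturbed spots as training data, so their
predictions may change. Computing labels (or genes) per training fold
is available by simply passing different inputs, but stratified folds
require a single cluster structure, so fixed-once is the default.

## Reproducibility and problem sizes

A single `rng_seed` in `declust_config()` fans out to per-stage seeds
through a fixed splitting scheme, so seed selection, simulation, and
fold assignment are independently reproducible; identical inputs and
seed give bit-identical outputs end to end. The test suite and the
acceptance script exercise the full pipeline on 20×20-spot lattices
(400 spots, 200 genes, 4 types, 3 replicates) and the CV harness on a
14×14 lattice with 10 folds — sizes chosen so the whole suite runs in a
few minutes on one CPU while keeping every code path realistic; all
numbers quoted in the README are produced by those runs.

## Known limitations

* Proportions are constant within a cluster: genuine within-domain
  gradients are flattened, and cell types absent from the reference are
  invisible.
* The clip-and-renormalize estimator is faithful to the cluster-based
  recipe but not an NNLS optimum; the NNLS flag quantifies the (small,
  usually zero) residual gap on request.
* The elbow rule, like all unsupervised model-order criteria, can be
  misled when domain counts exceed the candidate range or when domains
  differ greatly in size; the range is configurable and the WCSS curve
  is returned for inspection.
* ε = 4 and minPts = 8 are calibrated for Visium-density arrays in
  array-grid units; other platforms need rescaled values.
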