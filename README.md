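# declust

Cluster-based cell-type deconvolution of spatial transcriptomics (ST)
data in R.

Spots on RNA-capture ST arrays (10x Visium and kin) mix mRNA from
several cells, and per-spot deconvolution struggles with the sparse,
noisy profiles of individual spots. `declust` instead:

1. **clusters spots** into spatially coherent, transcriptionally
   similar groups — Ward hierarchical clustering on expression (elbow
   rule on the WCSS curve), DBSCAN sub-clustering on spot coordinates
   (ε = 4, minPts = 8 in array units), seed selection, and seeded
   region growing to the final clusters;
2. **selects marker genes** from an annotated scRNA-seq reference with
   a two-statistic rule — a one-sided robust *t* statistic (T1,
   p < 0.05) requiring up-regulation in one cell type, and a
   heterogeneity chi-square (T2, p > 0.05) requiring homogeneity among
   the remaining types; the top *t* = 10 genes per type form the
   reference matrix **Ẑ** (k types × g markers, mean linear expression);
3. **deconvolves each cluster's pseudo-bulk profile** x by ordinary
   least squares with a non-negative constraint — solve
   y = (ẐᵀẐ)⁻¹Ẑᵀx, clip negatives to 0, renormalize to Σy = 1 — and
   copies the cluster proportions back to the member spots.

The package also ships the machinery to test all of this without any
downloads: a multinomial spot simulator (10 cells/spot) with optional
ligand–receptor co-enrichment, a fully synthetic fixture generator
(negative-binomial reference with planted markers plus a lattice of
contiguous domains), simulation metrics (RMSE/MSE of proportions), and
a spatially stratified 10-fold cross-validation harness that scores
reconstructed against observed spot expression by RMSE, Pearson and
Spearman correlation.

## Worked example

```r
library(declust)

# a seeded synthetic benchmark: 20x20 spot lattice, 4 cell types in
# 4 quadrant domains, 10 planted markers/type, 10 cells per spot
fx  <- make_fixture(rng_seed = 1)
res <- run_declust(fx$st, fx$sc, declust_config(h_range = 2:10, rng_seed = 1))
res
#> declust_result: 400 spots, 4 clusters, 4 cell types, 40 marker genes

round(mse_by_type(res$Y_spot, fx$S[, colnames(res$Y_spot)]), 5)
#>   type1   type2   type3   type4
#> 0.00654 0.00621 0.00741 0.00799

proportions_rmse(res$Y_spot, fx$S[, colnames(res$Y_spot)])$overall
#> [1] 0.07480316
```

The per-type MSE of ~0.006–0.008 reads against the *realized* truth
(sampled cell counts / 10), which carries an irreducible multinomial
noise floor of ≈ 0.0067 at these settings — the estimator is close to
the attainable optimum. The clustering itself recovers the four planted
domains exactly (adjusted Rand index 1.00 for this seed), and the elbow
rule selects h = 4 clusters.

`cluster_spots()`, `select_markers()`, `build_reference()`,
`ols_deconvolve()`, `simulate_dataset()`, `simulate_lr_enriched()` and
`run_cv()` expose the individual stages; see the methods vignette
(`vignettes/declust-methods.Rmd`) for the model, parameter meanings and
design rationale. A thin command-line front end over the same functions
is installed at `inst/cli/declust.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/declust.R", package = "declust"))')" \
  run --st-expr expr.csv --st-coords positions.csv \
      --sc-expr ref.csv --sc-labels labels.csv --out-dir out/ --rng-seed 1
```

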