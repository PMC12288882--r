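#' Proportion-recovery error metrics
#'
#' `proportions_rmse` computes the per-spot RMSE over cell types between
#' estimated and true proportion matrices, plus the overall mean;
#' `mse_by_type` the per-type MSE averaged over spots (the RMSE without
#' the square root).
#'
#' @param Y_hat,S aligned n x k matrices (same spot order and cell-type
#'   order).
#' @return `proportions_rmse`: list with `per_spot` and `overall`;
#'   `mse_by_type`: named numeric vector over cell types.
#' @export
proportions_rmse <- function(Y_hat, S) {
  if (!all(dim(Y_hat) == dim(S))) {
    stop("proportions_rmse: shape mismatch ",
         paste(dim(Y_hat), collapse = "x"), " vs ",
         paste(dim(S), collapse = "x"))
  }
  per_spot <- sqrt(rowMeans((Y_hat - S)^2))
  list(per_spot = per_spot, overall = mean(per_spot))
}

#' @rdname proportions_rmse
#' @export
mse_by_type <- function(Y_hat, S) {
  if (!all(dim(Y_hat) == dim(S))) stop("mse_by_type: shape mismatch")
  out <- colMeans((Y_hat - S)^2)
  names(out) <- colnames(S)
  out
}

#' Spatially stratified cross-validation folds
#'
#' Within each cluster, spots are shuffled (seeded) and dealt round-robin
#' into `n_folds` folds, so every cluster's spots spread across folds as
#' evenly as sizes allow. A greedy swap pass then reduces same-fold
#' spatial adjacency: for each spot with a same-fold spatial neighbor, a
#' swap with a spot of another fold in the same cluster is accepted when
#' it lowers the total count of same-fold adjacent pairs. Perfect
#' non-adjacency is not always feasible on dense lattices; the residual
#' violation count is reported.
#'
#' @param final_labels per-spot cluster label.
#' @param coords n x 2 coordinates.
#' @param n_folds number of folds (default 10).
#' @param rng_seed integer seed.
#' @param neighbor_k,neighbor_radius spatial-neighbor definition.
#' @return list of class `fold_assignment` with `fold` (per-spot id in
#'   1..n_folds), `violations` (same-fold adjacent pairs after the swap
#'   pass), `violations_naive` (before).
#' @export
make_folds <- function(final_labels, coords, n_folds = 10, rng_seed = 1L,
                       neighbor_k = 8, neighbor_radius = 2) {
  if (n_folds < 2L) stop("make_folds: need n_folds >= 2")
  n <- length(final_labels)
  fold <- integer(n)
  with_seed(rng_seed, {
    for (cl in sort(unique(final_labels))) {
      idx <- which(final_labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  nb <- spot_neighbors(coords, k = neighbor_k, radius = neighbor_radius)
  count_viol <- function(f) {
    sum(vapply(seq_len(n), function(i) {
      sum(f[nb[[i]]] == f[i])
    }, numeric(1))) / 2
  }
  naive <- count_viol(fold)
  # greedy swap pass within clusters
  for (i in seq_len(n)) {
    if (!any(fold[nb[[i]]] == fold[i])) next
    same_cl <- which(final_labels == final_labels[i] & fold != fold[i])
    best_gain <- 0L; best_j <- NA_integer_
    local <- function(f, s) sum(f[nb[[s]]] == f[s])
    for (j in same_cl) {
      before <- local(fold, i) + local(fold, j)
      f2 <- fold
      f2[c(i, j)] <- fold[c(j, i)]
      after <- local(f2, i) + local(f2, j)
      gain <- before - after
      if (gain > best_gain) { best_gain <- gain; best_j <- j }
    }
    if (!is.na(best_j)) fold[c(i, best_j)] <- fold[c(best_j, i)]
  }
  structure(list(fold = fold, violations = count_viol(fold),
                 violations_naive = naive),
            class = "fold_assignment")
}

#' Predict test-spot proportions from neighboring training spots
#'
#' Each test spot is predicted as the mean proportion vector of its
#' spatial neighbors that belong to the training set, renormalized to sum
#' 1. A test spot with no training neighbor falls back to the nearest
#' training spot, with a warning.
#'
#' @param Y_train proportions for training spots (rows indexed by
#'   `train_idx`).
#' @param coords n x 2 coordinates of all spots.
#' @param train_idx,test_idx integer indices into the full spot set.
#' @param neighbor_k,neighbor_radius spatial-neighbor definition.
#' @return matrix with one row per test spot.
#' @export
neighbor_average_predict <- function(Y_train, coords, train_idx, test_idx,
                                     neighbor_k = 8, neighbor_radius = 2) {
  nb <- spot_neighbors(coords, k = neighbor_k, radius = neighbor_radius)
  pos <- match(seq_len(nrow(coords)), train_idx)  # spot -> row of Y_train
  out <- matrix(NA_real_, length(test_idx), ncol(Y_train),
                dimnames = list(NULL, colnames(Y_train)))
  fell_back <- 0L
  for (t in seq_along(test_idx)) {
    i <- test_idx[t]
    tr_nb <- nb[[i]][!is.na(pos[nb[[i]]])]
    if (length(tr_nb) == 0L) {
      fell_back <- fell_back + 1L
      d <- sqrt(colSums((t(coords[train_idx, , drop = FALSE]) -
                           coords[i, ])^2))
      tr_nb <- train_idx[which.min(d)]
    }
    p <- colMeans(Y_train[pos[tr_nb], , drop = FALSE])
    out[t, ] <- p / sum(p)
  }
  if (fell_back > 0L) {
    warning(fell_back, " test spots had no training neighbor; ",
            "nearest training spot used")
  }
  out
}

#' Reconstruct a spot profile from proportions (convolution)
#'
#' The predicted expression of a spot is the proportion-weighted sum of
#' the cell-type mean profiles, each mean taken over all reference cells
#' of the type across the shared genes.
#'
#' @param Y_row proportion vector summing to 1 (named or ordered by the
#'   reference types).
#' @param sc an [sc_reference].
#' @param genes optional gene subset (default all reference genes).
#' @return numeric gene vector.
#' @export
convolve_expression <- function(Y_row, sc, genes = NULL) {
  types <- levels(sc$cell_types)
  if (!is.null(names(Y_row))) Y_row <- Y_row[types]
  if (abs(sum(Y_row) - 1) > 1e-6) {
    stop("convolve_expression: proportions must sum to 1")
  }
  if (is.null(genes)) genes <- sc$gene_ids
  means <- t(vapply(types, function(ty) {
    colMeans(sc$expr[sc$cell_types == ty, genes, drop = FALSE])
  }, numeric(length(genes))))
  drop(as.numeric(Y_row) %*% means)
}

# midranks
rank_mid <- function(x) rank(x, ties.method = "average")

#' Per-spot reconstruction metrics
#'
#' Scores reconstructed against observed expression per spot: RMSE over
#' genes; the Pearson correlation coefficient; and the Spearman
#' coefficient via the rank-difference formula
#' 1 - 6 sum(d^2) / (g(g^2-1)) with midranks for ties (exactly the rank
#' Pearson correlation when all ranks are distinct). Spots with a
#' constant observed or predicted row have undefined correlations; those
#' entries are NA and excluded from the medians with a warning.
#'
#' @param observed,predicted aligned spot x gene matrices, g >= 2 genes.
#' @return list of class `cv_report` with `per_spot` (data.frame rmse,
#'   pcc, scc) and `summary` (medians over spots).
#' @export
cv_metrics <- function(observed, predicted) {
  if (!all(dim(observed) == dim(predicted))) {
    stop("cv_metrics: shape mismatch")
  }
  g <- ncol(observed)
  if (g < 2L) stop("cv_metrics: need >= 2 genes")
  n <- nrow(observed)
  rmse <- pcc <- scc <- numeric(n)
  n_const <- 0L
  for (i in seq_len(n)) {
    y <- observed[i, ]; yt <- predicted[i, ]
    rmse[i] <- sqrt(mean((y - yt)^2))
    if (stats::sd(y) == 0 || stats::sd(yt) == 0) {
      pcc[i] <- NA_real_; scc[i] <- NA_real_
      n_const <- n_const + 1L
      next
    }
    pcc[i] <- sum((y - mean(y)) * (yt - mean(yt))) /
      (sqrt(sum((y - mean(y))^2)) * sqrt(sum((yt - mean(yt))^2)))
    d <- rank_mid(y) - rank_mid(yt)
    scc[i] <- 1 - 6 * sum(d^2) / (g * (g^2 - 1))
  }
  if (n_const > 0L) {
    warning(n_const, " spots with constant expression; correlations NA")
  }
  per_spot <- data.frame(rmse = rmse, pcc = pcc, scc = scc)
  structure(
    list(per_spot = per_spot,
         summary = c(rmse = stats::median(rmse),
                     pcc = stats::median(pcc, na.rm = TRUE),
                     scc = stats::median(scc, na.rm = TRUE))),
    class = "cv_report"
  )
}

#' Spatial cross-validation of the deconvolution pipeline
#'
#' Cluster labels are fixed up front (computed once from the full data
#' unless supplied), so fold stratification follows the known cluster
#' structure. For each fold: the deconvolution stages (pseudo-bulk,
#' reference, OLS) run on training spots only; test-spot proportions are
#' predicted by neighbor averaging over training spots; predicted
#' expression is reconstructed by convolution with the reference
#' cell-type means; and the reconstruction is scored against the observed
#' test expression. Everything downstream of the cluster labels depends
#' only on training-spot expression, so perturbing test spots leaves the
#' training artifacts untouched.
#'
#' @param st an [st_dataset].
#' @param sc an [sc_reference].
#' @param config a [declust_config].
#' @param final_labels optional precomputed per-spot cluster labels;
#'   computed by [cluster_spots] on the full data when NULL.
#' @param genes optional fixed shared gene space; like the cluster
#'   labels, the gene space is part of the upstream structure fixed
#'   before fold assignment (computed from the full data when NULL).
#' @param n_folds number of folds (default `config$folds`).
#' @return a `cv_report` (see [cv_metrics]) with the fold assignment and
#'   per-spot predictions attached.
#' @export
run_cv <- function(st, sc, config = declust_config(), final_labels = NULL,
                   genes = NULL, n_folds = config$folds) {
  if (is.null(genes)) {
    st_var <- select_variable_genes(st, top_n = config$top_n_genes,
                                    on = config$vargenes_on)
    sc_var <- select_variable_genes(sc, top_n = config$top_n_genes,
                                    on = config$vargenes_on)
    genes <- intersect_genes(st_var, sc_var)$genes
  }
  shared <- intersect_genes(genes, intersect(st$gene_ids, sc$gene_ids))
  st_sub <- st_dataset(st$expr[, shared$genes, drop = FALSE], st$coords)
  sc_sub <- sc_reference(sc$expr[, shared$genes, drop = FALSE],
                         sc$cell_types)
  if (is.null(final_labels)) {
    final_labels <- cluster_spots(st_sub, config,
                                  genes = shared$genes)$final_labels
  }
  folds <- make_folds(final_labels, st_sub$coords, n_folds = n_folds,
                      rng_seed = stage_seed(config$rng_seed, "folds"),
                      neighbor_k = config$neighbor_k,
                      neighbor_radius = config$neighbor_radius)

  markers <- select_markers(sc_sub, t = config$t_markers,
                            alpha1 = config$alpha1, alpha2 = config$alpha2,
                            var_floor_frac = config$var_floor_frac)
  ref <- build_reference(sc_sub, markers)

  n <- nrow(st_sub$expr)
  pred_expr <- matrix(NA_real_, n, length(shared$genes),
                      dimnames = list(st_sub$spot_ids, shared$genes))
  pred_prop <- matrix(NA_real_, n, length(ref$cell_types),
                      dimnames = list(st_sub$spot_ids, ref$cell_types))
  type_means <- t(vapply(ref$cell_types, function(ty) {
    colMeans(sc_sub$expr[sc_sub$cell_types == ty, , drop = FALSE])
  }, numeric(length(shared$genes))))

  for (f in seq_len(n_folds)) {
    test_idx <- which(folds$fold == f)
    if (length(test_idx) == 0L) next
    train_idx <- which(folds$fold != f)
    res <- tryCatch({
      xstar <- pseudo_bulk(st_sub$expr[train_idx, , drop = FALSE],
                           final_labels[train_idx],
                           agg = config$pseudo_bulk_agg)
      Y <- ols_deconvolve(xstar[, ref$genes, drop = FALSE], ref,
                          method = config$deconv_method)
      Y_train <- expand_to_spots(Y, final_labels[train_idx],
                                 spot_ids = st_sub$spot_ids[train_idx])
      neighbor_average_predict(Y_train, st_sub$coords, train_idx,
                               test_idx,
                               neighbor_k = config$neighbor_k,
                               neighbor_radius = config$neighbor_radius)
    }, error = function(e) {
      stop("run_cv: fold ", f, ": ", conditionMessage(e))
    })
    pred_prop[test_idx, ] <- res
    pred_expr[test_idx, ] <- res %*% type_means
  }
  # score on the library-size-normalized log scale: the observed spot
  # aggregates ~cells_per_spot cells while the reconstruction is on the
  # single-cell scale, so raw-scale RMSE would measure library size
  report <- cv_metrics(suppressWarnings(normalize_counts(st_sub$expr)),
                       suppressWarnings(normalize_counts(pred_expr)))
  report$folds <- folds
  report$pred_prop <- pred_prop
  report$pred_expr <- pred_expr
  report$final_labels <- final_labels
  report
}
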