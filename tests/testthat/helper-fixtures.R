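# Small in-code fixtures and independent oracles shared across tests.

# A tiny annotated reference with Gaussian-ish separation between types.
tiny_sc <- function(k = 3, n_per_type = 20, n_genes = 30, effect = 5,
                    seed = 42) {
  stopifnot(n_genes >= 3 * k)
  set.seed(seed)
  types <- paste0("T", seq_len(k))
  labels <- rep(types, each = n_per_type)
  expr <- matrix(rpois(k * n_per_type * n_genes, lambda = 2),
                 k * n_per_type, n_genes,
                 dimnames = list(paste0("c", seq_len(k * n_per_type)),
                                 paste0("g", seq_len(n_genes))))
  for (ti in seq_len(k)) {
    marker_cols <- (ti - 1) * 3 + 1:3
    expr[labels == types[ti], marker_cols] <-
      expr[labels == types[ti], marker_cols] + effect
  }
  sc_reference(expr, labels)
}

# Independent DBSCAN oracle built from first principles: core points are
# found directly, core-core reachability resolved with a union-find, and
# border points attached afterwards. Returns list(labels, core).
brute_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                 logical(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in which(core)) {
    if (j > i && d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  labels <- integer(n)
  roots <- unique(vapply(which(core), find, integer(1)))
  for (r in seq_along(roots)) {
    labels[core & vapply(seq_len(n), find, integer(1)) == roots[r]] <- r
  }
  for (i in which(!core)) {
    nb_core <- which(core & d[i, ] <= eps)
    if (length(nb_core) > 0) labels[i] <- labels[nb_core[1]]
  }
  list(labels = labels, core = core)
}

# Partition agreement up to label permutation (0/noise must match exactly).
same_partition <- function(a, b) {
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  keep <- a != 0L
  a <- a[keep]; b <- b[keep]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Explicit normal-equations implementation of the clip+renormalize
# estimator, independent of the package's QR path.
oracle_clipped_ols <- function(X_star, Z_hat) {
  D <- t(Z_hat)
  t(apply(X_star, 1, function(x) {
    y <- pmax(drop(solve(t(D) %*% D) %*% t(D) %*% x), 0)
    y / sum(y)
  }))
}

# quick lattice coordinates
lattice_coords <- function(n_side) {
  as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
}
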