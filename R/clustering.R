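#' Within-cluster sum of squares
#'
#' WCSS = sum over clusters j, spots i of ||x_i^(j) - mu_j||^2, where mu_j
#' is the per-cluster mean expression profile. Empty clusters contribute 0.
#'
#' @param expr matrix, spots in rows.
#' @param labels cluster label per row.
#' @return nonnegative scalar.
#' @export
wcss <- function(expr, labels) {
  if (length(labels) != nrow(expr)) stop("wcss: one label per row required")
  total <- 0
  for (lv in unique(labels)) {
    rows <- expr[labels == lv, , drop = FALSE]
    if (nrow(rows) == 0L) next
    mu <- colMeans(rows)
    total <- total + sum(sweep(rows, 2, mu)^2)
  }
  total
}

#' Agglomerative clustering of spots by expression
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between
#' (normalized) expression profiles, cut at `h` clusters.
#'
#' @param expr matrix, spots in rows (normalized expression recommended).
#' @param h number of clusters, 1 <= h <= nrow(expr).
#' @return integer labels in 1..h.
#' @export
hierarchical_cluster <- function(expr, h) {
  n <- nrow(expr)
  if (h < 1L || h > n) stop("hierarchical_cluster: need 1 <= h <= ", n)
  hc <- stats::hclust(stats::dist(expr), method = "ward.D2")
  unname(stats::cutree(hc, k = h))
}

#' Choose the number of initial clusters by the elbow of the WCSS curve
#'
#' Computes the WCSS over a range of cluster counts from a single Ward
#' dendrogram (so the partitions are nested and the curve non-increasing)
#' and selects the elbow as the cluster count maximizing the discrete
#' second difference of the curve. A flat curve falls back to the smallest
#' count with a warning.
#'
#' @param expr matrix, spots in rows.
#' @param h_range candidate cluster counts (default `2:15`), clipped to
#'   the number of spots.
#' @return list of class `hierarchical_result` with `labels` (at
#'   `chosen_h`), `wcss_curve` (named by h), `chosen_h`, and
#'   `labels_by_h` (matrix of labels for every candidate h).
#' @export
choose_h_elbow <- function(expr, h_range = 2:15) {
  n <- nrow(expr)
  h_range <- sort(unique(pmin(h_range, n)))
  if (length(h_range) < 1L) stop("choose_h_elbow: empty h range")
  hc <- stats::hclust(stats::dist(expr), method = "ward.D2")
  labels_by_h <- sapply(h_range, function(h) stats::cutree(hc, k = h))
  if (is.null(dim(labels_by_h))) labels_by_h <- matrix(labels_by_h, nrow = n)
  colnames(labels_by_h) <- h_range
  curve <- apply(labels_by_h, 2, function(l) wcss(expr, l))
  names(curve) <- h_range
  tol <- 1e-10 * max(1, curve[1])
  if (max(curve) - min(curve) <= tol || length(h_range) < 3L) {
    if (max(curve) - min(curve) <= tol) {
      warning("choose_h_elbow: flat WCSS curve; using smallest h")
    }
    chosen <- h_range[1]
  } else {
    # second difference of the log curve at interior points; the log makes
    # the criterion scale-free, so the elbow is where the *relative* WCSS
    # reduction collapses, not where the absolute drop is largest
    lc <- log(curve + tol)
    d2 <- lc[-c(length(lc) - 1, length(lc))] - 2 * lc[-c(1, length(lc))] +
      lc[-c(1, 2)]
    chosen <- h_range[which.max(d2) + 1L]
  }
  structure(
    list(labels = unname(labels_by_h[, as.character(chosen)]),
         wcss_curve = curve, chosen_h = chosen,
         labels_by_h = labels_by_h),
    class = "hierarchical_result"
  )
}

#' Spatial neighbors of each spot
#'
#' For each spot, the up-to-`k` nearest spots by Euclidean coordinate
#' distance within `radius` grid units. This definition covers both square
#' lattices and hex-packed Visium rows, where literal 8-adjacency is
#' ill-defined.
#'
#' @param coords n x 2 coordinate matrix (array-grid units).
#' @param k maximum number of neighbors (default 8).
#' @param radius maximum distance (default 2).
#' @return list of integer index vectors, one per spot.
#' @export
spot_neighbors <- function(coords, k = 8, radius = 2) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  lapply(seq_len(n), function(i) {
    di <- d[i, ]
    cand <- setdiff(which(di <= radius), i)
    cand[order(di[cand], cand)][seq_len(min(k, length(cand)))]
  })
}

#' Tissue-boundary spots
#'
#' A spot is a boundary spot when it has fewer than the full complement of
#' `k` spatial neighbors within `radius` — i.e. it sits at the edge of the
#' captured tissue.
#'
#' @inheritParams spot_neighbors
#' @return logical vector, TRUE for boundary spots.
#' @export
boundary_spots <- function(coords, k = 8, radius = 2) {
  nb <- spot_neighbors(coords, k = k, radius = radius)
  lengths(nb) < k
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Standard DBSCAN on Euclidean coordinate distance: core points have at
#' least `min_pts` points (including themselves) within `eps`; clusters
#' are the density-connected components of core points plus their border
#' points; unreachable points are labeled 0 (noise).
#'
#' @param coords n x 2 coordinate matrix.
#' @param eps reachability radius (default 4, array-grid units).
#' @param min_pts minimum neighborhood size for a core point (default 8).
#' @return integer labels; 0 marks noise.
#' @export
dbscan_cluster <- function(coords, eps = 4, min_pts = 8) {
  n <- nrow(coords)
  labels <- integer(n)                 # 0 = noise / unvisited
  if (n == 0L) return(labels)
  d <- as.matrix(stats::dist(coords))
  nbhd <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl. self
  core <- lengths(nbhd) >= min_pts
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nbhd[[i]], i)
    while (length(frontier) > 0L) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) {
          frontier <- c(frontier, setdiff(nbhd[[j]], which(labels != 0L)))
        }
      }
    }
  }
  labels
}

#' Spatial sub-clusters of each initial expression cluster
#'
#' Runs DBSCAN on the coordinates of each initial (expression-derived)
#' cluster's spots separately. Sub-cluster ids are globally unique across
#' initial clusters; 0 marks noise.
#'
#' @param coords n x 2 coordinate matrix for all spots.
#' @param initial_labels per-spot initial cluster id.
#' @inheritParams dbscan_cluster
#' @return list with `subcluster` (per-spot global sub-cluster id, 0 =
#'   noise) and `parent` (named map sub-cluster id -> initial cluster id).
#' @export
dbscan_subclusters <- function(coords, initial_labels, eps = 4, min_pts = 8) {
  n <- nrow(coords)
  sub <- integer(n)
  parent <- integer(0)
  next_id <- 0L
  for (cl in sort(unique(initial_labels))) {
    idx <- which(initial_labels == cl)
    local <- dbscan_cluster(coords[idx, , drop = FALSE],
                            eps = eps, min_pts = min_pts)
    pos <- local > 0L
    sub[idx[pos]] <- local[pos] + next_id
    n_local <- if (any(pos)) max(local) else 0L
    if (n_local > 0L) {
      parent[as.character(next_id + seq_len(n_local))] <- cl
    }
    next_id <- next_id + n_local
  }
  list(subcluster = sub, parent = parent)
}

#' Select region-growing seeds from spatial sub-clusters
#'
#' Sub-clusters holding fewer than `frac_threshold` of all spots in the
#' dataset contribute no seeds. From each qualifying sub-cluster,
#' `floor(seed_frac * n_eligible)` spots are sampled uniformly without
#' replacement from its non-boundary members and labeled by the
#' sub-cluster.
#'
#' @param subclusters result of [dbscan_subclusters] (or an integer vector
#'   of per-spot sub-cluster ids with 0 = noise).
#' @param coords n x 2 coordinate matrix (used for the boundary rule).
#' @param frac_threshold minimum sub-cluster size as a fraction of all
#'   spots (default 0.05).
#' @param seed_frac fraction of eligible members sampled as seeds
#'   (default 0.5).
#' @param neighbor_k,neighbor_radius spatial-neighbor definition used for
#'   the boundary rule (see [boundary_spots]).
#' @param rng_seed integer seed making the sampling reproducible.
#' @return list of class `seed_set` with `seed_spots` (indices),
#'   `seed_labels` (sub-cluster id per seed), `subcluster` (per-spot).
#' @export
select_seeds <- function(subclusters, coords, frac_threshold = 0.05,
                         seed_frac = 0.5, neighbor_k = 8,
                         neighbor_radius = 2, rng_seed = 1L) {
  sub <- if (is.list(subclusters)) subclusters$subcluster else subclusters
  n <- length(sub)
  boundary <- boundary_spots(coords, k = neighbor_k, radius = neighbor_radius)
  seed_spots <- integer(0)
  seed_labels <- integer(0)
  ids <- sort(setdiff(unique(sub), 0L))
  with_seed(rng_seed, {
    for (id in ids) {
      members <- which(sub == id)
      if (length(members) < frac_threshold * n) next
      eligible <- members[!boundary[members]]
      if (length(eligible) == 0L) {
        warning("sub-cluster ", id, " has only boundary spots; no seeds")
        next
      }
      n_take <- floor(seed_frac * length(eligible))
      if (n_take == 0L) next
      take <- sort(sample(eligible, n_take))
      seed_spots <- c(seed_spots, take)
      seed_labels <- c(seed_labels, rep(id, n_take))
    }
  })
  if (length(seed_spots) == 0L) {
    stop("select_seeds: no seeds selected; relax frac_threshold/seed_frac")
  }
  structure(list(seed_spots = seed_spots, seed_labels = seed_labels,
                 subcluster = sub),
            class = "seed_set")
}

#' Seeded region growing over the spot lattice
#'
#' Grows labeled regions outward from the seed set. A sequentially sorted
#' list (SSL) holds the unlabeled spatial neighbors of the labeled region,
#' keyed by the Euclidean expression distance between the spot and the
#' running mean profile of the adjacent region. Each iteration pops the
#' minimum-distance spot (ties broken by spot index), assigns its label —
#' the unanimous label of its labeled neighbors, or, when neighbors
#' disagree, the label of the region nearest in expression space — updates
#' that region's running mean, and pushes the spot's unlabeled neighbors.
#' Spots never reached (spatially disconnected from all seeds) are assigned
#' post hoc to the expression-nearest region with a warning. Final clusters
#' are relabeled 1..h by decreasing size, and clusters smaller than
#' `min_cluster_size` are merged into the expression-nearest cluster.
#'
#' @param expr normalized expression matrix, spots in rows.
#' @param coords n x 2 coordinate matrix.
#' @param seed_set a `seed_set` from [select_seeds].
#' @param neighbor_k,neighbor_radius spatial-neighbor definition.
#' @param min_cluster_size clusters below this size are merged (default 3).
#' @return list of class `clustering_result` with `final_labels` (1..h),
#'   `n_clusters`, `seed_set`, `seed_fixed` (logical: seeds kept labels).
#' @export
srg <- function(expr, coords, seed_set, neighbor_k = 8, neighbor_radius = 2,
                min_cluster_size = 3) {
  n <- nrow(expr)
  nb <- spot_neighbors(coords, k = neighbor_k, radius = neighbor_radius)
  labels <- integer(n)  # 0 = unlabeled; values are seed (sub-cluster) ids
  labels[seed_set$seed_spots] <- seed_set$seed_labels

  region_ids <- sort(unique(seed_set$seed_labels))
  rkey <- match(labels, region_ids)  # NA for unlabeled
  region_sum <- matrix(0, length(region_ids), ncol(expr))
  region_n <- integer(length(region_ids))
  for (s in seq_along(seed_set$seed_spots)) {
    r <- match(seed_set$seed_labels[s], region_ids)
    region_sum[r, ] <- region_sum[r, ] + expr[seed_set$seed_spots[s], ]
    region_n[r] <- region_n[r] + 1L
  }

  dist_to_region <- function(i, r) {
    mu <- region_sum[r, ] / region_n[r]
    sqrt(sum((expr[i, ] - mu)^2))
  }

  # SSL: for each candidate spot, the minimum distance to an adjacent region
  ssl_dist <- rep(NA_real_, n)
  in_ssl <- logical(n)
  push <- function(i) {
    regs <- unique(stats::na.omit(rkey[nb[[i]]]))
    if (length(regs) == 0L) return(invisible(NULL))
    dmin <- min(vapply(regs, function(r) dist_to_region(i, r), numeric(1)))
    if (!in_ssl[i] || dmin < ssl_dist[i]) {
      ssl_dist[i] <<- dmin
      in_ssl[i] <<- TRUE
    }
    invisible(NULL)
  }
  for (i in which(labels == 0L)) {
    if (any(!is.na(rkey[nb[[i]]]))) push(i)
  }

  while (any(in_ssl)) {
    cand <- which(in_ssl)
    p <- cand[order(ssl_dist[cand], cand)][1]
    in_ssl[p] <- FALSE
    ssl_dist[p] <- NA_real_
    nb_regs <- unique(stats::na.omit(rkey[nb[[p]]]))
    if (length(nb_regs) == 0L) next   # stale entry; re-pushed later if reachable
    r <- if (length(nb_regs) == 1L) {
      nb_regs
    } else {
      dd <- vapply(nb_regs, function(r) dist_to_region(p, r), numeric(1))
      nb_regs[order(dd, nb_regs)][1]
    }
    labels[p] <- region_ids[r]
    rkey[p] <- r
    region_sum[r, ] <- region_sum[r, ] + expr[p, ]
    region_n[r] <- region_n[r] + 1L
    for (q in nb[[p]]) if (labels[q] == 0L) push(q)
  }

  unreached <- which(labels == 0L)
  if (length(unreached) > 0L) {
    warning(length(unreached),
            " spots disconnected from all seeds; assigned to the ",
            "expression-nearest region")
    for (i in unreached) {
      dd <- vapply(seq_along(region_ids), function(r) dist_to_region(i, r),
                   numeric(1))
      r <- which.min(dd)
      labels[i] <- region_ids[r]
      rkey[i] <- r
    }
  }

  seed_fixed <- all(labels[seed_set$seed_spots] == seed_set$seed_labels)

  # merge undersized clusters into the expression-nearest other cluster
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cluster_size]
    if (length(small) == 0L || length(sizes) <= 1L) break
    id <- as.integer(small[1])
    others <- as.integer(setdiff(names(sizes), small[1]))
    mu_small <- colMeans(expr[labels == id, , drop = FALSE])
    dd <- vapply(others, function(o) {
      sum((mu_small - colMeans(expr[labels == o, , drop = FALSE]))^2)
    }, numeric(1))
    labels[labels == id] <- others[which.min(dd)]
  }

  # relabel 1..h by decreasing size (ties by original id)
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  final <- unname(remap[as.character(labels)])

  structure(
    list(final_labels = final, n_clusters = length(remap),
         seed_set = seed_set, seed_fixed = seed_fixed,
         raw_labels = labels),
    class = "clustering_result"
  )
}

#' Pseudo-bulk aggregation of spot expression by cluster
#'
#' Aggregates linear-scale expression over the spots of each cluster. The
#' default is the mean, so cluster size does not scale the response and
#' the pseudo-bulk stays commensurate with per-cell reference profiles.
#'
#' @param expr linear-scale expression matrix, spots in rows.
#' @param labels per-spot cluster label (1..h).
#' @param agg `"mean"` (default) or `"sum"`.
#' @return h x g matrix, rows named by cluster id in increasing order.
#' @export
pseudo_bulk <- function(expr, labels, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  ids <- sort(unique(labels))
  out <- t(vapply(ids, function(j) {
    rows <- expr[labels == j, , drop = FALSE]
    if (agg == "mean") colMeans(rows) else colSums(rows)
  }, numeric(ncol(expr))))
  rownames(out) <- ids
  colnames(out) <- colnames(expr)
  out
}
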