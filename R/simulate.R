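#' Simulate one spot's expression from reference cells
#'
#' Draws cell counts per type from a multinomial with the given
#' proportions and a fixed total (default 10 cells per spot, within the
#' range observed on Visium arrays), samples that many cells of each type
#' uniformly with replacement from the reference, and sums their
#' linear-scale expression.
#'
#' @param proportions numeric vector over the reference cell types,
#'   summing to 1 (named by type, or ordered as `levels(sc$cell_types)`).
#' @param sc an [sc_reference].
#' @param cells_per_spot total cells in the spot (default 10).
#' @param pools optional named list restricting the cell indices sampled
#'   per type (used for ligand-receptor enrichment).
#' @return list with `profile` (gene vector), `counts` (cells per type),
#'   `cells` (sampled cell indices).
#' @export
simulate_spot <- function(proportions, sc, cells_per_spot = 10,
                          pools = NULL) {
  types <- levels(sc$cell_types)
  if (!is.null(names(proportions))) {
    proportions <- proportions[types]
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("simulate_spot: proportions must sum to 1")
  }
  counts <- as.integer(stats::rmultinom(1, cells_per_spot, proportions))
  names(counts) <- types
  cells <- integer(0)
  for (ti in seq_along(types)) {
    if (counts[ti] == 0L) next
    pool <- if (!is.null(pools) && !is.null(pools[[types[ti]]])) {
      pools[[types[ti]]]
    } else {
      which(sc$cell_types == types[ti])
    }
    if (length(pool) == 0L) {
      stop("simulate_spot: positive count for type '", types[ti],
           "' but its cell pool is empty")
    }
    cells <- c(cells, pool[sample.int(length(pool), counts[ti],
                                      replace = TRUE)])
  }
  profile <- colSums(sc$expr[cells, , drop = FALSE])
  list(profile = profile, counts = counts, cells = cells)
}

#' Simulate an ST dataset with known cell-type proportions
#'
#' Applies [simulate_spot] at every coordinate, preserving the spatial
#' layout of `coords` while controlling the per-spot cell-type mixture.
#' The recorded truth is the realized mixture: multinomial counts divided
#' by `cells_per_spot`.
#'
#' @param coords n x 2 spot coordinates (copied to the output).
#' @param S n x k matrix of target proportions (one row per spot; rows
#'   sum to 1), columns ordered/named by the reference cell types.
#' @param sc an [sc_reference].
#' @param cells_per_spot cells per spot (default 10).
#' @param rng_seed integer seed.
#' @param pools_by_spot optional list (length n) of per-type pool
#'   restrictions, see [simulate_spot].
#' @return list of class `simulated_st` with `st` (an [st_dataset]),
#'   `truth` (n x k realized proportions), `target` (S),
#'   `cell_assignments` (list of sampled cell indices per spot).
#' @export
simulate_dataset <- function(coords, S, sc, cells_per_spot = 10,
                             rng_seed = 1L, pools_by_spot = NULL) {
  coords <- as.matrix(coords)
  S <- as.matrix(S)
  if (nrow(S) != nrow(coords)) {
    stop("simulate_dataset: S must have one row per spot")
  }
  types <- levels(sc$cell_types)
  n <- nrow(coords)
  expr <- matrix(0, n, ncol(sc$expr),
                 dimnames = list(paste0("spot", seq_len(n)),
                                 colnames(sc$expr)))
  truth <- matrix(0, n, length(types),
                  dimnames = list(rownames(expr), types))
  assignments <- vector("list", n)
  with_seed(rng_seed, {
    for (i in seq_len(n)) {
      pools <- if (!is.null(pools_by_spot)) pools_by_spot[[i]] else NULL
      sp <- simulate_spot(S[i, ], sc, cells_per_spot, pools)
      expr[i, ] <- sp$profile
      truth[i, ] <- sp$counts / cells_per_spot
      assignments[[i]] <- sp$cells
    }
  })
  structure(
    list(st = st_dataset(expr, coords), truth = truth, target = S,
         cell_assignments = assignments),
    class = "simulated_st"
  )
}

#' Cells co-expressing a ligand-receptor pair
#'
#' Returns the reference cells whose expression of both the ligand and
#' the receptor gene is at or above the given quantile (computed over all
#' cells; ties pass via >=, type-7 quantiles).
#'
#' @param sc an [sc_reference].
#' @param ligand,receptor gene ids present in the reference.
#' @param quantile_cut quantile threshold (default 0.75: third quartile).
#' @return integer vector of cell indices.
#' @export
lr_filter_cells <- function(sc, ligand, receptor, quantile_cut = 0.75) {
  for (g in c(ligand, receptor)) {
    if (!g %in% sc$gene_ids) stop("lr_filter_cells: gene not found: ", g)
  }
  lg <- sc$expr[, ligand]
  rc <- sc$expr[, receptor]
  ok <- lg >= stats::quantile(lg, quantile_cut, type = 7) &
    rc >= stats::quantile(rc, quantile_cut, type = 7)
  if (!any(ok)) {
    stop("lr_filter_cells: no cells pass at quantile ", quantile_cut,
         "; lower the quantile")
  }
  unname(which(ok))
}

#' Simulate an ST dataset with ligand-receptor co-enrichment
#'
#' Like [simulate_dataset], but spots of designated clusters sample the
#' two named cell types only from cells co-expressing the given
#' ligand-receptor pair above the quantile threshold, mimicking
#' cell-type co-localization driven by intercellular signaling. Cluster
#' labels, cluster-level proportions, and LR gene pairs are inputs
#' (typically produced by external spatial-domain, bulk-deconvolution and
#' LR-inference tools).
#'
#' @param coords n x 2 spot coordinates.
#' @param cluster_labels per-spot cluster label.
#' @param S_cluster one proportion row per cluster (rownames = cluster
#'   ids), broadcast to the cluster's spots.
#' @param sc an [sc_reference].
#' @param enrichments data.frame with columns `cluster`, `ligand`,
#'   `receptor`, `type1`, `type2`, and optionally `quantile`
#'   (default 0.75).
#' @param cells_per_spot cells per spot (default 10).
#' @param rng_seed integer seed.
#' @return a `simulated_st` (see [simulate_dataset]).
#' @export
simulate_lr_enriched <- function(coords, cluster_labels, S_cluster, sc,
                                 enrichments, cells_per_spot = 10,
                                 rng_seed = 1L) {
  coords <- as.matrix(coords)
  S_cluster <- as.matrix(S_cluster)
  idx <- match(as.character(cluster_labels), rownames(S_cluster))
  if (anyNA(idx)) stop("simulate_lr_enriched: clusters without proportions")
  S <- S_cluster[idx, , drop = FALSE]

  pools_by_cluster <- list()
  if (!is.null(enrichments) && nrow(enrichments) > 0) {
    for (r in seq_len(nrow(enrichments))) {
      e <- enrichments[r, ]
      q <- if (!is.null(e$quantile) && !is.na(e$quantile)) e$quantile else 0.75
      passing <- lr_filter_cells(sc, e$ligand, e$receptor, q)
      pools <- list()
      for (ty in c(e$type1, e$type2)) {
        pool <- intersect(passing, which(sc$cell_types == ty))
        if (length(pool) == 0L) {
          stop("simulate_lr_enriched: no ", ty, " cells pass the ",
               e$ligand, "-", e$receptor, " filter")
        }
        pools[[ty]] <- pool
      }
      pools_by_cluster[[as.character(e$cluster)]] <- pools
    }
  }
  pools_by_spot <- lapply(as.character(cluster_labels), function(cl) {
    pools_by_cluster[[cl]]
  })
  simulate_dataset(coords, S, sc, cells_per_spot, rng_seed,
                   pools_by_spot = pools_by_spot)
}

# Contiguous domain layouts on a rectangular lattice.
domain_layout_labels <- function(coords, k, layout = c("quadrants",
                                                       "stripes")) {
  layout <- match.arg(layout)
  x <- coords[, 1]; y <- coords[, 2]
  if (layout == "quadrants") {
    if (k != 4L) stop("quadrants layout requires k = 4")
    1L + (x > stats::median(x)) + 2L * (y > stats::median(y))
  } else {
    cut_pts <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1))
    as.integer(cut(x, breaks = cut_pts, include.lowest = TRUE))
  }
}

#' Generate a fully synthetic reference + ST fixture
#'
#' Builds an annotated single-cell reference with negative-binomial
#' baseline counts and planted marker genes (an `effect_size` fold-change
#' in one cell type each), lays out a rectangular spot lattice partitioned
#' into contiguous domains with domain-specific proportion vectors (each
#' domain dominated by one cell type), and simulates the ST expression
#' with [simulate_dataset]. Everything is seeded and reproducible.
#'
#' @param n_side lattice side length (n_spots = n_side^2, default 20).
#' @param n_genes genes in the reference (default 200).
#' @param k cell types (default 4).
#' @param n_cells_per_type reference cells per type (default 50).
#' @param markers_per_type planted markers per type (default 10).
#' @param effect_size marker fold-change (default 4).
#' @param dominant_prop proportion of the dominant type in its domain
#'   (default 0.85; the rest is split evenly). Note that against the
#'   realized truth (counts / cells_per_spot) the per-type MSE of any
#'   cluster-constant estimator is bounded below by the multinomial
#'   variance floor mean of p(1-p)/cells_per_spot, so domain purity and
#'   cells per spot jointly set the attainable error.
#' @param cells_per_spot cells per simulated spot (default 10).
#' @param domain_layout `"quadrants"` (default, k = 4) or `"stripes"`.
#' @param nb_mu,nb_size negative-binomial baseline mean and dispersion
#'   parameters for reference counts (defaults 2 and 2; at these values
#'   the baseline SD is 2, so the default fold-change-4 marker shift of
#'   6 counts is a 3-SD effect).
#' @param rng_seed integer seed.
#' @return list of class `declust_fixture` with `sc` ([sc_reference]),
#'   `sim` (`simulated_st`), `st` ([st_dataset]), `S` (spot-level truth),
#'   `domains` (per-spot domain id), `planted_markers` (named list of
#'   gene ids per type).
#' @export
make_fixture <- function(n_side = 20, n_genes = 200, k = 4,
                         n_cells_per_type = 50, markers_per_type = 10,
                         effect_size = 4, dominant_prop = 0.85,
                         cells_per_spot = 10,
                         domain_layout = "quadrants",
                         nb_mu = 2, nb_size = 2, rng_seed = 1L) {
  stopifnot(n_side >= 2, n_genes >= k * markers_per_type, k >= 2,
            n_cells_per_type >= 2, markers_per_type >= 1)
  types <- paste0("type", seq_len(k))
  genes <- sprintf("g%04d", seq_len(n_genes))
  m <- k * n_cells_per_type
  planted <- stats::setNames(lapply(seq_len(k), function(ti) {
    genes[(ti - 1) * markers_per_type + seq_len(markers_per_type)]
  }), types)

  sc <- with_seed(stage_seed(rng_seed, "markers"), {
    mu <- matrix(nb_mu, m, n_genes, dimnames = list(NULL, genes))
    labels <- rep(types, each = n_cells_per_type)
    for (ti in seq_len(k)) {
      mu[labels == types[ti], planted[[types[ti]]]] <- nb_mu * effect_size
    }
    counts <- matrix(stats::rnbinom(m * n_genes, mu = as.vector(mu),
                                    size = nb_size),
                     m, n_genes, dimnames = list(
                       paste0("cell", seq_len(m)), genes))
    sc_reference(counts, labels)
  })

  coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
  domains <- domain_layout_labels(coords, k = min(k, 4L),
                                  layout = domain_layout)
  S <- matrix((1 - dominant_prop) / (k - 1), nrow(coords), k,
              dimnames = list(NULL, types))
  for (d in seq_len(max(domains))) {
    S[domains == d, ((d - 1) %% k) + 1] <- dominant_prop
  }
  S <- S / rowSums(S)

  sim <- simulate_dataset(coords, S, sc, cells_per_spot = cells_per_spot,
                          rng_seed = stage_seed(rng_seed, "simulate"))
  structure(
    list(sc = sc, sim = sim, st = sim$st, S = sim$truth, target_S = S,
         domains = domains, planted_markers = planted),
    class = "declust_fixture"
  )
}
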