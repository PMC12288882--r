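#' Pipeline configuration
#'
#' Collects every tunable of the deconvolution pipeline with its default.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults: `top_n_genes` (5000), `eps` (4),
#'   `min_pts` (8), `frac_threshold` (0.05), `seed_frac` (0.5), `h_range`
#'   (2:15), `t_markers` (10), `alpha1` (0.05), `alpha2` (0.05),
#'   `cells_per_spot` (10), `folds` (10), `rng_seed` (1), `neighbor_k`
#'   (8), `neighbor_radius` (2), `min_cluster_size` (3), `normalization`
#'   ("cpm_log1p"), `target_sum` (1e4), `vargenes_on` ("lognorm"),
#'   `pseudo_bulk_agg` ("mean"), `deconv_method` ("clipped_ols"),
#'   `var_floor_frac` (0.01).
#' @return named list of class `declust_config`.
#' @export
declust_config <- function(...) {
  defaults <- list(
    top_n_genes = 5000, eps = 4, min_pts = 8, frac_threshold = 0.05,
    seed_frac = 0.5, h_range = 2:15, t_markers = 10, alpha1 = 0.05,
    alpha2 = 0.05, cells_per_spot = 10, folds = 10, rng_seed = 1L,
    neighbor_k = 8, neighbor_radius = 2, min_cluster_size = 3,
    normalization = "cpm_log1p", target_sum = 1e4,
    vargenes_on = "lognorm", pseudo_bulk_agg = "mean",
    deconv_method = "clipped_ols", var_floor_frac = 0.01
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("declust_config: unknown keys: ", paste(bad, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "declust_config")
}

#' Read a configuration file
#'
#' A plain `key = value` or `key: value` text file mirroring
#' [declust_config]; `h_range` accepts `a:b`. Unknown keys are rejected.
#'
#' @param path file path.
#' @return a `declust_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    if (!grepl("^[A-Za-z_.][A-Za-z0-9_.]*\\s*[:=]", ln)) {
      stop("read_config: cannot parse line '", ln, "'")
    }
    key <- sub("\\s*[:=].*$", "", ln)
    val <- trimws(sub("^[^:=]*[:=]\\s*", "", ln))
    over[[key]] <- if (grepl("^\\d+:\\d+$", val)) {
      r <- as.integer(strsplit(val, ":")[[1]]); r[1]:r[2]
    } else if (grepl("^-?[0-9.eE+-]+$", val)) {
      as.numeric(val)
    } else val
  }
  declust_config(over)
}

#' Cluster the spots of an ST dataset
#'
#' The spatial clustering stage: variable-gene selection and
#' normalization, Ward hierarchical clustering with the elbow rule,
#' per-cluster DBSCAN spatial sub-clustering, seed selection, and seeded
#' region growing.
#'
#' @param st an [st_dataset].
#' @param config a [declust_config].
#' @param genes optional gene subset used for clustering (default: top
#'   variable genes of `st`).
#' @return `clustering_result` (see [srg]) with the `hierarchical_result`
#'   and sub-cluster provenance attached.
#' @export
cluster_spots <- function(st, config = declust_config(), genes = NULL) {
  if (is.null(genes)) {
    genes <- select_variable_genes(st, top_n = config$top_n_genes,
                                   on = config$vargenes_on)
  }
  expr_norm <- suppressWarnings(normalize_counts(
    st$expr[, genes, drop = FALSE], method = config$normalization,
    target_sum = config$target_sum))
  hier <- choose_h_elbow(expr_norm, h_range = config$h_range)
  subc <- dbscan_subclusters(st$coords, hier$labels,
                             eps = config$eps, min_pts = config$min_pts)
  seeds <- select_seeds(subc, st$coords,
                        frac_threshold = config$frac_threshold,
                        seed_frac = config$seed_frac,
                        neighbor_k = config$neighbor_k,
                        neighbor_radius = config$neighbor_radius,
                        rng_seed = stage_seed(config$rng_seed, "seeds"))
  res <- srg(expr_norm, st$coords, seeds,
             neighbor_k = config$neighbor_k,
             neighbor_radius = config$neighbor_radius,
             min_cluster_size = config$min_cluster_size)
  res$hierarchical <- hier
  res$subclusters <- subc
  res$genes <- genes
  res
}

#' Run the full cluster-based deconvolution pipeline
#'
#' Orchestrates the stages end to end: shared gene space, spatial
#' clustering of spots, pseudo-bulk aggregation, marker-gene discovery
#' from the reference, constrained-OLS deconvolution at cluster level,
#' and expansion to spot level. Fully reproducible given
#' `config$rng_seed`.
#'
#' @param st an [st_dataset].
#' @param sc an [sc_reference].
#' @param config a [declust_config].
#' @return list of class `declust_result` with `clustering`,
#'   `marker_table`, `reference`, `Y` (cluster-level proportions),
#'   `Y_spot` (spot-level), `shared_genes`, `config`.
#' @export
run_declust <- function(st, sc, config = declust_config()) {
  st_var <- select_variable_genes(st, top_n = config$top_n_genes,
                                  on = config$vargenes_on)
  sc_var <- select_variable_genes(sc, top_n = config$top_n_genes,
                                  on = config$vargenes_on)
  shared <- intersect_genes(st_var, sc_var)
  st_sub <- st_dataset(st$expr[, shared$genes, drop = FALSE], st$coords)
  sc_sub <- sc_reference(sc$expr[, shared$genes, drop = FALSE],
                         sc$cell_types)

  clustering <- cluster_spots(st_sub, config, genes = shared$genes)

  markers <- select_markers(sc_sub, t = config$t_markers,
                            alpha1 = config$alpha1, alpha2 = config$alpha2,
                            var_floor_frac = config$var_floor_frac)
  ref <- build_reference(sc_sub, markers)

  xstar <- pseudo_bulk(st_sub$expr, clustering$final_labels,
                       agg = config$pseudo_bulk_agg)
  Y <- ols_deconvolve(xstar[, ref$genes, drop = FALSE], ref,
                      method = config$deconv_method)
  Y_spot <- expand_to_spots(Y, clustering$final_labels,
                            spot_ids = st_sub$spot_ids)

  structure(
    list(clustering = clustering, marker_table = markers, reference = ref,
         X_star = xstar, Y = Y, Y_spot = Y_spot,
         shared_genes = shared$genes, config = config),
    class = "declust_result"
  )
}

#' @export
print.declust_result <- function(x, ...) {
  cat("declust_result:", nrow(x$Y_spot), "spots,",
      x$clustering$n_clusters, "clusters,",
      ncol(x$Y), "cell types,", length(x$reference$genes),
      "marker genes\n")
  invisible(x)
}
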