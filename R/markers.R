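#' Up-regulation statistic (robust one-sided t)
#'
#' Welch-type t statistic of the target cell type's mean minus the mean of
#' all other cells, on (typically log1p-normalized) expression. A variance
#' floor — a fraction of the gene's pooled variance — guards against
#' zero-variance, dropout-heavy genes producing infinite statistics. The
#' p-value is the upper tail (positive statistic = up-regulated in the
#' target type).
#'
#' @param expr_gene numeric vector of one gene's expression over cells.
#' @param labels cell-type label per cell.
#' @param target_type the type tested for up-regulation.
#' @param var_floor_frac variance floor as a fraction of the gene's global
#'   variance (default 0.01).
#' @return list with `stat` and `p`.
#' @export
t1_statistic <- function(expr_gene, labels, target_type,
                         var_floor_frac = 0.01) {
  in_t <- labels == target_type
  x <- expr_gene[in_t]
  y <- expr_gene[!in_t]
  if (length(x) < 2L || length(y) < 2L) {
    stop("t1_statistic: need >= 2 cells in target and complement")
  }
  floor_v <- var_floor_frac * stats::var(expr_gene)
  vx <- max(stats::var(x), floor_v)
  vy <- max(stats::var(y), floor_v)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) return(list(stat = 0, p = 1))
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(stat = stat, p = stats::pt(stat, df = df, lower.tail = FALSE))
}

#' Homogeneity statistic across the remaining cell types (chi-square)
#'
#' Cochran's-Q-style heterogeneity chi-square over the per-type means of
#' the non-target cell types: Q = sum_c w_c (m_c - m_w)^2 with m_c the
#' type-c mean, w_c the inverse squared standard error of m_c, and m_w the
#' weighted grand mean. Under homogeneity Q ~ chi-square with
#' (number of remaining types - 1) degrees of freedom. Types with fewer
#' than 2 cells are excluded with a warning and the df reduced.
#'
#' @inheritParams t1_statistic
#' @param var_floor_frac variance floor as a fraction of the gene's global
#'   variance, applied per type (default 0.01).
#' @return list with `stat`, `p`, `df`.
#' @export
t2_statistic <- function(expr_gene, labels, target_type,
                         var_floor_frac = 0.01) {
  rest <- labels != target_type
  types <- unique(labels[rest])
  if (length(types) < 2L) {
    stop("t2_statistic: need >= 2 remaining cell types")
  }
  floor_v <- var_floor_frac * stats::var(expr_gene)
  ms <- ws <- numeric(0)
  for (ty in types) {
    v <- expr_gene[labels == ty]
    if (length(v) < 2L) {
      warning("t2_statistic: type '", ty, "' has < 2 cells; excluded")
      next
    }
    se2 <- max(stats::var(v), floor_v) / length(v)
    if (se2 == 0) se2 <- .Machine$double.eps
    ms <- c(ms, mean(v))
    ws <- c(ws, 1 / se2)
  }
  if (length(ms) < 2L) stop("t2_statistic: fewer than 2 usable types")
  mw <- sum(ws * ms) / sum(ws)
  q <- sum(ws * (ms - mw)^2)
  df <- length(ms) - 1L
  list(stat = q, p = stats::pchisq(q, df = df, lower.tail = FALSE), df = df)
}

# Vectorized T1/T2 over all genes for one target type. expr: cells x genes.
marker_stats_type <- function(expr, labels, target_type,
                              var_floor_frac = 0.01) {
  in_t <- labels == target_type
  nx <- sum(in_t); ny <- sum(!in_t)
  gv <- matrixStats_colVars(expr)
  floor_v <- var_floor_frac * gv
  mx <- colMeans(expr[in_t, , drop = FALSE])
  my <- colMeans(expr[!in_t, , drop = FALSE])
  vx <- pmax(matrixStats_colVars(expr[in_t, , drop = FALSE]), floor_v)
  vy <- pmax(matrixStats_colVars(expr[!in_t, , drop = FALSE]), floor_v)
  se2 <- vx / nx + vy / ny
  se2[se2 == 0] <- .Machine$double.eps
  t1 <- (mx - my) / sqrt(se2)
  df1 <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p1 <- stats::pt(t1, df = df1, lower.tail = FALSE)

  types <- setdiff(unique(labels), target_type)
  types <- types[vapply(types, function(ty) sum(labels == ty) >= 2L,
                        logical(1))]
  if (length(types) < 2L) {
    # heterogeneity among remaining types is not assessable
    q <- rep(0, ncol(expr))
    p2 <- rep(1, ncol(expr))
  } else {
    M <- vapply(types, function(ty) {
      colMeans(expr[labels == ty, , drop = FALSE])
    }, numeric(ncol(expr)))
    W <- vapply(types, function(ty) {
      rows <- expr[labels == ty, , drop = FALSE]
      se2c <- pmax(matrixStats_colVars(rows), floor_v) / nrow(rows)
      se2c[se2c == 0] <- .Machine$double.eps
      1 / se2c
    }, numeric(ncol(expr)))
    M <- matrix(M, nrow = ncol(expr))
    W <- matrix(W, nrow = ncol(expr))
    mw <- rowSums(W * M) / rowSums(W)
    q <- rowSums(W * (M - mw)^2)
    df2 <- length(types) - 1L
    p2 <- stats::pchisq(q, df = df2, lower.tail = FALSE)
  }
  data.frame(gene = colnames(expr), t1 = unname(t1), p1 = unname(p1),
             t2 = unname(q), p2 = unname(p2), stringsAsFactors = FALSE)
}

# column variances without extra dependencies
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Select cell-type-specific marker genes (two-statistic procedure)
#'
#' For each cell type, a gene qualifies when it is significantly
#' up-regulated in that type versus all others (T1 p-value < `alpha1`) and
#' shows no significant heterogeneity among the remaining types (T2
#' p-value > `alpha2`). Qualifying genes are ranked by descending T1
#' statistic (ties by gene id) and the top `t` kept. A cell type with no
#' qualifying gene falls back to the top `t` genes by T1 alone, with a
#' warning. Statistics are computed on log1p-normalized expression.
#'
#' @param sc an [sc_reference].
#' @param genes optional gene subset (default all reference genes).
#' @param t markers kept per cell type (default 10).
#' @param alpha1 T1 p-value threshold (default 0.05).
#' @param alpha2 T2 p-value threshold (default 0.05).
#' @param var_floor_frac see [t1_statistic].
#' @return data.frame of class `marker_table` with columns gene,
#'   cell_type, t1, p1, t2, p2, selected, rank.
#' @export
select_markers <- function(sc, genes = NULL, t = 10, alpha1 = 0.05,
                           alpha2 = 0.05, var_floor_frac = 0.01) {
  expr <- suppressWarnings(normalize_counts(sc$expr))
  if (!is.null(genes)) {
    bad <- setdiff(genes, colnames(expr))
    if (length(bad) > 0) stop("genes not in reference: ",
                              paste(utils::head(bad, 5), collapse = ", "))
    expr <- expr[, genes, drop = FALSE]
  }
  labels <- as.character(sc$cell_types)
  out <- list()
  for (ty in levels(sc$cell_types)) {
    st <- marker_stats_type(expr, labels, ty, var_floor_frac)
    st$cell_type <- ty
    pass <- st$p1 < alpha1 & st$p2 > alpha2
    if (!any(pass)) {
      warning("no genes pass the joint T1/T2 criterion for '", ty,
              "'; falling back to top ", t, " by T1")
      pool <- st
    } else {
      pool <- st[pass, , drop = FALSE]
    }
    pool <- pool[order(-pool$t1, pool$gene), , drop = FALSE]
    keep <- utils::head(pool, t)
    st$selected <- st$gene %in% keep$gene
    st$rank <- NA_integer_
    st$rank[match(keep$gene, st$gene)] <- seq_len(nrow(keep))
    out[[ty]] <- st
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("gene", "cell_type", "t1", "p1", "t2", "p2",
                 "selected", "rank")]
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Build the cell-type reference profile matrix
#'
#' The reference matrix has one row per cell type and one column per
#' selected marker gene (union over types); entry (i, j) is the mean
#' linear-scale expression of marker gene j over all reference cells of
#' type i.
#'
#' @param sc an [sc_reference].
#' @param marker_table a `marker_table` from [select_markers].
#' @return list of class `reference_matrix` with `profiles` (k x g
#'   matrix), `cell_types`, `genes`.
#' @export
build_reference <- function(sc, marker_table) {
  genes <- sort(unique(marker_table$gene[marker_table$selected]))
  if (length(genes) == 0L) stop("build_reference: no selected markers")
  types <- levels(sc$cell_types)
  prof <- t(vapply(types, function(ty) {
    colMeans(sc$expr[sc$cell_types == ty, genes, drop = FALSE])
  }, numeric(length(genes))))
  rownames(prof) <- types
  colnames(prof) <- genes
  if (any(rowSums(prof) == 0)) {
    stop("build_reference: cell type with an all-zero marker profile: ",
         paste(types[rowSums(prof) == 0], collapse = ", "))
  }
  structure(list(profiles = prof, cell_types = types, genes = genes),
            class = "reference_matrix")
}
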