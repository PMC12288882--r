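#' Spatial transcriptomics dataset
#'
#' Bundles a spot-by-gene expression matrix with 2D spot coordinates. The
#' coordinate system is expected to be in array-grid units (integer
#' `array_row`/`array_col` for Visium data): spatial parameters elsewhere in
#' the package (DBSCAN `eps`, neighbor radius) are expressed in these units.
#'
#' @param expr numeric matrix, spots in rows, genes in columns. Row and
#'   column names are used as spot and gene identifiers; generated when
#'   absent.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y) in array-grid units.
#' @return An object of class `st_dataset`: a list with elements `expr`
#'   (n x g matrix), `coords` (n x 2 matrix), `spot_ids`, `gene_ids`.
#' @export
st_dataset <- function(expr, coords) {
  expr <- as.matrix(expr)
  coords <- as.matrix(coords)
  if (nrow(expr) == 0L || ncol(expr) == 0L) {
    stop("st_dataset: empty expression matrix")
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("spot", seq_len(nrow(expr)))
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("gene", seq_len(ncol(expr)))
  }
  if (nrow(coords) != nrow(expr)) {
    stop("st_dataset: coords has ", nrow(coords), " rows but expr has ",
         nrow(expr))
  }
  if (ncol(coords) != 2L) stop("st_dataset: coords must have 2 columns")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(expr)
  if (anyDuplicated(rownames(expr))) stop("st_dataset: duplicate spot ids")
  if (anyDuplicated(colnames(expr))) stop("st_dataset: duplicate gene ids")
  if (min(expr) < 0) stop("st_dataset: negative expression values")
  structure(
    list(expr = expr, coords = coords,
         spot_ids = rownames(expr), gene_ids = colnames(expr)),
    class = "st_dataset"
  )
}

#' @export
print.st_dataset <- function(x, ...) {
  cat("st_dataset:", length(x$spot_ids), "spots x",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Annotated single-cell reference
#'
#' @param expr numeric matrix, cells in rows, genes in columns.
#' @param cell_types character or factor vector, one label per cell.
#' @return An object of class `sc_reference`: list with `expr`,
#'   `cell_types` (factor), `cell_ids`, `gene_ids`.
#' @export
sc_reference <- function(expr, cell_types) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) == 0L) {
    stop("sc_reference: empty expression matrix")
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("cell", seq_len(nrow(expr)))
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("gene", seq_len(ncol(expr)))
  }
  if (length(cell_types) != nrow(expr)) {
    stop("sc_reference: one cell-type label per cell required")
  }
  cell_types <- factor(as.character(cell_types))
  if (anyNA(cell_types)) stop("sc_reference: NA cell-type labels")
  if (nlevels(cell_types) < 2L) {
    warning("sc_reference: fewer than 2 distinct cell types")
  }
  if (anyDuplicated(rownames(expr))) stop("sc_reference: duplicate cell ids")
  if (anyDuplicated(colnames(expr))) stop("sc_reference: duplicate gene ids")
  if (min(expr) < 0) stop("sc_reference: negative expression values")
  structure(
    list(expr = expr, cell_types = cell_types,
         cell_ids = rownames(expr), gene_ids = colnames(expr)),
    class = "sc_reference"
  )
}

#' @export
print.sc_reference <- function(x, ...) {
  cat("sc_reference:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes,", nlevels(x$cell_types), "cell types\n")
  invisible(x)
}

# Reads a dense CSV/TSV matrix (first column = row ids) or a matrix-market
# triplet with companion features/barcodes files next to it.
read_expr_matrix <- function(expr_path) {
  if (grepl("\\.mtx$", expr_path)) {
    m <- Matrix::readMM(expr_path)
    dir <- dirname(expr_path)
    feat_path <- file.path(dir, "features.tsv")
    if (!file.exists(feat_path)) feat_path <- file.path(dir, "genes.tsv")
    bc_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat_path) || !file.exists(bc_path)) {
      stop("matrix-market input requires features.tsv/genes.tsv and ",
           "barcodes.tsv beside ", expr_path)
    }
    feats <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    bcs <- utils::read.table(bc_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    # 10x convention: genes in rows, barcodes in columns
    m <- as.matrix(m)
    rownames(m) <- feats[[1]]
    colnames(m) <- bcs[[1]]
    t(m)
  } else {
    sep <- if (grepl("\\.tsv$", expr_path)) "\t" else ","
    df <- utils::read.table(expr_path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    as.matrix(df)
  }
}

# Visium tissue-positions table (headered or 6-column legacy) or a plain
# 3-column id,x,y table. Returns data.frame(id, x, y, in_tissue).
read_coords_table <- function(coords_path) {
  first <- readLines(coords_path, n = 1L)
  has_header <- grepl("barcode|in_tissue|array_row", first)
  df <- utils::read.csv(coords_path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) >= 6L) {
    if (!has_header) {
      names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                          "pxl_row", "pxl_col")
    }
    data.frame(id = as.character(df$barcode),
               x = as.numeric(df$array_row),
               y = as.numeric(df$array_col),
               in_tissue = as.integer(df$in_tissue),
               stringsAsFactors = FALSE)
  } else if (ncol(df) == 3L) {
    data.frame(id = as.character(df[[1]]), x = as.numeric(df[[2]]),
               y = as.numeric(df[[3]]), in_tissue = 1L,
               stringsAsFactors = FALSE)
  } else {
    stop("unrecognized coordinates table: expected Visium tissue-positions ",
         "(6+ columns) or id,x,y (3 columns), got ", ncol(df), " columns")
  }
}

#' Read a spatial transcriptomics dataset
#'
#' Reads expression (dense CSV/TSV with row ids, or matrix-market `.mtx`
#' with companion `features.tsv`/`barcodes.tsv`) and spot coordinates
#' (Visium tissue-positions table or plain `id,x,y` CSV). When the
#' positions table has an `in_tissue` flag, only in-tissue spots are
#' retained; `array_row`/`array_col` are used as the coordinate system.
#'
#' @param expr_path path to the expression matrix.
#' @param coords_path path to the coordinates table.
#' @return An [st_dataset].
#' @export
read_st <- function(expr_path, coords_path) {
  expr <- read_expr_matrix(expr_path)
  co <- read_coords_table(coords_path)
  missing <- setdiff(rownames(expr), co$id)
  if (length(missing) > 0) {
    stop("spots in expression without coordinates: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  # spots flagged out-of-tissue are dropped from the expression too
  co <- co[co$in_tissue == 1L, , drop = FALSE]
  expr <- expr[rownames(expr) %in% co$id, , drop = FALSE]
  if (nrow(expr) == 0L) stop("no in-tissue spots remain")
  co <- co[match(rownames(expr), co$id), , drop = FALSE]
  st_dataset(expr, cbind(co$x, co$y))
}

#' Write a spatial dataset to CSV files
#'
#' @param st an [st_dataset].
#' @param expr_path,coords_path output CSV paths.
#' @export
write_st <- function(st, expr_path, coords_path) {
  utils::write.csv(as.data.frame(st$expr), expr_path)
  utils::write.csv(data.frame(barcode = st$spot_ids,
                              x = st$coords[, 1], y = st$coords[, 2]),
                   coords_path, row.names = FALSE)
  invisible(st)
}

#' Read an annotated scRNA-seq reference
#'
#' @param expr_path expression matrix (cells x genes; dense CSV/TSV or
#'   matrix-market as in [read_st]).
#' @param labels_path CSV mapping cell id to cell-type label (two columns,
#'   with or without header). Cells without a label are dropped with a
#'   warning.
#' @return An [sc_reference].
#' @export
read_sc <- function(expr_path, labels_path) {
  expr <- read_expr_matrix(expr_path)
  first <- readLines(labels_path, n = 1L)
  has_header <- grepl("cell|barcode|type|label", first, ignore.case = TRUE)
  lab <- utils::read.csv(labels_path, header = has_header,
                         stringsAsFactors = FALSE)
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  got <- labels[rownames(expr)]
  unlabeled <- is.na(got) | got == ""
  if (all(unlabeled)) stop("read_sc: no labeled cells")
  if (any(unlabeled)) {
    warning("read_sc: dropping ", sum(unlabeled), " unlabeled cells")
    expr <- expr[!unlabeled, , drop = FALSE]
    got <- got[!unlabeled]
  }
  sc_reference(expr, got)
}

#' Write a single-cell reference to CSV files
#'
#' @param sc an [sc_reference].
#' @param expr_path,labels_path output CSV paths.
#' @export
write_sc <- function(sc, expr_path, labels_path) {
  utils::write.csv(as.data.frame(sc$expr), expr_path)
  utils::write.csv(data.frame(cell_id = sc$cell_ids,
                              cell_type = as.character(sc$cell_types)),
                   labels_path, row.names = FALSE)
  invisible(sc)
}

#' Library-size normalization
#'
#' Scales every row (spot or cell) to a common library size, then applies
#' `log1p`. Zero-sum rows are left all-zero with a warning. `method =
#' "none"` returns the input unchanged.
#'
#' @param expr nonnegative matrix, observations in rows.
#' @param method `"cpm_log1p"` (default) or `"none"`.
#' @param target_sum common library size after scaling (default 1e4).
#' @return matrix of the same shape.
#' @export
normalize_counts <- function(expr, method = c("cpm_log1p", "none"),
                             target_sum = 1e4) {
  method <- match.arg(method)
  if (method == "none") return(expr)
  rs <- rowSums(expr)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " zero-sum rows left all-zero")
    rs[zero] <- 1
  }
  log1p(expr * (target_sum / rs))
}

#' Select the most variable genes
#'
#' Ranks genes by the variance of their log1p library-size-normalized
#' expression and returns the top `top_n` gene ids (all genes when fewer
#' are present). Deterministic: ties are broken by gene id.
#'
#' @param x an [st_dataset] or [sc_reference] (or a bare matrix with
#'   observations in rows).
#' @param top_n number of genes to keep (default 5000).
#' @param on `"lognorm"` (default) computes variance on log1p-normalized
#'   values; `"raw"` on the input scale.
#' @return character vector of gene ids, highest variance first.
#' @export
select_variable_genes <- function(x, top_n = 5000, on = c("lognorm", "raw")) {
  on <- match.arg(on)
  expr <- if (is.matrix(x)) x else x$expr
  if (ncol(expr) < 1L) stop("no genes")
  m <- if (on == "lognorm") {
    suppressWarnings(normalize_counts(expr))
  } else expr
  v <- apply(m, 2, stats::var)
  ord <- order(-v, colnames(expr))
  colnames(expr)[ord][seq_len(min(top_n, ncol(expr)))]
}

#' Intersect gene sets from the ST and reference data
#'
#' Returns the shared gene space in a stable (lexicographic) order with
#' index maps into each input ordering, so all downstream matrices are
#' reproducible across input file orderings.
#'
#' @param st_genes,sc_genes character vectors of gene ids.
#' @return list with `genes` (sorted shared ids), `st_index`, `sc_index`.
#' @export
intersect_genes <- function(st_genes, sc_genes) {
  if (length(st_genes) == 0L || length(sc_genes) == 0L) {
    stop("intersect_genes: empty input gene list")
  }
  genes <- sort(intersect(st_genes, sc_genes))
  if (length(genes) == 0L) {
    stop("intersect_genes: no shared genes between ST and reference")
  }
  structure(
    list(genes = genes,
         st_index = match(genes, st_genes),
         sc_index = match(genes, sc_genes)),
    class = "shared_gene_space"
  )
}
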