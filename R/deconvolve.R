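#' Cluster-level cell-type proportions by constrained OLS
#'
#' For each pseudo-bulk profile x (a row of `X_star`), solves the
#' unconstrained least-squares system x ~ t(Z_hat) %*% y, clips negative
#' coefficients to zero, and renormalizes the row to sum 1. This literal
#' clip-and-renormalize estimator is the default; `method = "nnls"` swaps
#' in a true non-negative least-squares solve (Lawson-Hanson via
#' `pracma::lsqnonneg`) for comparison.
#'
#' The OLS solve uses a QR decomposition rather than the explicit normal
#' equations; the two agree to ~1e-10 on well-conditioned inputs.
#'
#' @param X_star h x g pseudo-bulk matrix, columns aligned to the columns
#'   of `Z_hat` (same gene order).
#' @param Z_hat k x g cell-type reference profile matrix (a
#'   `reference_matrix$profiles` or any numeric matrix).
#' @param method `"clipped_ols"` (default) or `"nnls"`.
#' @return matrix of class `proportion_matrix` (h x k): rows sum to 1,
#'   entries in [0, 1]. Rows named by `X_star` rows, columns by cell type.
#' @export
ols_deconvolve <- function(X_star, Z_hat,
                           method = c("clipped_ols", "nnls")) {
  method <- match.arg(method)
  if (inherits(Z_hat, "reference_matrix")) Z_hat <- Z_hat$profiles
  X_star <- as.matrix(X_star)
  if (is.null(dim(X_star))) X_star <- matrix(X_star, nrow = 1)
  if (ncol(X_star) != ncol(Z_hat)) {
    stop("ols_deconvolve: X_star has ", ncol(X_star),
         " genes but Z_hat has ", ncol(Z_hat))
  }
  k <- nrow(Z_hat)
  design <- t(Z_hat)  # g x k
  if (k > 1L) {
    qr_d <- qr(design)
    if (qr_d$rank < k) {
      cc <- stats::cor(design)
      bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
      pairs <- apply(bad, 1, function(ij) {
        paste(rownames(cc)[ij[1]], colnames(cc)[ij[2]], sep = " ~ ")
      })
      stop("ols_deconvolve: reference matrix is rank deficient",
           if (length(pairs) > 0) {
             paste0("; collinear cell types: ",
                    paste(pairs, collapse = ", "))
           } else "")
    }
  }
  Y <- matrix(NA_real_, nrow(X_star), k,
              dimnames = list(rownames(X_star), rownames(Z_hat)))
  for (i in seq_len(nrow(X_star))) {
    x <- X_star[i, ]
    y <- if (method == "clipped_ols") {
      pmax(qr.coef(qr(design), x), 0)
    } else {
      pracma::lsqnonneg(design, x)$x
    }
    s <- sum(y)
    if (s <= 0) {
      warning("cluster ", rownames(X_star)[i] %||% i,
              ": all coefficients clipped to zero; uniform proportions")
      y <- rep(1 / k, k)
    } else {
      y <- y / s
    }
    Y[i, ] <- y
  }
  class(Y) <- c("proportion_matrix", class(Y))
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand cluster-level proportions to spot level
#'
#' Each spot inherits the proportion row of its cluster.
#'
#' @param cluster_props h x k `proportion_matrix` with rownames = cluster
#'   ids.
#' @param final_labels per-spot cluster label.
#' @param spot_ids optional row names for the output.
#' @return n x k `proportion_matrix`.
#' @export
expand_to_spots <- function(cluster_props, final_labels, spot_ids = NULL) {
  idx <- match(as.character(final_labels), rownames(cluster_props))
  if (anyNA(idx)) {
    stop("expand_to_spots: spots with labels absent from cluster rows: ",
         paste(utils::head(unique(final_labels[is.na(idx)]), 10),
               collapse = ", "))
  }
  out <- cluster_props[idx, , drop = FALSE]
  rownames(out) <- spot_ids %||% paste0("spot", seq_along(final_labels))
  class(out) <- c("proportion_matrix", "matrix", "array")
  out
}
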