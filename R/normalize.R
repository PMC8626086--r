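#' Log counts-per-10k normalization
#'
#' `value = ln(1 + 10000 * count / cell_total)`. Cells with zero total are
#' passed through as zeros. Sparsity is preserved (zero counts map to zero).
#' This is the explicit, testable surrogate used throughout the package in
#' place of a regularized negative-binomial variance stabilization.
#'
#' @param m a [count_matrix()] or a sparse/dense genes-x-cells count matrix.
#' @return a `dgCMatrix` of normalized values, genes x cells.
#' @export
normalize_log_cp10k <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  total <- Matrix::colSums(counts)
  scale <- ifelse(total > 0, 1e4 / total, 0)
  norm <- counts %*% Matrix::Diagonal(x = scale)
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

# per-gene mean and variance of a sparse genes x cells matrix
sparse_row_stats <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowSums(x) / n
  ex2 <- Matrix::rowSums(x^2) / n
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  list(mean = as.numeric(mu), var = pmax(0, as.numeric(v)))
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized expression across
#' cells. On log-scale values the mean-variance trend is already strongly
#' compressed, and genes whose expression differs between cell populations
#' (bimodal on the log scale) rise to the top; a constant gene has variance
#' zero and can never outrank a varying one. Ties are broken by gene
#' identifier, lexicographically, so the selection is fully deterministic.
#'
#' @param norm normalized genes-x-cells matrix (see [normalize_log_cp10k()]).
#' @param n_hvg number of genes to keep (capped at the number of genes).
#' @return character vector of selected gene ids, in rank order.
#' @export
select_hvg <- function(norm, n_hvg) {
  st <- sparse_row_stats(norm)
  genes <- rownames(norm)
  ord <- order(-st$var, genes)
  genes[ord][seq_len(min(n_hvg, length(genes)))]
}

#' Principal-component embedding of cells
#'
#' Genes are z-scored across cells (zero-variance genes contribute zeros),
#' clipped at +/-10, and the cells-x-genes matrix is decomposed by SVD. A
#' deterministic sign convention is applied per component: the gene loading
#' with the largest magnitude is made positive.
#'
#' @param norm normalized genes-x-cells matrix.
#' @param genes gene ids to use (e.g. from [select_hvg()]).
#' @param n_pcs number of components; must not exceed
#'   `min(length(genes), n_cells - 1)`.
#' @return a cells x `n_pcs` matrix of class `embedding` with attributes
#'   `explained_variance` (non-increasing) and `source = "pca_single"`.
#' @export
run_pca <- function(norm, genes, n_pcs) {
  genes <- intersect(genes, rownames(norm))
  if (!length(genes)) stop("no requested genes present in the matrix")
  x <- as.matrix(Matrix::t(norm[genes, , drop = FALSE]))  # cells x genes
  if (n_pcs > min(ncol(x), nrow(x) - 1))
    stop("n_pcs exceeds the rank bound min(n_genes, n_cells - 1)")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  x <- sweep(x, 2, mu)
  nz <- s > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, s[nz], "/")
  x[, !nz] <- 0
  x[x > 10] <- 10; x[x < -10] <- -10
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)] * flip, n_pcs)
  dimnames(coords) <- list(colnames(norm), paste0("PC", seq_len(n_pcs)))
  structure(coords,
            explained_variance = sv$d[seq_len(n_pcs)]^2 / max(1, nrow(x) - 1),
            source = "pca_single", class = c("embedding", "matrix", "array"))
}
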