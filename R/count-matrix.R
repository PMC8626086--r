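#' Gene-by-cell UMI count matrix
#'
#' The basic container for single-nucleus expression data: a sparse
#' nonnegative-integer matrix of UMI counts (genes in rows, cells in columns)
#' with unique gene and cell identifiers, a species tag and a logical
#' mitochondrial-gene mask. Mitochondrial genes are identified by default from
#' the conventional "MT-"/"mt-" name prefix (case-insensitive); an explicit
#' mask overrides this.
#'
#' @param counts a matrix or [Matrix::sparseMatrix()] of nonnegative integer
#'   counts, genes x cells. Row and column names are used as gene/cell ids
#'   unless `gene_ids`/`cell_ids` are given.
#' @param species one of `"human"`, `"mouse"`, `"synthetic"`.
#' @param gene_ids,cell_ids optional character vectors of unique identifiers.
#' @param mito_mask optional logical vector over genes; `NULL` derives it from
#'   the `MT-` prefix.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `species` and `mito_mask`.
#' @examples
#' m <- count_matrix(matrix(c(1, 0, 2, 3), 2, 2,
#'   dimnames = list(c("SCN10A", "MT-ND1"), c("c1", "c2"))), "human")
#' m$mito_mask
#' @export
count_matrix <- function(counts, species = c("synthetic", "human", "mouse"),
                         gene_ids = NULL, cell_ids = NULL, mito_mask = NULL) {
  species <- match.arg(species)
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn)) dimnames(counts) <- dn
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(cell_ids)) colnames(counts) <- cell_ids
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("gene and cell identifiers are required")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("gene and cell identifiers are required")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell_ids")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be nonnegative integers")
  if (is.null(mito_mask))
    mito_mask <- grepl("^mt-", rownames(counts), ignore.case = TRUE)
  if (length(mito_mask) != nrow(counts))
    stop("mito_mask length must equal the number of genes")
  structure(list(counts = counts, species = species,
                 mito_mask = as.logical(mito_mask)),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%s), %d mitochondrial genes\n",
              nrow(x$counts), ncol(x$counts), x$species, sum(x$mito_mask)))
  invisible(x)
}

#' Subset a count matrix by cells (and optionally genes)
#' @param m a `count_matrix`.
#' @param cells,genes logical/integer/character indices; `NULL` keeps all.
#' @return a `count_matrix`.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  mask <- m$mito_mask
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, rownames(counts))
    counts <- counts[genes, , drop = FALSE]
    mask <- mask[genes]
  }
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  count_matrix(counts, species = m$species, mito_mask = mask)
}

#' Write a CellRanger-style Matrix-Market bundle
#'
#' Writes `matrix.mtx`, `features.tsv` (gene_id, gene_name, feature_type) and
#' `barcodes.tsv` into `dir`, uncompressed.
#'
#' @param m a `count_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_bundle <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  write.table(
    data.frame(rownames(m$counts), rownames(m$counts), "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(colnames(m$counts), file.path(dir, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a CellRanger-style Matrix-Market bundle
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param species species tag for the resulting matrix.
#' @param mito_mask optional explicit mitochondrial mask.
#' @return a `count_matrix`.
#' @export
read_count_bundle <- function(dir, species = "synthetic", mito_mask = NULL) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))
  counts <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  feats <- read.delim(paths[2], header = FALSE, stringsAsFactors = FALSE)
  bars <- read.delim(paths[3], header = FALSE, stringsAsFactors = FALSE)[[1]]
  rownames(counts) <- feats[[1]]
  colnames(counts) <- bars
  count_matrix(counts, species = species, mito_mask = mito_mask)
}
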