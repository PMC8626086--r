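#' Cross-species integration configuration
#'
#' @param n_pcs_joint dimensions of the joint embedding (default 30, the space
#'   in which cluster divergences are estimated).
#' @param resolution_joint modularity resolution for joint clustering.
#' @param dims_hint recorded for provenance only (the anchor-based analysis
#'   this workflow simplifies used 15 integration dims); unused here.
#' @param seed integer seed.
#' @export
integration_config <- function(n_pcs_joint = 30, resolution_joint = 0.5,
                               dims_hint = 15L, seed = 1L) {
  stopifnot(n_pcs_joint >= 2, resolution_joint > 0)
  structure(list(n_pcs_joint = as.integer(n_pcs_joint),
                 resolution_joint = resolution_joint,
                 dims_hint = as.integer(dims_hint), seed = as.integer(seed)),
            class = "integration_config")
}

#' Harmonize gene names across species by case-insensitive matching
#'
#' Gene names in both matrices are uppercased; when two distinct rows of one
#' matrix collide onto the same uppercase name the row with the higher total
#' count is kept (with a warning). Both matrices are then restricted to the
#' shared uppercase gene set, rows in identical order.
#'
#' @param a,b [count_matrix()] objects.
#' @return list with harmonized `a` and `b` (identical gene vectors).
#' @examples
#' \dontrun{harmonize_genes(human, mouse)}
#' @export
harmonize_genes <- function(a, b) {
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  upper_dedup <- function(m) {
    up <- toupper(rownames(m$counts))
    if (anyDuplicated(up)) {
      tot <- Matrix::rowSums(m$counts)
      # keep the highest-total row per uppercase name (ties: first row)
      ord <- order(up, -tot)
      keep <- ord[!duplicated(up[ord])]
      keep <- sort(keep)
      warning("gene-name case collisions resolved by total count: ",
              paste(unique(up[duplicated(up)]), collapse = ", "))
      m <- subset_cells(m, genes = keep)
      up <- toupper(rownames(m$counts))
    }
    rownames(m$counts) <- up
    m
  }
  a <- upper_dedup(a); b <- upper_dedup(b)
  shared <- intersect(rownames(a$counts), rownames(b$counts))
  if (!length(shared)) stop("no shared genes after case harmonization")
  list(a = subset_cells(a, genes = match(shared, rownames(a$counts))),
       b = subset_cells(b, genes = match(shared, rownames(b$counts))))
}

#' Joint embedding of two harmonized datasets
#'
#' Each dataset is log-CP10K normalized and per-gene z-scored *within
#' dataset*, removing dataset-specific location and scale (a deliberately
#' simple stand-in for anchor-based integration: the quantity consumed
#' downstream is just a common PC space, and an externally computed embedding
#' can be supplied to the divergence module instead). The standardized blocks
#' are concatenated and decomposed by a joint PCA to `n_pcs_joint`.
#'
#' @param a,b harmonized [count_matrix()] objects (identical gene rows, at
#'   least 2 cells each).
#' @param config an [integration_config()].
#' @param labels_a,labels_b optional per-cell original cluster labels, carried
#'   through as metadata.
#' @return list of class `co_embedding`: `coords` (cells x n_pcs_joint),
#'   `species` (`"a"`/`"b"` origin), `cell_id`, `orig_label`.
#' @export
co_embed <- function(a, b, config = integration_config(),
                     labels_a = NULL, labels_b = NULL) {
  stopifnot(inherits(config, "integration_config"))
  if (!identical(rownames(a$counts), rownames(b$counts)))
    stop("gene rows differ; run harmonize_genes() first")
  if (ncol(a$counts) < 2 || ncol(b$counts) < 2)
    stop("each dataset needs at least 2 cells (within-dataset z-scoring)")
  zblock <- function(m) {
    x <- as.matrix(Matrix::t(normalize_log_cp10k(m)))  # cells x genes
    mu <- colMeans(x)
    s <- apply(x, 2, sd)
    x <- sweep(x, 2, mu)
    nz <- s > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, s[nz], "/")
    x[, !nz] <- 0
    x[x > 10] <- 10; x[x < -10] <- -10
    x
  }
  xa <- zblock(a); xb <- zblock(b)
  x <- rbind(xa, xb)
  x <- sweep(x, 2, colMeans(x))
  k <- min(config$n_pcs_joint, ncol(x), nrow(x) - 1)
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  }, numeric(1))
  coords <- sv$u %*% diag(sv$d[seq_len(k)] * flip, k)
  cell_id <- c(colnames(a$counts), colnames(b$counts))
  dimnames(coords) <- list(cell_id, paste0("PC", seq_len(k)))
  structure(list(
    coords = coords,
    species = rep(c("a", "b"), c(nrow(xa), nrow(xb))),
    cell_id = cell_id,
    orig_label = c(if (is.null(labels_a)) rep(NA_character_, nrow(xa)) else
                     as.character(labels_a),
                   if (is.null(labels_b)) rep(NA_character_, nrow(xb)) else
                     as.character(labels_b))),
    class = "co_embedding")
}

#' Cross-tabulate joint clusters against original labels
#'
#' @param joint_labels factor/character of joint cluster per cell.
#' @param orig_labels original (single-species) label per cell.
#' @return list with `counts` (joint x original contingency table) and `prop`
#'   (row-normalized proportions).
#' @export
joint_cluster_crosstab <- function(joint_labels, orig_labels) {
  if (length(joint_labels) != length(orig_labels))
    stop("label vectors must have equal length")
  counts <- table(joint = joint_labels, original = orig_labels)
  prop <- sweep(counts, 1, pmax(1, rowSums(counts)), "/")
  list(counts = counts, prop = prop)
}

#' Read / write an embedding CSV interchangeable with external tools
#'
#' Column layout: `cell_id, species, orig_label, PC1..PCk`. This is the
#' interchange point for users who compute the joint space elsewhere (e.g. an
#' anchor-integrated PCA) and only want the divergence analysis.
#'
#' @param emb a `co_embedding`.
#' @param path CSV path.
#' @return for the writer, `path` invisibly; for the reader, a `co_embedding`.
#' @export
write_embedding_csv <- function(emb, path) {
  stopifnot(inherits(emb, "co_embedding"))
  df <- data.frame(cell_id = emb$cell_id, species = emb$species,
                   orig_label = emb$orig_label, emb$coords,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pc_cols <- grep("^PC[0-9]+$", colnames(df))
  coords <- as.matrix(df[, pc_cols, drop = FALSE])
  rownames(coords) <- df$cell_id
  structure(list(coords = coords, species = as.character(df$species),
                 cell_id = df$cell_id,
                 orig_label = as.character(df$orig_label)),
            class = "co_embedding")
}
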