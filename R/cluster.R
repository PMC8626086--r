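#' Clustering configuration
#'
#' Defaults mirror the human single-species analysis settings: 16 PCs and a
#' low-stringency modularity resolution of 2.0 (the mouse reference analysis
#' used 20 PCs at resolution 3.5).
#'
#' @param n_hvg highly variable genes for PCA.
#' @param n_pcs PCs used for the k-NN graph.
#' @param resolution modularity resolution.
#' @param knn_k nearest neighbors for the SNN graph.
#' @param seed integer seed for community detection.
#' @export
cluster_config <- function(n_hvg = 2000, n_pcs = 16, resolution = 2.0,
                           knn_k = 20, seed = 1L) {
  stopifnot(n_hvg >= 1, n_pcs >= 1, resolution > 0, knn_k >= 1)
  structure(list(n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
                 resolution = resolution, knn_k = as.integer(knn_k),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Build a shared-nearest-neighbor graph and detect communities
#'
#' Builds the k-NN graph in PC space (Euclidean; self excluded; distance ties
#' broken by cell index), symmetrizes it to a shared-nearest-neighbor graph
#' weighted by the Jaccard overlap of neighbor lists (each list includes the
#' cell itself; edges with overlap below 1/15 are pruned, keeping at least the
#' mutual k-NN backbone connected through positive weights), and optimizes
#' modularity with the Leiden algorithm at the given resolution.
#'
#' @param embedding a cells x dims matrix (e.g. from [run_pca()]).
#' @param knn_k neighbors per cell; must be `< n_cells`.
#' @param resolution modularity resolution parameter.
#' @param seed integer seed (community detection is stochastic).
#' @return factor of cluster labels (`"C1"`, `"C2"`, ... by decreasing size),
#'   named by cell id, with attribute `stage = "raw"`.
#' @export
cluster_graph <- function(embedding, knn_k = 20, resolution = 2.0, seed = 1L) {
  n <- nrow(embedding)
  if (knn_k < 1) stop("knn_k must be >= 1")
  if (n <= knn_k) stop("need more cells than knn_k")
  nn <- knn_lookup(embedding, embedding, knn_k, exclude_self = TRUE)$index
  # neighbor lists including self, as a sparse indicator for fast overlap
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), knn_k + 1L), j = c(seq_len(n), as.vector(nn)),
    x = 1, dims = c(n, n))
  ov <- Matrix::tcrossprod(adj)             # shared-neighbor counts
  ov <- methods::as(ov, "CsparseMatrix")
  jac <- ov
  jac@x <- ov@x / (2 * (knn_k + 1L) - ov@x)  # Jaccard of the two lists
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5)))
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(paste0("C", seq_along(sizes)), names(sizes))
  out <- factor(relabel[as.character(memb)],
                levels = paste0("C", seq_along(sizes)))
  names(out) <- rownames(embedding)
  attr(out, "stage") <- "raw"
  out
}

#' Merge closely related clusters lacking distinguishing markers
#'
#' Iteratively considers mutually nearest cluster pairs (centroid Euclidean
#' distance in PC space, nearest pairs first) and merges a pair when a marker
#' scan in both directions ([find_markers()] with `min_pct = 0.25`,
#' `min_diff_pct = 0.25`) yields no gene at adjusted p < `alpha`. Repeats
#' until no mutually nearest pair is mergeable. The merged cluster keeps the
#' first cluster's label; cluster count never increases.
#'
#' @param norm normalized genes-x-cells matrix.
#' @param embedding cells x dims PC matrix (same cells as `norm` columns).
#' @param partition factor of cluster labels named by cell id.
#' @param min_pct,min_diff_pct,alpha merge criterion parameters.
#' @return merged factor partition with attribute `stage = "merged"`.
#' @export
merge_indistinct_clusters <- function(norm, embedding, partition,
                                      min_pct = 0.25, min_diff_pct = 0.25,
                                      alpha = 0.05) {
  labels <- as.character(partition)
  names(labels) <- names(partition)
  distinct <- character(0)  # cache of pairs already found separable
  repeat {
    cl <- sort(unique(labels))
    if (length(cl) < 2) break
    cent <- t(vapply(cl, function(g)
      colMeans(embedding[labels == g, , drop = FALSE]),
      numeric(ncol(embedding))))
    d <- as.matrix(dist(cent)); diag(d) <- Inf
    nearest <- cl[apply(d, 1, which.min)]
    mutual <- which(nearest[match(nearest, cl)] == cl & cl < nearest)
    if (!length(mutual)) break
    pairs <- data.frame(a = cl[mutual], b = nearest[mutual],
                        d = d[cbind(mutual, match(nearest[mutual], cl))])
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    merged <- FALSE
    for (r in seq_len(nrow(pairs))) {
      key <- paste(pairs$a[r], pairs$b[r], sep = "|")
      if (key %in% distinct) next
      part <- factor(labels)
      m1 <- find_markers(norm, part, pairs$a[r], pairs$b[r],
                         min_pct = min_pct, min_diff_pct = min_diff_pct)
      m2 <- find_markers(norm, part, pairs$b[r], pairs$a[r],
                         min_pct = min_pct, min_diff_pct = min_diff_pct)
      n_sig <- sum(m1$adjusted_p < alpha) + sum(m2$adjusted_p < alpha)
      if (n_sig == 0) {
        labels[labels == pairs$b[r]] <- pairs$a[r]
        merged <- TRUE
        break
      } else distinct <- c(distinct, key)
    }
    if (!merged) break
  }
  out <- factor(labels)
  names(out) <- names(partition)
  attr(out, "stage") <- "merged"
  out
}

#' Default neuronal / non-neuronal triage panels
#'
#' Somatosensory-neuron genes versus glial/non-neuronal markers. The
#' non-neuronal panel uses `PLP1` (proteolipid protein 1, the canonical
#' oligodendrocyte/Schwann-cell marker); both panels are configurable.
#' @name triage_panels
#' @export
neuronal_panel_default <- c("SNAP25", "SCN9A", "SCN10A", "PIEZO2", "NEFH")

#' @rdname triage_panels
#' @export
nonneuronal_panel_default <- c("PLP1", "MBP", "QKI", "LPAR1", "APOE")

#' Tag and remove non-neuronal clusters
#'
#' For each cluster, the neuronal score is the mean normalized expression over
#' the neuronal panel and likewise for the non-neuronal panel; a cluster is
#' removed when its non-neuronal score strictly exceeds its neuronal score
#' (ties retain). Panel genes absent from the matrix are skipped with a
#' warning; it is an error for both panels to be entirely absent.
#'
#' @param norm normalized genes-x-cells matrix.
#' @param partition factor of cluster labels named by cell id.
#' @param m the [count_matrix()] the normalization came from (subset returned).
#' @param neuronal_genes,nonneuronal_genes marker panels.
#' @return list with `calls` (data.frame: cluster, neuronal_score,
#'   nonneuronal_score, neuronal), `counts` (the retained-cell
#'   [count_matrix()]) and `retained_cells` (character).
#' @export
triage_neuronal <- function(norm, partition, m,
                            neuronal_genes = neuronal_panel_default,
                            nonneuronal_genes = nonneuronal_panel_default) {
  stopifnot(inherits(m, "count_matrix"))
  have_n <- intersect(neuronal_genes, rownames(norm))
  have_nn <- intersect(nonneuronal_genes, rownames(norm))
  if (!length(have_n) && !length(have_nn))
    stop("neither triage panel has any gene present in the matrix")
  missing <- setdiff(c(neuronal_genes, nonneuronal_genes), rownames(norm))
  if (length(missing))
    warning("triage panel genes absent and skipped: ",
            paste(missing, collapse = ", "))
  cl <- levels(droplevels(partition))
  score <- function(genes, cells) {
    if (!length(genes)) return(0)
    mean(Matrix::rowMeans(norm[genes, cells, drop = FALSE]))
  }
  calls <- do.call(rbind, lapply(cl, function(g) {
    cells <- names(partition)[partition == g]
    data.frame(cluster = g,
               neuronal_score = score(have_n, cells),
               nonneuronal_score = score(have_nn, cells),
               stringsAsFactors = FALSE)
  }))
  calls$neuronal <- calls$nonneuronal_score <= calls$neuronal_score
  keep_cl <- calls$cluster[calls$neuronal]
  cells <- names(partition)[as.character(partition) %in% keep_cl]
  list(calls = calls,
       counts = subset_cells(m, cells = match(cells, colnames(m$counts))),
       retained_cells = cells)
}
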