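#' Differential markers of a cluster by Wilcoxon rank-sum
#'
#' Candidate genes must be detected (value > 0) in at least `min_pct` of the
#' cells of the positive cluster and show a detection-rate difference
#' `pct_in - pct_out >= min_diff_pct`. Candidates are tested with a two-sided
#' Wilcoxon rank-sum on the normalized values ([rank_sum_test()]; exact
#' enumeration for tiny groups, tie-corrected normal approximation otherwise)
#' and Bonferroni-adjusted over the genes actually tested. The log fold change
#' is `ln((mean(expm1(in)) + 1e-9) / (mean(expm1(out)) + 1e-9))`.
#'
#' @param norm normalized genes-x-cells matrix ([normalize_log_cp10k()]).
#' @param partition factor of cluster labels named by cell id.
#' @param cluster_a positive cluster label.
#' @param cluster_b reference cluster label, or `NULL` for all other cells.
#' @param min_pct minimum detection fraction in the positive cluster.
#' @param min_diff_pct minimum detection-rate difference.
#' @return data.frame with columns `gene`, `cluster`, `log_fold_change`,
#'   `pct_in`, `pct_out`, `p_value`, `adjusted_p`, ordered by p-value.
#' @export
find_markers <- function(norm, partition, cluster_a, cluster_b = NULL,
                         min_pct = 0.1, min_diff_pct = 0) {
  cells <- names(partition)
  if (is.null(cells) || !all(cells %in% colnames(norm)))
    stop("partition must be named by cell ids present in the matrix")
  in_cells <- cells[partition == cluster_a]
  out_cells <- if (is.null(cluster_b)) cells[partition != cluster_a] else
    cells[partition == cluster_b]
  if (!length(in_cells)) stop("cluster_a is empty")
  if (!length(out_cells)) stop("reference group is empty")
  xin <- norm[, in_cells, drop = FALSE]
  xout <- norm[, out_cells, drop = FALSE]
  pct_in <- as.numeric(Matrix::rowSums(xin > 0)) / length(in_cells)
  pct_out <- as.numeric(Matrix::rowSums(xout > 0)) / length(out_cells)
  cand <- which(pct_in >= min_pct & (pct_in - pct_out) >= min_diff_pct)
  if (!length(cand))
    return(data.frame(gene = character(0), cluster = character(0),
                      log_fold_change = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0)))
  xin_d <- as.matrix(xin[cand, , drop = FALSE])
  xout_d <- as.matrix(xout[cand, , drop = FALSE])
  pv <- vapply(seq_along(cand), function(i)
    rank_sum_test(xin_d[i, ], xout_d[i, ], "two.sided")$p_value, numeric(1))
  lfc <- log((rowMeans(expm1(xin_d)) + 1e-9) /
             (rowMeans(expm1(xout_d)) + 1e-9))
  out <- data.frame(gene = rownames(norm)[cand],
                    cluster = as.character(cluster_a),
                    log_fold_change = lfc,
                    pct_in = pct_in[cand], pct_out = pct_out[cand],
                    p_value = pv,
                    adjusted_p = pmin(1, pv * length(cand)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Markers of every cluster against the rest
#'
#' @inheritParams find_markers
#' @return row-bound [find_markers()] tables over all clusters.
#' @export
find_all_markers <- function(norm, partition, min_pct = 0.1,
                             min_diff_pct = 0) {
  do.call(rbind, lapply(levels(droplevels(partition)), function(g)
    find_markers(norm, partition, g, NULL,
                 min_pct = min_pct, min_diff_pct = min_diff_pct)))
}
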