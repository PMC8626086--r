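#' Quality-control thresholds
#'
#' Boundary semantics: the detected-gene bounds are a closed interval
#' (`min_genes <= n <= max_genes` retained) while the mitochondrial bound is
#' strict (`mito_frac < max_mito_frac` retained). Presets encode the standard
#' inclusion rules for each species: human 500-10,000 genes and < 10%
#' mitochondrial; mouse 400-12,000 genes and < 1% mitochondrial.
#'
#' @param preset `"human"`, `"mouse"`, or `NULL` for explicit thresholds.
#' @param min_genes,max_genes,max_mito_frac explicit thresholds; override the
#'   preset when given.
#' @return list of class `qc_config`.
#' @examples
#' qc_config("human")
#' @export
qc_config <- function(preset = NULL, min_genes = NULL, max_genes = NULL,
                      max_mito_frac = NULL) {
  presets <- list(human = list(min_genes = 500L, max_genes = 10000L,
                               max_mito_frac = 0.10),
                  mouse = list(min_genes = 400L, max_genes = 12000L,
                               max_mito_frac = 0.01))
  base <- if (!is.null(preset)) presets[[match.arg(preset, names(presets))]]
          else list(min_genes = 500L, max_genes = 10000L, max_mito_frac = 0.10)
  cfg <- list(min_genes = as.integer(min_genes %||% base$min_genes),
              max_genes = as.integer(max_genes %||% base$max_genes),
              max_mito_frac = max_mito_frac %||% base$max_mito_frac)
  if (cfg$min_genes > cfg$max_genes) stop("min_genes must be <= max_genes")
  stopifnot(cfg$max_mito_frac >= 0, cfg$max_mito_frac <= 1)
  structure(cfg, class = "qc_config")
}

#' Per-nucleus quality metrics
#'
#' @param m a [count_matrix()].
#' @return data.frame with one row per cell: `cell_id`, `n_genes_detected`
#'   (genes with count > 0), `total_umi`, `mito_frac` (mitochondrial UMI over
#'   total UMI; 0 for empty cells).
#' @export
compute_qc_metrics <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  total <- Matrix::colSums(m$counts)
  detected <- Matrix::colSums(m$counts > 0)
  mito <- if (any(m$mito_mask))
    Matrix::colSums(m$counts[m$mito_mask, , drop = FALSE]) else
    rep(0, ncol(m$counts))
  frac <- ifelse(total > 0, mito / total, 0)
  data.frame(cell_id = colnames(m$counts),
             n_genes_detected = as.integer(detected),
             total_umi = as.numeric(total), mito_frac = as.numeric(frac),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter nuclei on detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with
#' `min_genes <= n_genes_detected <= max_genes` and
#' `mito_frac < max_mito_frac`; gene set and cell order are preserved.
#'
#' @param m a [count_matrix()].
#' @param metrics output of [compute_qc_metrics()] on `m` (computed if `NULL`).
#' @param config a [qc_config()].
#' @return the filtered [count_matrix()]; warns (does not fail) if no cell
#'   survives.
#' @export
filter_nuclei <- function(m, metrics = NULL, config = qc_config("human")) {
  stopifnot(inherits(m, "count_matrix"), inherits(config, "qc_config"))
  metrics <- metrics %||% compute_qc_metrics(m)
  keep <- metrics$n_genes_detected >= config$min_genes &
    metrics$n_genes_detected <= config$max_genes &
    metrics$mito_frac < config$max_mito_frac
  if (!any(keep)) warning("no cells pass the QC thresholds")
  subset_cells(m, cells = which(keep))
}

#' Doublet-scoring configuration
#' @param n_artificial number of artificial doublets to synthesize.
#' @param k_neighbors neighborhood size for the score.
#' @param n_pcs PCs for the co-embedding.
#' @param expected_rate fraction of real cells called doublets.
#' @param seed integer seed.
#' @export
doublet_config <- function(n_artificial = 500, k_neighbors = 30, n_pcs = 10,
                           expected_rate = 0.05, seed = 1L) {
  stopifnot(n_artificial >= 1, k_neighbors >= 1, n_pcs >= 1,
            expected_rate >= 0, expected_rate < 1)
  structure(list(n_artificial = as.integer(n_artificial),
                 k_neighbors = as.integer(k_neighbors),
                 n_pcs = as.integer(n_pcs), expected_rate = expected_rate,
                 seed = as.integer(seed)),
            class = "doublet_config")
}

#' Score cells for doublet likelihood by artificial-doublet proximity
#'
#' A simplified nearest-neighbor doublet scorer: artificial doublets are built
#' by summing the raw counts of random real cell pairs; real and artificial
#' profiles are co-embedded by shared log-CP10K normalization and PCA, and each
#' real cell's score is the fraction of artificial profiles among its
#' `k_neighbors` nearest neighbors (self excluded). The top `expected_rate`
#' fraction of cells by score is called. Scoring here is diagnostic: the
#' clustering workflow does not remove called doublets.
#'
#' @param m a [count_matrix()] with at least 2 cells.
#' @param config a [doublet_config()].
#' @return data.frame with `cell_id`, `doublet_score` in \[0, 1\] and logical
#'   `doublet_call`.
#' @export
doublet_score <- function(m, config = doublet_config()) {
  stopifnot(inherits(m, "count_matrix"), inherits(config, "doublet_config"))
  n <- ncol(m$counts)
  if (n < 2) stop("doublet scoring needs at least 2 cells")
  with_seed(config$seed, {
    p1 <- sample.int(n, config$n_artificial, replace = TRUE)
    p2 <- sample.int(n, config$n_artificial, replace = TRUE)
    art <- m$counts[, p1, drop = FALSE] + m$counts[, p2, drop = FALSE]
    colnames(art) <- sprintf("artificial%05d", seq_len(config$n_artificial))
    combined <- count_matrix(cbind(m$counts, art), species = m$species,
                             mito_mask = m$mito_mask)
    norm <- normalize_log_cp10k(combined)
    n_pcs <- min(config$n_pcs, nrow(norm) - 1L, ncol(norm) - 1L)
    emb <- run_pca(norm, rownames(norm), n_pcs)
    k <- min(config$k_neighbors, nrow(emb) - 1L)
    nn <- knn_lookup(emb, emb, k, exclude_self = TRUE)
    is_art <- c(rep(FALSE, n), rep(TRUE, config$n_artificial))
    score <- rowMeans(matrix(is_art[nn$index], nrow(emb), k))[seq_len(n)]
    call <- rep(FALSE, n)
    n_call <- floor(config$expected_rate * n)
    if (n_call > 0)
      call[order(score, decreasing = TRUE)[seq_len(n_call)]] <- TRUE
    data.frame(cell_id = colnames(m$counts), doublet_score = score,
               doublet_call = call, row.names = NULL, stringsAsFactors = FALSE)
  })
}
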