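# End-to-end orchestration: binds qc, clustering, marker finding, triage,
# cross-species embedding and divergence into reproducible runs with a
# manifest of output hashes.

write_manifest <- function(out_dir, config, stages) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- substring(files, nchar(out_dir) + 2)
  manifest <- list(package = "drgmap",
                   version = as.character(utils::packageVersion("drgmap")),
                   created = format(Sys.time(), tz = "UTC"),
                   config = config, stages = stages, file_md5 = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

run_stage <- function(name, expr, log_fn) {
  log_fn("stage ", name, " started")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Single-species analysis: QC, clustering, triage, merging, markers
#'
#' Runs the full single-dataset workflow: QC metrics and threshold filtering,
#' optional doublet scoring (diagnostic only; called doublets are not
#' removed), log-CP10K normalization, HVG selection, PCA, SNN graph
#' clustering, neuronal/non-neuronal triage (skipped when `neuronal_genes` is
#' `NULL`, e.g. for data without the panels), re-clustering of the retained
#' cells, merging of clusters without distinguishing markers, and
#' one-vs-rest marker tables. Artifacts (CSV) and a manifest with per-file
#' MD5 hashes are written to `out_dir` when given.
#'
#' @param input a [count_matrix()] or a path to a Matrix-Market bundle
#'   directory readable by [read_count_bundle()].
#' @param qc a [qc_config()].
#' @param clustering a [cluster_config()].
#' @param neuronal_genes,nonneuronal_genes triage panels; `NULL` skips triage.
#' @param doublets a [doublet_config()] or `NULL` to skip scoring.
#' @param marker_min_pct,marker_min_diff_pct filters for the final marker
#'   tables.
#' @param out_dir output directory (`NULL` returns results without writing).
#' @param verbose emit per-stage log lines.
#' @return list with `qc_metrics`, `partition` (factor, final stage),
#'   `embedding`, `markers`, `triage` (or `NULL`), `doublets` (or `NULL`),
#'   `counts` (the analyzed [count_matrix()]).
#' @export
run_single_species <- function(input, qc = qc_config("human"),
                               clustering = cluster_config(),
                               neuronal_genes = NULL,
                               nonneuronal_genes = nonneuronal_panel_default,
                               doublets = NULL,
                               marker_min_pct = 0.1, marker_min_diff_pct = 0,
                               out_dir = NULL, verbose = FALSE) {
  log_fn <- function(...) if (verbose) message("[drgmap] ", ...)
  m <- if (inherits(input, "count_matrix")) input else
    run_stage("read_input", read_count_bundle(input), log_fn)

  metrics <- run_stage("qc_metrics", compute_qc_metrics(m), log_fn)
  mf <- run_stage("qc_filter", filter_nuclei(m, metrics, qc), log_fn)
  log_fn(ncol(mf$counts), " / ", ncol(m$counts), " cells pass QC (",
         "genes in [", qc$min_genes, ", ", qc$max_genes, "], mito < ",
         qc$max_mito_frac, ")")
  doub <- if (!is.null(doublets))
    run_stage("doublet_score", doublet_score(mf, doublets), log_fn) else NULL

  cluster_once <- function(mat, stage) {
    norm <- normalize_log_cp10k(mat)
    hvg <- select_hvg(norm, clustering$n_hvg)
    n_pcs <- min(clustering$n_pcs, length(hvg), ncol(norm) - 1L)
    emb <- run_pca(norm, hvg, n_pcs)
    part <- cluster_graph(emb, knn_k = min(clustering$knn_k, ncol(norm) - 1L),
                          resolution = clustering$resolution,
                          seed = clustering$seed)
    attr(part, "stage") <- stage
    list(norm = norm, emb = emb, part = part)
  }
  st <- run_stage("cluster_raw", cluster_once(mf, "raw"), log_fn)
  log_fn("raw clustering: ", nlevels(st$part), " clusters (",
         clustering$n_pcs, " PCs, resolution ", clustering$resolution, ")")

  triage <- NULL
  if (!is.null(neuronal_genes)) {
    triage <- run_stage("triage_neuronal",
      triage_neuronal(st$norm, st$part, mf, neuronal_genes,
                      nonneuronal_genes), log_fn)
    mf <- triage$counts
    st <- run_stage("recluster_neurons", cluster_once(mf, "neuron_filtered"),
                    log_fn)
    log_fn("retained ", ncol(mf$counts), " neuronal cells; reclustered into ",
           nlevels(st$part), " clusters")
  }

  part <- run_stage("merge_clusters",
    merge_indistinct_clusters(st$norm, st$emb, st$part), log_fn)
  markers <- run_stage("find_markers",
    find_all_markers(st$norm, part, min_pct = marker_min_pct,
                     min_diff_pct = marker_min_diff_pct), log_fn)

  res <- list(qc_metrics = metrics, partition = part, embedding = st$emb,
              markers = markers, triage = triage, doublets = doub,
              counts = mf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    qout <- metrics
    if (!is.null(doub)) qout <- merge(qout, doub, by = "cell_id", sort = FALSE)
    write.csv(qout, file.path(out_dir, "qc_metrics.csv"), row.names = FALSE)
    write.csv(data.frame(cell_id = names(part), cluster = as.character(part),
                         stage = attr(part, "stage")),
              file.path(out_dir, "partition.csv"), row.names = FALSE)
    write.csv(data.frame(cell_id = rownames(st$emb), st$emb,
                         check.names = FALSE),
              file.path(out_dir, "embedding.csv"), row.names = FALSE)
    write.csv(markers, file.path(out_dir, "markers.csv"), row.names = FALSE)
    write_manifest(out_dir,
                   config = list(qc = unclass(qc),
                                 clustering = unclass(clustering)),
                   stages = c("qc", "cluster", if (!is.null(triage)) "triage",
                              "merge", "markers"))
  }
  res
}

#' Cross-species analysis: harmonize, co-embed, joint cluster, KL matrix
#'
#' Harmonizes gene names case-insensitively, co-embeds both datasets into a
#' common PC space, clusters the joint embedding, cross-tabulates joint
#' clusters against the original labels, and computes the cluster-by-cluster
#' k-NN KL divergence matrix with its natural-log heatmap.
#'
#' @param a,b [count_matrix()] objects for the two species.
#' @param labels_a,labels_b per-cell original cluster labels (factors named or
#'   ordered as the matrix columns).
#' @param integration an [integration_config()].
#' @param divergence a [divergence_config()].
#' @param subsample_b optional number of `b` cells to subsample before
#'   embedding (balanced co-clustering: a much larger reference set is known
#'   to dominate the joint geometry; default matches the size of `a`). Use
#'   `Inf` to keep all cells.
#' @param out_dir output directory (`NULL` returns results without writing).
#' @param verbose emit per-stage log lines.
#' @return list with `embedding` (`co_embedding`), `joint_partition`,
#'   `crosstab`, `divergence` (`divergence_matrix`).
#' @export
run_cross_species <- function(a, b, labels_a, labels_b,
                              integration = integration_config(),
                              divergence = divergence_config(),
                              subsample_b = NULL, out_dir = NULL,
                              verbose = FALSE) {
  log_fn <- function(...) if (verbose) message("[drgmap] ", ...)
  stopifnot(length(labels_a) == ncol(a$counts),
            length(labels_b) == ncol(b$counts))
  n_b <- ncol(b$counts)
  target <- subsample_b %||% ncol(a$counts)
  if (is.finite(target) && n_b > target) {
    keep <- with_seed(integration$seed, sort(sample.int(n_b, target)))
    b <- subset_cells(b, cells = keep)
    labels_b <- labels_b[keep]
    log_fn("subsampled species b to ", target, " cells")
  }
  h <- run_stage("harmonize_genes", harmonize_genes(a, b), log_fn)
  log_fn(nrow(h$a$counts), " shared genes after case harmonization")
  emb <- run_stage("co_embed",
    co_embed(h$a, h$b, integration, labels_a, labels_b), log_fn)
  joint <- run_stage("joint_cluster",
    cluster_graph(emb$coords, knn_k = 20,
                  resolution = integration$resolution_joint,
                  seed = integration$seed), log_fn)
  ct <- joint_cluster_crosstab(joint, paste(emb$species, emb$orig_label,
                                            sep = ":"))
  dm <- run_stage("kl_matrix", kl_matrix(emb, divergence), log_fn)
  res <- list(embedding = emb, joint_partition = joint, crosstab = ct,
              divergence = dm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_embedding_csv(emb, file.path(out_dir, "joint_embedding.csv"))
    write.csv(data.frame(cell_id = emb$cell_id, species = emb$species,
                         orig_label = emb$orig_label,
                         joint_cluster = as.character(joint)),
              file.path(out_dir, "joint_partition.csv"), row.names = FALSE)
    write.csv(as.data.frame.matrix(ct$counts),
              file.path(out_dir, "joint_crosstab.csv"))
    render_heatmap(dm, file.path(out_dir, "ln_kl.csv"),
                   file.path(out_dir, "ln_kl_heatmap.png"))
    write_manifest(out_dir,
                   config = list(integration = unclass(integration),
                                 divergence = unclass(divergence)),
                   stages = c("harmonize", "co_embed", "joint_cluster",
                              "kl_matrix", "heatmap"))
  }
  res
}
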