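blob_embedding <- function(centers, n_each = 60, sd = 0.1, seed = 2) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(n_each, centers[i, 2], sd))))
  rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  coords
}

test_that("well-separated blobs are recovered as pure communities", {
  emb <- blob_embedding(rbind(c(0, 0), c(10, 0), c(0, 10)))
  part <- cluster_graph(emb, knn_k = 15, resolution = 0.5, seed = 1)
  expect_equal(nlevels(part), 3)
  truth <- rep(1:3, each = 60)
  expect_equal(ari(part, truth), 1)
  expect_equal(ari(part, truth), mclust::adjustedRandIndex(part, truth))
})

test_that("degenerate and invalid inputs are handled", {
  same <- matrix(1, 40, 2, dimnames = list(sprintf("c%02d", 1:40), NULL))
  part <- cluster_graph(same, knn_k = 10, resolution = 0.5, seed = 1)
  expect_equal(nlevels(part), 1)
  expect_error(cluster_graph(same, knn_k = 0), "knn_k")
  expect_error(cluster_graph(same[1:5, ], knn_k = 10), "more cells")
})

test_that("higher resolution does not coarsen the partition of a fixed graph", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6)), n_each = 40)
  sizes <- vapply(c(0.5, 1.5, 2.5, 3.5), function(r)
    nlevels(cluster_graph(emb, knn_k = 12, resolution = r, seed = 3)),
    integer(1))
  expect_true(sizes[length(sizes)] >= sizes[1])
})

test_that("clusters that are random halves of one population merge; planted
           clusters do not; single clusters pass through", {
  cfg <- sim_count_config(n_genes = 400, n_cells = 400, n_clusters = 2,
                          marker_genes_per_cluster = 20, marker_fold = 8,
                          doublet_rate = 0, seed = 21)
  sim <- simulate_counts(cfg)
  norm <- normalize_log_cp10k(sim$counts)
  emb <- run_pca(norm, select_hvg(norm, 100), 10)
  part <- as.character(sim$true_labels)
  i1 <- which(part == "C1")
  part[i1[seq_len(floor(length(i1) / 2))]] <- "C1split"
  part <- factor(part)
  names(part) <- colnames(sim$counts$counts)

  merged <- merge_indistinct_clusters(norm, emb, part)
  expect_equal(nlevels(merged), 2)               # split healed, C2 kept apart
  expect_equal(ari(merged, sim$true_labels), 1)
  expect_lte(nlevels(merged), nlevels(part))     # merging never adds clusters

  single <- factor(rep("C1", ncol(norm)))
  names(single) <- colnames(norm)
  expect_equal(nlevels(merge_indistinct_clusters(norm, emb, single)), 1)
})

test_that("triage removes clusters dominated by non-neuronal markers", {
  set.seed(30)
  n <- 90
  genes <- c("SNAP25", "SCN10A", "PLP1", "MBP", "APOE", sprintf("BG%02d", 1:20))
  mat <- matrix(rnbinom(length(genes) * n, size = 2, mu = 0.2), length(genes),
                dimnames = list(genes, sprintf("c%03d", 1:n)))
  part <- factor(rep(c("neu", "glia", "quiet"), each = 30))
  names(part) <- colnames(mat)
  mat[c("SNAP25", "SCN10A"), part == "neu"] <- 5L
  mat[c("PLP1", "MBP", "APOE"), part == "glia"] <- 5L
  mat[, part == "quiet"] <- 0L                   # both scores zero: tie retains
  m <- count_matrix(mat)
  norm <- normalize_log_cp10k(m)

  expect_warning(tri <- triage_neuronal(norm, part, m), "skipped")
  expect_identical(sort(tri$calls$cluster[tri$calls$neuronal]),
                   c("neu", "quiet"))
  expect_setequal(colnames(tri$counts$counts),
                  names(part)[part %in% c("neu", "quiet")])
  # a gene shared by both panels still yields a well-defined call
  tri2 <- triage_neuronal(norm, part, m,
                          neuronal_genes = c("SNAP25", "APOE"),
                          nonneuronal_genes = c("PLP1", "APOE"))
  expect_equal(nrow(tri2$calls), 3)
  expect_error(triage_neuronal(norm, part, m,
                               neuronal_genes = "NOPE1",
                               nonneuronal_genes = "NOPE2"),
               "neither triage panel")
  expect_warning(triage_neuronal(norm, part, m,
                                 neuronal_genes = c("SNAP25", "MISSING")),
                 "skipped")
})

test_that("the clustering stage recovers planted cluster structure", {
  cfg <- sim_count_config(n_genes = 600, n_cells = 600, n_clusters = 5,
                          marker_genes_per_cluster = 20, marker_fold = 8,
                          doublet_rate = 0, seed = 3)
  sim <- simulate_counts(cfg)
  norm <- normalize_log_cp10k(sim$counts)
  emb <- run_pca(norm, select_hvg(norm, 200), 16)
  part <- cluster_graph(emb, knn_k = 20, resolution = 2.0, seed = 1)
  merged <- merge_indistinct_clusters(norm, emb, part)
  expect_gt(ari(merged, sim$true_labels), 0.9)
  # determinism end-to-end under fixed seeds
  part2 <- cluster_graph(emb, knn_k = 20, resolution = 2.0, seed = 1)
  expect_identical(as.character(part), as.character(part2))
})
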