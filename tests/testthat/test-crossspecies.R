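test_that("gene harmonization uppercases, intersects and keeps row order aligned", {
  a <- toy_counts(matrix(1:4, 2), c("SCN10A", "TAC1"), c("a1", "a2"))
  b <- toy_counts(matrix(1:4, 2), c("Scn10a", "Piezo2"), c("b1", "b2"))
  h <- harmonize_genes(a, b)
  expect_identical(rownames(h$a$counts), "SCN10A")
  expect_identical(rownames(h$a$counts), rownames(h$b$counts))

  # identical lists: unchanged except case
  a2 <- toy_counts(matrix(1:4, 2), c("Kit", "Ret"), c("a1", "a2"))
  h2 <- harmonize_genes(a2, a2)
  expect_identical(rownames(h2$a$counts), c("KIT", "RET"))
  expect_equal(as.matrix(h2$a$counts), as.matrix(a2$counts),
               ignore_attr = TRUE)

  disj <- toy_counts(matrix(1:4, 2), c("X1", "X2"), c("b1", "b2"))
  expect_error(harmonize_genes(a, disj), "no shared genes")

  # case collision: the higher-count row wins, with a warning
  coll <- toy_counts(rbind(c(1L, 1L), c(9L, 9L), c(2L, 2L)),
                     c("abc", "ABC", "TAC1"), c("b1", "b2"))
  expect_warning(hc <- harmonize_genes(a, coll), "collision")
  expect_identical(sort(rownames(hc$b$counts)), "TAC1")
})

test_that("co-embedding a dataset with its own copy mixes the blocks", {
  cfg <- sim_count_config(n_genes = 300, n_cells = 250, n_clusters = 3,
                          marker_genes_per_cluster = 15, marker_fold = 8,
                          doublet_rate = 0, seed = 31)
  sim <- simulate_counts(cfg)
  a <- sim$counts
  b <- count_matrix(a$counts, species = a$species, mito_mask = a$mito_mask)
  colnames(b$counts) <- sub("^cell", "copy", colnames(b$counts))
  emb <- co_embed(a, b, integration_config(n_pcs_joint = 10),
                  sim$true_labels, sim$true_labels)
  joint <- cluster_graph(emb$coords, knn_k = 15, resolution = 0.5, seed = 1)
  # per-joint-cluster dataset entropy: ~50:50 in every cluster
  ent <- vapply(levels(joint), function(g) {
    p <- mean(emb$species[joint == g] == "a")
    if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  }, numeric(1))
  expect_gte(mean(ent), 0.95)

  expect_error(co_embed(subset_cells(a, cells = 1), subset_cells(b, cells = 1)),
               "at least 2 cells")
  expect_error(co_embed(a, subset_cells(b, genes = 1:10)), "gene rows differ")
})

test_that("co-embedding geometry is invariant to the argument order", {
  cfg <- sim_count_config(n_genes = 200, n_cells = 120, n_clusters = 2,
                          doublet_rate = 0, seed = 33)
  a <- simulate_counts(cfg)$counts
  cfg2 <- sim_count_config(n_genes = 200, n_cells = 100, n_clusters = 2,
                           doublet_rate = 0, seed = 34)
  b <- simulate_counts(cfg2)$counts
  colnames(b$counts) <- sub("^cell", "bcell", colnames(b$counts))
  e1 <- co_embed(a, b, integration_config(n_pcs_joint = 8))
  e2 <- co_embed(b, a, integration_config(n_pcs_joint = 8))
  # pairwise distances (rotation/sign agnostic) must match after reordering
  ord1 <- order(e1$cell_id); ord2 <- order(e2$cell_id)
  d1 <- as.matrix(dist(e1$coords[ord1, ]))
  d2 <- as.matrix(dist(e2$coords[ord2, ]))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("crosstab accounts for every cell and row-normalizes", {
  joint <- factor(c("J1", "J1", "J2", "J2", "J2"))
  orig <- factor(c("H1", "H2", "H2", "H2", "H3"))
  ct <- joint_cluster_crosstab(joint, orig)
  expect_equal(sum(ct$counts), 5)
  expect_true(all(abs(rowSums(ct$prop) - 1) < 1e-12))
  one <- joint_cluster_crosstab(factor(rep("J1", 5)), orig)
  expect_equal(nrow(one$counts), 1)
  expect_equal(as.vector(one$counts), as.vector(table(orig)))
})

test_that("embedding CSVs round-trip through the external interchange format", {
  cfg <- sim_count_config(n_genes = 150, n_cells = 60, n_clusters = 2,
                          doublet_rate = 0, seed = 35)
  sim <- simulate_counts(cfg)
  b <- count_matrix(sim$counts$counts, mito_mask = sim$counts$mito_mask)
  colnames(b$counts) <- sub("^cell", "copy", colnames(b$counts))
  emb <- co_embed(sim$counts, b, integration_config(n_pcs_joint = 5),
                  sim$true_labels, sim$true_labels)
  path <- file.path(tempdir(), "emb.csv")
  write_embedding_csv(emb, path)
  back <- read_embedding_csv(path)
  expect_equal(back$coords, emb$coords, tolerance = 1e-12)
  expect_identical(back$species, emb$species)
  expect_identical(back$orig_label, emb$orig_label)
  expect_error(read_embedding_csv("/nonexistent/emb.csv"), "not found")
})
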