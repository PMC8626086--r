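test_that("simulation is deterministic under a fixed config and seed", {
  cfg <- sim_count_config(n_genes = 120, n_cells = 80, n_clusters = 3, seed = 42)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$true_labels, s2$true_labels)
  expect_identical(s1$true_doublets, s2$true_doublets)

  sp <- sim_spatial_config(n_points = 200, mode = "thomas", seed = 9)
  expect_identical(simulate_spatial_map(sp), simulate_spatial_map(sp))
})

test_that("zero base mean degenerates to an all-zero singlet matrix", {
  cfg <- sim_count_config(n_genes = 50, n_cells = 30, n_clusters = 2,
                          base_mean = 0, seed = 1)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$counts$counts), 0)
  expect_false(any(sim$true_doublets))
})

test_that("config validation rejects impossible marker layouts and bad props", {
  expect_error(sim_count_config(n_genes = 50, n_clusters = 5,
                                marker_genes_per_cluster = 20),
               "exceeds available genes")
  expect_error(sim_count_config(n_clusters = 2, cluster_props = c(0.7, 0.6)),
               "sum to 1")
  expect_error(sim_spatial_config(mode = "thomas", parent_sigma = 0),
               "parent_sigma")
})

test_that("negative binomial moments are recovered empirically", {
  cfg <- sim_count_config(n_genes = 300, n_cells = 2000, n_clusters = 1,
                          base_mean = 0.5, dispersion = 2,
                          marker_genes_per_cluster = 0, libsize_sigma = 0,
                          mito_gene_frac = 0, doublet_rate = 0, seed = 11)
  sim <- simulate_counts(cfg)
  x <- as.matrix(sim$counts$counts)
  mu <- 0.5
  v_theory <- mu + mu^2 / 2          # mean/shape NB: var = mu + mu^2/theta
  se <- sqrt(v_theory / ncol(x))
  gene_means <- rowMeans(x)
  expect_gte(mean(abs(gene_means - mu) < 3 * se), 0.99)
  # pooled variance close to the NB variance, far from Poisson
  gene_vars <- apply(x, 1, var)
  expect_equal(mean(gene_vars), v_theory, tolerance = 0.05)
  expect_gt(mean(gene_vars), mu * 1.1)
})

test_that("two-species simulation encodes orthology by letter case", {
  ca <- sim_count_config(n_genes = 200, n_cells = 60, n_clusters = 3,
                         marker_genes_per_cluster = 10, seed = 5)
  cb <- sim_count_config(n_genes = 200, n_cells = 60, n_clusters = 3,
                         marker_genes_per_cluster = 10, seed = 6)
  map <- data.frame(cluster_a = 1:2, cluster_b = 1:2)
  ts <- simulate_two_species(ca, cb, map, divergence_frac = 0.2)
  ga <- rownames(ts$a$counts$counts)
  gb <- rownames(ts$b$counts$counts)
  expect_identical(ga, toupper(ga))                       # species A ALL-CAPS
  expect_identical(substr(gb, 2, 100), tolower(substr(gb, 2, 100)))
  expect_true("GENE00001" %in% ga && "Gene00001" %in% gb) # same stem, two cases
  # paired marker stems share (1 - divergence) of their members
  shared <- length(intersect(ts$truth$marker_stems_a[[1]],
                             ts$truth$marker_stems_b[[1]]))
  expect_equal(shared, 8)
})

test_that("divergence fraction 0 and 1 give identical / disjoint marker stems", {
  ca <- sim_count_config(n_genes = 200, n_cells = 40, n_clusters = 2,
                         marker_genes_per_cluster = 10, seed = 1)
  cb <- sim_count_config(n_genes = 200, n_cells = 40, n_clusters = 2,
                         marker_genes_per_cluster = 10, seed = 2)
  map <- data.frame(cluster_a = 1:2, cluster_b = 1:2)
  t0 <- simulate_two_species(ca, cb, map, divergence_frac = 0)
  expect_identical(t0$truth$marker_stems_a, t0$truth$marker_stems_b)
  t1 <- simulate_two_species(ca, cb, map, divergence_frac = 1)
  expect_length(intersect(unlist(t1$truth$marker_stems_a),
                          unlist(t1$truth$marker_stems_b)), 0)
  expect_error(simulate_two_species(ca, cb, data.frame(a = 1, b = 9)),
               "absent")
})

test_that("csr maps have binomial label frequencies independent of position", {
  sm <- simulate_spatial_map(sim_spatial_config(n_points = 10000, mode = "csr",
                                                seed = 3))
  frac_a <- mean(sm$label == "A")
  expect_gte(frac_a, 0.48); expect_lte(frac_a, 0.52)

  # chi-square of label vs spatial quadrant non-significant in >= 98/100 runs
  pvals <- vapply(1:100, function(s) {
    m <- simulate_spatial_map(sim_spatial_config(n_points = 600, mode = "csr",
                                                 seed = 4000 + s))
    quad <- interaction(m$x_um > 750, m$y_um > 750)
    suppressWarnings(stats::chisq.test(table(m$label, quad))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("single-label and wide-scatter thomas maps behave as expected", {
  one <- simulate_spatial_map(sim_spatial_config(n_points = 50, labels = "X",
                                                 label_props = 1, seed = 2))
  expect_true(all(one$label == "X"))

  # with huge parent scatter the same-label nearest-neighbor excess vanishes
  same_rate <- function(m) {
    nn <- neighborhood_composition(as_spatial_point_set(m), 1, 1)
    mean(vapply(seq_len(nrow(m)), function(i)
      nn$raw[i, 1, as.character(m$label[i])], numeric(1)))
  }
  wide <- simulate_spatial_map(sim_spatial_config(
    n_points = 1500, mode = "thomas", parent_sigma = 1e6, seed = 5))
  tight <- simulate_spatial_map(sim_spatial_config(
    n_points = 1500, mode = "thomas", parent_sigma = 30, seed = 5))
  expect_lt(abs(same_rate(wide) - 0.5), 0.05)
  expect_gt(same_rate(tight), 0.7)
})
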