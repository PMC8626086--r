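#' Configuration for the negative-binomial count simulator
#'
#' The generator draws UMI counts gene-wise from a negative binomial
#' parameterized by mean and shape (`var = mu + mu^2 / dispersion`), the
#' standard noise model for droplet scRNA/snRNA-seq. Each cluster elevates a
#' disjoint block of marker genes by `marker_fold`; per-cell library-size
#' factors are log-normal with unit mean; a `mito_gene_frac` fraction of genes
#' is mitochondrial with means scaled so the expected mitochondrial UMI
#' fraction is `mito_mean_frac`; a `doublet_rate` fraction of cells is formed
#' by summing two freshly drawn singlet profiles (heterotypic with probability
#' 0.75, mimicking physical co-encapsulation of two nuclei).
#'
#' @param n_genes,n_cells,n_clusters positive integers.
#' @param cluster_props probability vector over clusters (default uniform).
#' @param base_mean baseline expected UMI per gene per cell.
#' @param marker_genes_per_cluster markers planted per cluster (disjoint sets).
#' @param marker_fold fold elevation of marker means (> 1).
#' @param dispersion NB shape theta (> 0).
#' @param libsize_sigma log-normal sd of the per-cell library factor.
#' @param mito_gene_frac fraction of genes that are mitochondrial.
#' @param mito_mean_frac expected mitochondrial UMI fraction per cell.
#' @param doublet_rate fraction of cells replaced by summed doublet profiles.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a validated list of class `sim_count_config`.
#' @export
sim_count_config <- function(n_genes = 1000, n_cells = 1000, n_clusters = 5,
                             cluster_props = NULL, base_mean = 0.2,
                             marker_genes_per_cluster = 20, marker_fold = 8,
                             dispersion = 2, libsize_sigma = 0.3,
                             mito_gene_frac = 0.02, mito_mean_frac = 0.05,
                             doublet_rate = 0.05, seed = 1L) {
  cluster_props <- cluster_props %||% rep(1 / n_clusters, n_clusters)
  stopifnot(n_genes >= 1, n_cells >= 1, n_clusters >= 1,
            length(cluster_props) == n_clusters,
            base_mean >= 0, marker_genes_per_cluster >= 0, marker_fold > 1,
            dispersion > 0, libsize_sigma >= 0,
            mito_gene_frac >= 0, mito_gene_frac <= 1,
            mito_mean_frac >= 0, mito_mean_frac < 1,
            doublet_rate >= 0, doublet_rate < 1)
  check_props(cluster_props, "cluster_props")
  n_mito <- round(mito_gene_frac * n_genes)
  if (marker_genes_per_cluster * n_clusters > n_genes - n_mito)
    stop("marker_genes_per_cluster x n_clusters exceeds available genes")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 cluster_props = cluster_props, base_mean = base_mean,
                 marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
                 marker_fold = marker_fold, dispersion = dispersion,
                 libsize_sigma = libsize_sigma, mito_gene_frac = mito_gene_frac,
                 mito_mean_frac = mito_mean_frac, doublet_rate = doublet_rate,
                 seed = as.integer(seed)),
            class = "sim_count_config")
}

# Core generator. marker_idx: list (length n_clusters) of gene row indices
# elevated in that cluster; mito_idx: integer indices of mitochondrial genes.
# Assumes the RNG is already seeded by the caller.
sim_core <- function(cfg, gene_names, marker_idx, mito_idx, cell_prefix = "cell") {
  G <- cfg$n_genes; N <- cfg$n_cells; K <- cfg$n_clusters
  labels <- sample.int(K, N, replace = TRUE, prob = cfg$cluster_props)
  doublet <- rep(FALSE, N)
  counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(G, N))
  if (cfg$base_mean > 0) {
    base <- rep(cfg$base_mean, G)
    if (length(mito_idx)) {
      # scale mito means so E[mito UMI]/E[total UMI] ~ mito_mean_frac;
      # expected non-mito total averaged over clusters includes marker lifts
      nonmito_total <- cfg$base_mean * (G - length(mito_idx)) +
        cfg$base_mean * (cfg$marker_fold - 1) *
          sum(lengths(marker_idx) * cfg$cluster_props)
      base[mito_idx] <- cfg$mito_mean_frac / (1 - cfg$mito_mean_frac) *
        nonmito_total / length(mito_idx)
    }
    libf <- if (cfg$libsize_sigma > 0)
      rlnorm(N, meanlog = -cfg$libsize_sigma^2 / 2, sdlog = cfg$libsize_sigma)
    else rep(1, N)
    draw_cells <- function(cl, lf) {
      mu_g <- base
      if (length(marker_idx[[cl]]))
        mu_g[marker_idx[[cl]]] <- mu_g[marker_idx[[cl]]] * cfg$marker_fold
      matrix(rnbinom(G * length(lf), size = cfg$dispersion,
                     mu = rep(mu_g, times = length(lf)) * rep(lf, each = G)),
             nrow = G)
    }
    dense <- matrix(0L, G, N)
    for (cl in seq_len(K)) {
      idx <- which(labels == cl)
      if (length(idx)) dense[, idx] <- draw_cells(cl, libf[idx])
    }
    n_doub <- round(cfg$doublet_rate * N)
    if (n_doub > 0) {
      doub_cells <- sample.int(N, n_doub)
      for (j in doub_cells) {
        c1 <- labels[j]
        hetero <- K > 1 && runif(1) < 0.75
        c2 <- if (hetero) sample(setdiff(seq_len(K), c1), 1) else
          sample.int(K, 1, prob = cfg$cluster_props)
        lf2 <- if (cfg$libsize_sigma > 0)
          rlnorm(2, -cfg$libsize_sigma^2 / 2, cfg$libsize_sigma) else c(1, 1)
        dense[, j] <- draw_cells(c1, lf2[1]) + draw_cells(c2, lf2[2])
      }
      doublet[doub_cells] <- TRUE
    }
    counts <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  }
  rownames(counts) <- gene_names
  colnames(counts) <- sprintf("%s%05d", cell_prefix, seq_len(N))
  mask <- logical(G); mask[mito_idx] <- TRUE
  list(counts = count_matrix(counts, species = "synthetic", mito_mask = mask),
       true_labels = factor(paste0("C", labels), paste0("C", seq_len(K))),
       true_doublets = doublet)
}

#' Simulate a cluster-structured UMI count matrix
#'
#' @param config a [sim_count_config()].
#' @return list with `counts` (a [count_matrix()]), `true_labels` (factor of
#'   generating clusters; for doublets, the first parent's cluster) and
#'   `true_doublets` (logical). With `base_mean = 0` the matrix is all zero
#'   and every cell is a singlet (the zero-rate NB is degenerate at 0).
#' @examples
#' sim <- simulate_counts(sim_count_config(n_genes = 50, n_cells = 40, seed = 7))
#' table(sim$true_labels)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  n_mito <- round(config$mito_gene_frac * config$n_genes)
  n_nonmito <- config$n_genes - n_mito
  gene_names <- c(sprintf("G%05d", seq_len(n_nonmito)),
                  if (n_mito) sprintf("MT-G%03d", seq_len(n_mito)))
  mpc <- config$marker_genes_per_cluster
  marker_idx <- lapply(seq_len(config$n_clusters), function(cl)
    if (mpc == 0) integer(0) else ((cl - 1) * mpc + 1):(cl * mpc))
  mito_idx <- if (n_mito) (n_nonmito + 1):config$n_genes else integer(0)
  with_seed(config$seed,
            sim_core(config, gene_names, marker_idx, mito_idx))
}

title_case <- function(s) paste0(toupper(substr(s, 1, 1)),
                                 tolower(substring(s, 2)))

#' Simulate two species with partially shared marker programs
#'
#' Generates one count matrix per "species" over a common gene-stem universe.
#' Species A gene names are ALL-CAPS, species B title-case with the same stem,
#' so orthology is recoverable by case-insensitive matching (as done by
#' [harmonize_genes()]). Clusters paired in `shared_cluster_map` share their
#' marker stems except for a `divergence_frac` fraction swapped for
#' species-specific markers (the ortholog still exists in both genomes; only
#' its elevation diverges). Unpaired clusters get private marker sets. A small
#' fraction (5%) of each species' genes is species-private, so the gene
#' intersection is proper.
#'
#' @param config_a,config_b [sim_count_config()]s with equal `n_genes`.
#' @param shared_cluster_map data.frame/matrix with columns `cluster_a`,
#'   `cluster_b` (integer cluster indices to pair).
#' @param divergence_frac fraction in \[0, 1\] of paired markers that diverge.
#' @return list with `a`, `b` (each as returned by [simulate_counts()]) and
#'   `truth` (pairing, per-cluster marker stems per species).
#' @export
simulate_two_species <- function(config_a, config_b, shared_cluster_map,
                                 divergence_frac = 0.2) {
  stopifnot(inherits(config_a, "sim_count_config"),
            inherits(config_b, "sim_count_config"),
            divergence_frac >= 0, divergence_frac <= 1)
  if (config_a$n_genes != config_b$n_genes)
    stop("the two configs must use the same n_genes (shared stem universe)")
  map <- as.data.frame(shared_cluster_map)
  colnames(map) <- c("cluster_a", "cluster_b")
  if (any(map$cluster_a < 1 | map$cluster_a > config_a$n_clusters) ||
      any(map$cluster_b < 1 | map$cluster_b > config_b$n_clusters))
    stop("shared_cluster_map references clusters absent from a config")
  if (anyDuplicated(map$cluster_a) || anyDuplicated(map$cluster_b))
    stop("shared_cluster_map must pair each cluster at most once")

  G <- config_a$n_genes
  n_mito <- round(config_a$mito_gene_frac * G)
  n_priv <- ceiling(0.05 * (G - n_mito))
  n_shared <- G - n_mito - n_priv
  shared_stems <- sprintf("gene%05d", seq_len(n_shared))
  mito_stems <- if (n_mito) sprintf("mt-g%03d", seq_len(n_mito)) else character(0)
  stems_a <- c(shared_stems, sprintf("aonly%05d", seq_len(n_priv)), mito_stems)
  stems_b <- c(shared_stems, sprintf("bonly%05d", seq_len(n_priv)), mito_stems)

  # allocate disjoint marker stems from the shared pool
  cursor <- 0L
  take <- function(n) {
    if (cursor + n > n_shared) stop("not enough shared genes for marker layout")
    out <- shared_stems[cursor + seq_len(n)]
    cursor <<- cursor + n
    out
  }
  mk_a <- vector("list", config_a$n_clusters)
  mk_b <- vector("list", config_b$n_clusters)
  mpc_a <- config_a$marker_genes_per_cluster
  mpc_b <- config_b$marker_genes_per_cluster
  for (r in seq_len(nrow(map))) {
    m_common <- round((1 - divergence_frac) * min(mpc_a, mpc_b))
    common <- take(m_common)
    mk_a[[map$cluster_a[r]]] <- c(common, take(mpc_a - m_common))
    mk_b[[map$cluster_b[r]]] <- c(common, take(mpc_b - m_common))
  }
  for (cl in setdiff(seq_len(config_a$n_clusters), map$cluster_a))
    mk_a[[cl]] <- take(mpc_a)
  for (cl in setdiff(seq_len(config_b$n_clusters), map$cluster_b))
    mk_b[[cl]] <- take(mpc_b)

  mito_idx <- if (n_mito) (G - n_mito + 1):G else integer(0)
  sim_a <- with_seed(config_a$seed,
    sim_core(config_a, toupper(stems_a),
             lapply(mk_a, function(s) match(s, stems_a)), mito_idx, "a_cell"))
  sim_b <- with_seed(config_b$seed,
    sim_core(config_b, title_case(stems_b),
             lapply(mk_b, function(s) match(s, stems_b)), mito_idx, "b_cell"))
  list(a = sim_a, b = sim_b,
       truth = list(pairing = map, marker_stems_a = mk_a, marker_stems_b = mk_b))
}

#' Configuration for the spatial point-pattern simulator
#'
#' `csr` draws positions uniformly on the domain with labels i.i.d. from
#' `label_props` (labels independent of position: the null of the neighborhood
#' analysis). `thomas` scatters each label's points around label-specific
#' parent points (Gaussian with sd `parent_sigma`), so same-label cells
#' aggregate spatially (the alternative).
#'
#' @param n_points number of cells.
#' @param labels character vector of label names.
#' @param label_props probability vector over labels (default uniform).
#' @param mode `"csr"` or `"thomas"`.
#' @param n_parents parents per label (thomas mode).
#' @param parent_sigma offspring scatter sd in micrometers (thomas mode).
#' @param domain width and height of the rectangular field, micrometers.
#' @param seed integer seed.
#' @return list of class `sim_spatial_config`.
#' @export
sim_spatial_config <- function(n_points = 800, labels = c("A", "B"),
                               label_props = NULL, mode = c("csr", "thomas"),
                               n_parents = 10, parent_sigma = 50,
                               domain = c(width = 1500, height = 1500),
                               seed = 1L) {
  mode <- match.arg(mode)
  label_props <- label_props %||% rep(1 / length(labels), length(labels))
  stopifnot(n_points >= 1, length(labels) >= 1,
            length(label_props) == length(labels),
            n_parents >= 1, length(domain) == 2, all(domain > 0))
  check_props(label_props, "label_props")
  if (mode == "thomas" && parent_sigma <= 0)
    stop("parent_sigma must be > 0 in thomas mode")
  structure(list(n_points = as.integer(n_points), labels = labels,
                 label_props = label_props, mode = mode,
                 n_parents = as.integer(n_parents), parent_sigma = parent_sigma,
                 domain = unname(domain), seed = as.integer(seed)),
            class = "sim_spatial_config")
}

#' Simulate an annotated 2-D cell map
#'
#' @param config a [sim_spatial_config()].
#' @return data.frame with columns `x_um`, `y_um`, `label` (factor) and
#'   `section_id`, of class `spatial_point_set`.
#' @export
simulate_spatial_map <- function(config) {
  stopifnot(inherits(config, "sim_spatial_config"))
  with_seed(config$seed, {
    n <- config$n_points
    lab <- factor(sample(config$labels, n, replace = TRUE,
                         prob = config$label_props), levels = config$labels)
    if (config$mode == "csr") {
      x <- runif(n, 0, config$domain[1])
      y <- runif(n, 0, config$domain[2])
    } else {
      x <- numeric(n); y <- numeric(n)
      for (L in config$labels) {
        idx <- which(lab == L)
        if (!length(idx)) next
        px <- runif(config$n_parents, 0, config$domain[1])
        py <- runif(config$n_parents, 0, config$domain[2])
        pa <- sample.int(config$n_parents, length(idx), replace = TRUE)
        # offspring are not clipped to the domain: clipping would distort the
        # Gaussian scatter near edges
        x[idx] <- px[pa] + rnorm(length(idx), sd = config$parent_sigma)
        y[idx] <- py[pa] + rnorm(length(idx), sd = config$parent_sigma)
      }
    }
    out <- data.frame(x_um = x, y_um = y, label = lab, section_id = 1L)
    class(out) <- c("spatial_point_set", "data.frame")
    out
  })
}
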