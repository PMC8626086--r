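#' Divergence-estimation configuration
#'
#' @param k nearest-neighbor order of the estimator (default 1).
#' @param min_cells smallest cluster size admitted to the divergence matrix.
#' @param epsilon_clamp floor applied to the estimate before taking its
#'   natural log (raw estimates are reported unclamped).
#' @param dims number of embedding dimensions used (default 30).
#' @export
divergence_config <- function(k = 1L, min_cells = 5L, epsilon_clamp = 1e-6,
                              dims = 30L) {
  stopifnot(k >= 1, min_cells >= 1, epsilon_clamp > 0, dims >= 1)
  structure(list(k = as.integer(k), min_cells = as.integer(min_cells),
                 epsilon_clamp = epsilon_clamp, dims = as.integer(dims)),
            class = "divergence_config")
}

#' k-NN Kullback-Leibler divergence between two samples
#'
#' The nearest-neighbor estimator of `D(P || Q)` from samples: with
#' `rho_k(x_i)` the distance from `x_i` to its k-th nearest neighbor within
#' the P sample (self excluded) and `nu_k(x_i)` the distance to its k-th
#' nearest neighbor in the Q sample,
#'
#' `D_hat = (d / n) * sum_i log(nu_k(x_i) / rho_k(x_i)) + log(m / (n - 1))`.
#'
#' The estimate is asymptotically consistent but can be negative at finite
#' sample sizes; no clamping is applied here. Zero neighbor distances (exact
#' duplicate points) are regularized by substituting the smallest positive
#' distance times 1e-12.
#'
#' @param p_sample n x d matrix of query-distribution points.
#' @param q_sample m x d matrix of reference-distribution points.
#' @param k neighbor order; requires `n >= k + 1` and `m >= k`.
#' @return the scalar divergence estimate (nats).
#' @examples
#' set.seed(1)
#' p <- matrix(rnorm(2000), ncol = 2)
#' q <- matrix(rnorm(2000, mean = 1), ncol = 2)
#' kl_knn(p, q)  # close to the closed form d * mu^2 / 2 = 1
#' @export
kl_knn <- function(p_sample, q_sample, k = 1L) {
  p_sample <- as.matrix(p_sample); q_sample <- as.matrix(q_sample)
  if (ncol(p_sample) != ncol(q_sample)) stop("dimension mismatch")
  n <- nrow(p_sample); m <- nrow(q_sample); d <- ncol(p_sample)
  if (n <= k) stop("need n >= k + 1 points in p_sample")
  if (m < k) stop("need m >= k points in q_sample")
  rho <- knn_lookup(p_sample, p_sample, k, exclude_self = TRUE)$dist[, k]
  nu <- knn_lookup(p_sample, q_sample, k, exclude_self = FALSE)$dist[, k]
  fix_zero <- function(v) {
    if (any(v == 0)) {
      pos <- v[v > 0]
      v[v == 0] <- if (length(pos)) min(pos) * 1e-12 else 1e-300
    }
    v
  }
  rho <- fix_zero(rho); nu <- fix_zero(nu)
  d / n * sum(log(nu / rho)) + log(m / (n - 1))
}

#' Pairwise cluster divergence matrix in a joint embedding
#'
#' Computes `kl_knn` for every (query-species cluster, reference-species
#' cluster) pair using the first `dims` embedding columns. Clusters with fewer
#' than `min_cells` cells are reported as missing (`NA` rows/columns and
#' listed in `skipped`), never as zero. The matrix is generally asymmetric;
#' no symmetrization is applied.
#'
#' @param emb a `co_embedding` (or list with `coords`, `species`,
#'   `orig_label`) carrying species and original-cluster metadata.
#' @param config a [divergence_config()].
#' @param query_species,ref_species which species tag forms rows / columns.
#' @return list of class `divergence_matrix`: `kl` (raw estimates), `ln_kl`
#'   (`log(pmax(kl, epsilon_clamp))`), `n_p`, `m_q` (cluster sizes),
#'   `skipped` (character).
#' @export
kl_matrix <- function(emb, config = divergence_config(),
                      query_species = "a", ref_species = "b") {
  stopifnot(inherits(config, "divergence_config"))
  coords <- emb$coords[, seq_len(min(config$dims, ncol(emb$coords))),
                       drop = FALSE]
  sp <- emb$species; lab <- emb$orig_label
  qlab <- sort(unique(lab[sp == query_species]))
  rlab <- sort(unique(lab[sp == ref_species]))
  if (!length(qlab) || !length(rlab))
    stop("a species has zero clusters in the embedding metadata")
  qsize <- vapply(qlab, function(g) sum(sp == query_species & lab == g),
                  integer(1))
  rsize <- vapply(rlab, function(g) sum(sp == ref_species & lab == g),
                  integer(1))
  ok_q <- qsize >= config$min_cells & qsize >= config$k + 1L
  ok_r <- rsize >= config$min_cells & rsize >= config$k
  kl <- matrix(NA_real_, length(qlab), length(rlab),
               dimnames = list(qlab, rlab))
  for (i in which(ok_q)) {
    pi <- coords[sp == query_species & lab == qlab[i], , drop = FALSE]
    for (j in which(ok_r)) {
      qj <- coords[sp == ref_species & lab == rlab[j], , drop = FALSE]
      kl[i, j] <- kl_knn(pi, qj, k = config$k)
    }
  }
  structure(list(kl = kl,
                 ln_kl = log(pmax(kl, config$epsilon_clamp)),
                 n_p = setNames(qsize, qlab), m_q = setNames(rsize, rlab),
                 skipped = c(qlab[!ok_q], rlab[!ok_r])),
            class = "divergence_matrix")
}

#' Write the ln-KL matrix as CSV and render it as a heatmap
#'
#' Row and column order is taken from the matrix as-is (no clustering or
#' reordering is applied by the renderer).
#'
#' @param dm a `divergence_matrix`.
#' @param csv_path output CSV for the `ln_kl` values (row labels in the first
#'   column).
#' @param figure_path optional PNG path; skipped when `NULL`.
#' @return the paths written, invisibly.
#' @export
render_heatmap <- function(dm, csv_path, figure_path = NULL) {
  stopifnot(inherits(dm, "divergence_matrix"))
  df <- data.frame(cluster = rownames(dm$ln_kl), dm$ln_kl,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(figure_path)) {
    grDevices::png(figure_path, width = 1200, height = 900, res = 150)
    on.exit(grDevices::dev.off())
    x <- dm$ln_kl
    x[!is.finite(x)] <- NA
    pheatmap::pheatmap(x, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = "ln KL divergence (query rows vs reference columns)",
                       na_col = "grey80")
  }
  invisible(c(csv_path, figure_path))
}

#' Read back a ln-KL CSV written by [render_heatmap()]
#' @param csv_path path written by [render_heatmap()].
#' @return numeric matrix of ln-KL values with dimnames.
#' @export
read_lnkl_csv <- function(csv_path) {
  df <- read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
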