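# Shared fixture builders and independent oracles for the test suite.

# tiny count matrix from a dense integer matrix with explicit names
toy_counts <- function(mat, gene_ids, cell_ids, species = "synthetic",
                       mito_mask = NULL) {
  dimnames(mat) <- list(gene_ids, cell_ids)
  count_matrix(mat, species = species, mito_mask = mito_mask)
}

# a count_matrix whose cells have exactly `detected` detected genes (one UMI
# per detected non-mito gene; with a positive mito fraction the single mito
# gene counts as one of them and carries round(f/(1-f) * (detected-1)) UMIs)
cells_with_detected <- function(detected, mito_frac = 0, n_genes = max(detected) + 1) {
  stopifnot(n_genes > max(detected))
  n <- length(detected)
  mat <- matrix(0L, n_genes + 1L, n)  # last row is the mito gene
  for (j in seq_len(n)) {
    f <- mito_frac[min(j, length(mito_frac))]
    n_plain <- detected[j] - (f > 0)
    if (n_plain > 0) mat[seq_len(n_plain), j] <- 1L
    if (f > 0 && detected[j] > 0)
      mat[n_genes + 1L, j] <- max(1L, round(f / (1 - f) * n_plain))
  }
  toy_counts(mat, c(sprintf("G%04d", seq_len(n_genes)), "MT-1"),
             sprintf("cell%03d", seq_len(n)))
}

# independent brute-force reference for the k-NN KL estimator: double loop,
# full distance enumeration with sort(), the same formula written separately
kl_bruteforce <- function(p, q, k = 1) {
  n <- nrow(p); m <- nrow(q); d <- ncol(p)
  rho <- numeric(n); nu <- numeric(n)
  for (i in seq_len(n)) {
    dp <- sqrt(colSums((t(p[-i, , drop = FALSE]) - p[i, ])^2))
    dq <- sqrt(colSums((t(q) - p[i, ])^2))
    rho[i] <- sort(dp)[k]
    nu[i] <- sort(dq)[k]
  }
  fix <- function(v) {
    z <- v == 0
    if (any(z)) v[z] <- if (any(!z)) min(v[!z]) * 1e-12 else 1e-300
    v
  }
  rho <- fix(rho); nu <- fix(nu)
  d / n * sum(log(nu / rho)) + log(m / (n - 1))
}

# independent exact Mann-Whitney oracle: enumerate every assignment of the
# pooled midranks to the first group, count as-extreme rank sums
mw_exact_oracle <- function(x, y, alternative) {
  n1 <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + length(y) + 1) / 2
  sets <- combn(n1 + length(y), n1)
  Ws <- apply(sets, 2, function(id) sum(r[id]))
  eps <- 1e-9
  switch(alternative,
         greater = mean(Ws >= W - eps),
         less = mean(Ws <= W + eps),
         two.sided = mean(abs(Ws - mu) >= abs(W - mu) - eps))
}

# adjusted Rand index (cross-checked against mclust in test-cluster.R)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
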