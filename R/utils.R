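# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared Euclidean cross-distances between two point sets
#'
#' Computed blockwise with BLAS (`tcrossprod`) so that k-NN queries over a few
#' thousand points stay fast without compiled code. Small negative values from
#' floating cancellation are clamped at zero.
#'
#' @param x,y numeric matrices with the same number of columns (points in rows).
#' @return matrix of squared distances, `nrow(x)` by `nrow(y)`.
#' @noRd
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

#' k nearest neighbor distances of query points within a reference set
#'
#' Thin wrapper over the compiled linear-scan search. Distance ties are
#' broken by the smaller reference index, so results are deterministic.
#'
#' @param query,ref point matrices (rows = points, same ncol).
#' @param k neighbor order.
#' @param exclude_self if TRUE, `query` and `ref` are the same set and each
#'   point's zero self-distance is removed before ranking.
#' @return list with `dist` (n x k matrix of distances, increasing in k) and
#'   `index` (n x k matrix of reference row indices).
#' @noRd
knn_lookup <- function(query, ref, k, exclude_self = FALSE) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  storage.mode(query) <- "double"; storage.mode(ref) <- "double"
  avail <- nrow(ref) - as.integer(exclude_self)
  if (k > avail) stop("k = ", k, " exceeds available neighbors (", avail, ")")
  .cpp_knn(query, ref, as.integer(k), isTRUE(exclude_self))
}

#' Validate a probability vector
#' @noRd
check_props <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(what, " must be nonnegative and sum to 1 (got sum = ", sum(p), ")")
  invisible(p)
}

#' Deterministic RNG scope
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state, so
#' seeded generators do not perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
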