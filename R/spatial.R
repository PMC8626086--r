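#' Validate an annotated 2-D cell map
#'
#' Expected columns: `x_um`, `y_um` (micrometer centroid coordinates),
#' `label` (categorical; for the two-marker analysis these are the
#' single-positive annotations, double-positive cells having been excluded
#' upstream), and optionally `section_id` (neighborhoods never cross
#' sections; defaults to a single section).
#'
#' @param df a data.frame (e.g. read from CSV with header
#'   `x_um,y_um,label[,section_id]`).
#' @return the validated data.frame of class `spatial_point_set`.
#' @export
as_spatial_point_set <- function(df) {
  need <- c("x_um", "y_um", "label")
  if (!all(need %in% colnames(df)))
    stop("spatial point set needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("coordinates must be finite")
  if (is.null(df$section_id)) df$section_id <- 1L
  df$label <- factor(df$label)
  class(df) <- unique(c("spatial_point_set", class(df)))
  df
}

# row-wise cumulative sums via a triangular matrix multiply (fast for the
# small neighborhood range)
row_cumsum <- function(m) {
  k <- ncol(m)
  tri <- matrix(0, k, k); tri[upper.tri(tri, diag = TRUE)] <- 1
  m %*% tri
}

# neighbor label matrix (centers x n_max) per section, pooled; ties in
# distance broken by point index
neighbor_labels <- function(s, n_max) {
  sections <- split(seq_len(nrow(s)), s$section_id)
  short <- vapply(sections, function(i) length(i) <= n_max, logical(1))
  if (any(short))
    stop("every section must contain more than n_max points; offending: ",
         paste(names(sections)[short], collapse = ", "))
  idx_out <- matrix(NA_integer_, nrow(s), n_max)
  for (i in sections) {
    pts <- cbind(s$x_um[i], s$y_um[i])
    nn <- knn_lookup(pts, pts, n_max, exclude_self = TRUE)$index
    idx_out[i, ] <- matrix(i[nn], length(i), n_max)
  }
  idx_out
}

#' Neighborhood label composition around every cell
#'
#' For each center cell and each neighborhood size `n` in
#' `[n_min, n_max]`, finds the `n` nearest other annotated cells of the same
#' section (Euclidean distance, self excluded, distance ties broken by point
#' index) and records the proportion of each target label among them. Curves
#' are aggregated across centers, pooling centers across sections; the SEM
#' treats centers as the independent unit. The random expectation for target
#' label `L` around a given center is `(count of L in its section, minus one
#' if the center is itself L) / (section size - 1)`, averaged over the centers
#' of each center-label group.
#'
#' @param s a `spatial_point_set` (see [as_spatial_point_set()]).
#' @param n_min,n_max neighborhood size range (every section must have more
#'   than `n_max` points).
#' @return list of class `neighborhood_curve`: `curve` (data.frame:
#'   `center_label`, `target_label`, `n`, `mean`, `sem`, `expected`), `raw`
#'   (array centers x sizes x target labels of per-center proportions),
#'   `center_label`, `n_range`.
#' @export
neighborhood_composition <- function(s, n_min = 1L, n_max = 40L) {
  s <- as_spatial_point_set(s)
  stopifnot(n_min >= 1, n_min <= n_max)
  labs <- levels(s$label)
  nn_idx <- neighbor_labels(s, n_max)
  n_range <- n_min:n_max
  raw <- array(NA_real_, c(nrow(s), length(n_range), length(labs)),
               dimnames = list(NULL, n_range, labs))
  for (L in labs) {
    hit <- matrix(s$label[nn_idx] == L, nrow(s), n_max)
    prop <- sweep(row_cumsum(hit), 2, seq_len(n_max), "/")
    raw[, , L] <- prop[, n_range, drop = FALSE]
  }
  # per-center random expectation by section
  sec_size <- ave(seq_len(nrow(s)), s$section_id, FUN = length)
  exp_center <- sapply(labs, function(L) {
    cnt <- ave(as.numeric(s$label == L), s$section_id, FUN = sum)
    (cnt - (s$label == L)) / (sec_size - 1)
  })
  curve <- do.call(rbind, lapply(labs, function(cl) {
    centers <- which(s$label == cl)
    do.call(rbind, lapply(labs, function(tl) {
      x <- matrix(raw[centers, , tl, drop = FALSE], nrow = length(centers))
      data.frame(center_label = cl, target_label = tl, n = n_range,
                 mean = colMeans(x),
                 sem = apply(x, 2, sd) / sqrt(length(centers)),
                 expected = mean(exp_center[centers, tl]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(curve = curve, raw = raw,
                 center_label = as.character(s$label), n_range = n_range),
            class = "neighborhood_curve")
}

#' Random-labeling expectation of neighborhood composition
#'
#' The proportion of each label expected around a center if labels were
#' assigned at random to the observed positions: for target label `L`,
#' `(count(L) - [center is L]) / (N - 1)` within the center's section,
#' averaged over centers. Independent of the coordinates by construction.
#'
#' @param s a `spatial_point_set`.
#' @param center_label restrict the averaging to centers with this label
#'   (`NULL` averages over all centers).
#' @return named numeric vector of expected proportions per target label.
#' @export
expected_random_proportion <- function(s, center_label = NULL) {
  s <- as_spatial_point_set(s)
  labs <- levels(s$label)
  centers <- if (is.null(center_label)) seq_len(nrow(s)) else
    which(s$label == center_label)
  if (!length(centers)) stop("no centers with label ", center_label)
  sec_size <- ave(seq_len(nrow(s)), s$section_id, FUN = length)
  vapply(setNames(labs, labs), function(L) {
    cnt <- ave(as.numeric(s$label == L), s$section_id, FUN = sum)
    mean(((cnt - (s$label == L)) / (sec_size - 1))[centers])
  }, numeric(1))
}

#' One-tailed Mann-Whitney test of same-label neighborhood enrichment
#'
#' For each target label and each neighborhood size `n`, compares the
#' per-center proportions of that label between centers that carry the label
#' themselves and centers that do not, with the one-tailed alternative that
#' the proportion is greater around same-label centers (spatial aggregation
#' of like cells). Uses [rank_sum_test()]: exact enumeration when both center
#' groups have at most 8 members, tie-corrected normal approximation with
#' continuity correction otherwise. The summary is the maximum p over the
#' whole size range, i.e. significance "across the complete range" means
#' `max_p` below the chosen level; no further multiplicity correction is
#' applied.
#'
#' @param curve a `neighborhood_curve` from [neighborhood_composition()].
#' @param alternative `"greater"` (default: same-label enrichment) or
#'   `"less"`.
#' @return list with `table` (data.frame: `target_label`, `n`, `U`, `p`) and
#'   `max_p`.
#' @export
clustering_test <- function(curve, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(curve, "neighborhood_curve"))
  labs <- dimnames(curve$raw)[[3]]
  out <- do.call(rbind, lapply(labs, function(L) {
    same <- curve$center_label == L
    if (!any(same) || all(same))
      stop("both center groups must be non-empty for target label ", L)
    do.call(rbind, lapply(seq_along(curve$n_range), function(j) {
      ts <- rank_sum_test(curve$raw[same, j, L], curve$raw[!same, j, L],
                          alternative = alternative)
      data.frame(target_label = L, n = curve$n_range[j],
                 U = ts$statistic, p = ts$p_value,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
  list(table = out, max_p = max(out$p))
}

#' Label-permutation null for neighborhood same-label enrichment
#'
#' Complements the parametric test with a permutation baseline: labels are
#' shuffled over the fixed coordinates (within section), and the observed mean
#' same-label proportion at each neighborhood size is compared to its
#' permutation distribution. One-sided add-one p-values:
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param s a `spatial_point_set`.
#' @param n_sizes integer vector of neighborhood sizes to evaluate.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame with `n`, `observed` and `p`.
#' @export
permutation_null <- function(s, n_sizes = 1:40, n_perm = 999, seed = 1L) {
  s <- as_spatial_point_set(s)
  if (n_perm < 100) stop("n_perm must be >= 100")
  n_max <- max(n_sizes)
  nn_idx <- neighbor_labels(s, n_max)
  sections <- split(seq_len(nrow(s)), s$section_id)
  stat <- function(lab) {
    same <- matrix(lab[nn_idx] == lab[row(nn_idx)], nrow(s), n_max)
    colMeans(sweep(row_cumsum(same), 2, seq_len(n_max), "/"))[n_sizes]
  }
  obs <- stat(s$label)
  with_seed(seed, {
    exceed <- numeric(length(n_sizes))
    lab <- as.character(s$label)
    for (b in seq_len(n_perm)) {
      perm <- lab
      for (i in sections) perm[i] <- perm[sample(i)]
      exceed <- exceed + (stat(perm) >= obs - 1e-12)
    }
    data.frame(n = n_sizes, observed = obs,
               p = (1 + exceed) / (1 + n_perm), row.names = NULL)
  })
}
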