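#' Canberra distances between samples
#'
#' The Canberra metric sums scaled absolute coordinate differences,
#' `d(x, y) = sum_g |x_g - y_g| / (|x_g| + |y_g|)`, with coordinates that
#' are zero in both points contributing nothing. Operates on a
#' samples-in-columns expression matrix; distances are between samples.
#'
#' @param values Genes x samples matrix of nonnegative values, or a
#'   `count_matrix` (clustered on `log2(normalized + 1)` of its
#'   endogenous probes).
#' @return A `dist` object over samples.
#' @export
canberra_distances <- function(values) {
  if (inherits(values, "count_matrix")) {
    ids <- matrix_rows(values, "Endogenous")
    values <- log2(values$values[ids, , drop = FALSE] + 1)
  }
  if (any(values < 0)) stop("Canberra distances need nonnegative values")
  stats::dist(t(values), method = "canberra")
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion in its
#' squared-dissimilarity (ward.D2) form.
#'
#' @param d A `dist` object.
#' @return An `hclust` tree with monotone nondecreasing merge heights.
#' @export
ward_linkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(d, method = "ward.D2")
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbor distances of `m` sampled real points (to
#' their nearest other real point, `w`) with those of `m` uniform points
#' drawn in the per-dimension bounding box (to their nearest real point,
#' `u`): `H = sum(u) / (sum(u) + sum(w))`. Uniformly scattered data give
#' H near 0.5; strongly clustered data push H toward 1. If all points
#' coincide, every `w` is zero and H is 1 by convention (flagged via the
#' `degenerate` attribute).
#'
#' @param data Samples x features numeric matrix (>= 10 samples).
#' @param m_fraction Fraction of points sampled (default 0.1, with a
#'   floor of 10 points, capped at n - 1).
#' @param seed Integer seed for the point samples.
#' @return H in `[0, 1]`.
#' @export
hopkins <- function(data, m_fraction = 0.1, seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 10L) stop("Hopkins statistic needs at least 10 samples")
  m <- min(max(ceiling(m_fraction * n), 10L), n - 1L)
  set.seed(seed)
  idx <- sample.int(n, m)
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  uniform <- sapply(seq_len(ncol(data)), function(j)
    stats::runif(m, lo[j], hi[j]))
  uniform <- matrix(uniform, nrow = m)

  nn_dist <- function(points, ref) {
    # nearest neighbor in ref for each row of points
    apply(points, 1, function(p) {
      d2 <- colSums((t(ref) - p)^2)
      sqrt(min(d2))
    })
  }
  w <- vapply(idx, function(i) {
    d2 <- colSums((t(data[-i, , drop = FALSE]) - data[i, ])^2)
    sqrt(min(d2))
  }, 1.0)
  u <- nn_dist(uniform, data)
  if (sum(u) + sum(w) == 0)
    return(structure(1, degenerate = TRUE))
  structure(sum(u) / (sum(u) + sum(w)),
            degenerate = all(w == 0))
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair of samples
#' first joins); a measure of how faithfully the dendrogram summarizes
#' the distance structure. An ultrametric input reproduces itself
#' exactly, giving r = 1.
#'
#' @param d The `dist` the tree was built from.
#' @param tree The `hclust` tree.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(d, tree) {
  stopifnot(inherits(d, "dist"), inherits(tree, "hclust"))
  if (attr(d, "Size") < 3L)
    stop("cophenetic correlation is undefined for fewer than 3 samples")
  stats::cor(as.vector(d), as.vector(stats::cophenetic(tree)))
}

#' c-index across cluster numbers and the optimal k
#'
#' For each k the tree is cut into k clusters; with `N_w` within-cluster
#' pairs, `S_w` the sum of their distances, and `S_min` / `S_max` the
#' sums of the `N_w` smallest / largest distances overall,
#' `C_k = (S_w - S_min) / (S_max - S_min)`, in `[0, 1]` and small for
#' compact, well-separated partitions. The optimal k minimizes `C_k`
#' (ties resolved toward the smallest k).
#'
#' @param d A `dist` object.
#' @param tree The `hclust` tree built from `d`.
#' @param k_range Candidate cluster numbers (default `2:10`, clipped to
#'   `n - 1`).
#' @return A list: `c_index_by_k` (named vector) and `optimal_k`.
#' @export
c_index_optimal_k <- function(d, tree, k_range = 2:10) {
  n <- attr(d, "Size")
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("empty k_range")
  dv <- sort(as.vector(d))
  if (max(dv) == min(dv) && max(dv) == 0)
    stop("c-index undefined: all points identical")
  cum <- cumsum(dv)
  cum_rev <- cumsum(rev(dv))
  cidx <- vapply(k_range, function(k) {
    cl <- stats::cutree(tree, k = k)
    same <- as.vector(stats::dist(cbind(cl))) == 0
    n_w <- sum(same)
    if (n_w == 0L) return(NA_real_)
    s_w <- sum(as.vector(d)[same])
    s_min <- cum[n_w]
    s_max <- cum_rev[n_w]
    if (s_max == s_min) return(0)
    (s_w - s_min) / (s_max - s_min)
  }, 1.0)
  names(cidx) <- k_range
  ok <- which(!is.na(cidx))
  optimal <- k_range[ok[which.min(cidx[ok])]]
  list(c_index_by_k = cidx, optimal_k = optimal)
}

#' Full clustering diagnostics for a normalized matrix
#'
#' Canberra/Ward hierarchical clustering of samples on
#' `log2(normalized + 1)` expression, plus the three validation
#' statistics: Hopkins clustering tendency, cophenetic correlation, and
#' the c-index curve with its optimal cluster number.
#'
#' @param norm A `content_normalized` [count_matrix()] or a genes x
#'   samples matrix.
#' @param k_range Candidate cluster numbers.
#' @param seed Seed for the Hopkins point samples.
#' @return A `cluster_diagnostics` list: `dist`, `tree`, `hopkins_H`,
#'   `cophenetic_r`, `c_index_by_k`, `optimal_k`.
#' @export
cluster_diagnostics <- function(norm, k_range = 2:10, seed = 1L) {
  if (inherits(norm, "count_matrix")) {
    ids <- matrix_rows(norm, "Endogenous")
    values <- log2(norm$values[ids, , drop = FALSE] + 1)
  } else {
    values <- norm
  }
  d <- canberra_distances(values)
  tree <- ward_linkage(d)
  h <- hopkins(t(values), seed = seed)
  r <- cophenetic_correlation(d, tree)
  ci <- c_index_optimal_k(d, tree, k_range)
  structure(list(dist = d, tree = tree, hopkins_H = as.numeric(h),
                 cophenetic_r = r, c_index_by_k = ci$c_index_by_k,
                 optimal_k = ci$optimal_k),
            class = "cluster_diagnostics")
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat(sprintf(
    "cluster diagnostics: Hopkins H = %.3f, cophenetic r = %.3f, optimal k = %d (c-index %.3f)\n",
    x$hopkins_H, x$cophenetic_r, x$optimal_k,
    x$c_index_by_k[as.character(x$optimal_k)]))
  invisible(x)
}
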