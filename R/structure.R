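#' Inter-group average-linkage Euclidean distance
#'
#' The ESC-proximity statistic: the mean of all `|A| * |B|` pairwise Euclidean
#' distances between members of two sample groups, computed over a chosen
#' feature set (typically the differential signature), with standard error
#' defined as the standard deviation of the pairwise distances divided by the
#' square root of the number of pairs. With a single pair the standard error
#' is reported as 0 and flagged.
#'
#' @param mat An [expression_matrix()].
#' @param groups A [sample_groups()].
#' @param a,b Group labels.
#' @param features Optional feature ids to restrict the distance computation
#'   to (default: all features in `mat`).
#' @return List of class `GroupDistance` with elements `group_a`, `group_b`,
#'   `mean_distance`, `se`, `n_pairs`, `single_pair`.
#' @export
group_distance <- function(mat, groups, a, b, features = NULL) {
  sa <- intersect(sample_ids(mat), group_samples(groups, a))
  sb <- intersect(sample_ids(mat), group_samples(groups, b))
  if (length(sa) == 0L || length(sb) == 0L)
    stop("both groups must be non-empty in the matrix")
  x <- mat$values
  if (!is.null(features)) {
    features <- intersect(features, rownames(x))
    if (length(features) == 0L) stop("feature set is empty after intersection")
    x <- x[features, , drop = FALSE]
  }
  dists <- numeric(length(sa) * length(sb))
  k <- 0L
  for (i in sa) for (j in sb) {
    k <- k + 1L
    dists[k] <- sqrt(sum((x[, i] - x[, j])^2))
  }
  n_pairs <- length(dists)
  se <- if (n_pairs > 1L) stats::sd(dists) / sqrt(n_pairs) else 0
  structure(list(group_a = a, group_b = b, mean_distance = mean(dists),
                 se = se, n_pairs = n_pairs, single_pair = n_pairs == 1L),
            class = "GroupDistance")
}

#' Principal component embedding of samples
#'
#' Samples as points from the singular decomposition of the feature-centered
#' matrix. Axis signs are arbitrary.
#'
#' @param mat An [expression_matrix()].
#' @param k Number of components (truncated to the matrix rank with a warning
#'   if too large).
#' @return List of class `Embedding` with `coords` (samples x k) and
#'   `var_explained` (variance per retained axis, nonincreasing).
#' @export
pca_embedding <- function(mat, k = 2) {
  if (ncol(mat$values) < 2L) stop("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(mat$values), center = TRUE, scale. = FALSE)
  r <- sum(pc$sdev > 1e-12 * pc$sdev[1L])
  if (k > r) {
    warning("k exceeds rank; truncated to ", r)
    k <- r
  }
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = pc$sdev[seq_len(k)]^2,
                 total_variance = sum(pc$sdev^2)),
            class = "Embedding")
}

#' Classical multidimensional scaling of samples
#'
#' Double-centering of the squared Euclidean sample-distance matrix followed
#' by eigendecomposition (Torgerson scaling); reproduces PCA scores up to
#' rotation/sign for Euclidean input.
#'
#' @inheritParams pca_embedding
#' @return List of class `Embedding` with `coords` and `eig`.
#' @export
mds_embedding <- function(mat, k = 2) {
  if (ncol(mat$values) < 2L) stop("MDS needs >= 2 samples")
  d <- stats::dist(t(mat$values))
  kk <- min(k, ncol(mat$values) - 1L)
  if (kk < k) warning("k exceeds n - 1; truncated to ", kk)
  fit <- stats::cmdscale(d, k = kk, eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L,
                                             dimnames = list(labels(d), NULL))
  structure(list(coords = coords, eig = fit$eig), class = "Embedding")
}

#' Average-linkage (UPGMA) hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples with the Euclidean metric and
#' average linkage; merges and heights follow the standard deterministic
#' agglomeration.
#'
#' @param mat An [expression_matrix()].
#' @return An object of class `hclust` over the sample ids.
#' @export
average_linkage_tree <- function(mat) {
  if (ncol(mat$values) < 2L) stop("clustering needs >= 2 samples")
  stats::hclust(stats::dist(t(mat$values)), method = "average")
}

#' Members of each branch at the first split of a dendrogram
#'
#' Convenience for tree-topology assertions: labels in the two subtrees
#' created by the final (root) merge.
#'
#' @param tree An `hclust` object.
#' @return List of two character vectors.
#' @export
root_split <- function(tree) {
  n <- length(tree$labels)
  members <- function(idx) {
    if (idx < 0) return(tree$labels[-idx])
    unlist(lapply(tree$merge[idx, ], members))
  }
  top <- tree$merge[n - 1L, ]
  list(sort(members(top[1L])), sort(members(top[2L])))
}
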