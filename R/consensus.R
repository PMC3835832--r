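#' Hard cluster assignment from an NMF W factor
#'
#' Each sample (row of `W`) is assigned to the component carrying its
#' largest weight; ties go to the lowest component index.
#'
#' @param W non-negative sample x rank matrix.
#' @return Integer vector of labels in `1..ncol(W)`, named by sample.
#' @export
assign_clusters <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be non-negative")
  zero <- rowSums(W) == 0
  if (any(zero))
    stop("all-zero row(s) in W (uninformative sample): ",
         paste(head(which(zero)), collapse = ", "))
  labels <- max.col(W, ties.method = "first")
  names(labels) <- rownames(W)
  labels
}

#' Co-clustering consensus matrix over multiple runs
#'
#' For `T` independent labelings of the same samples, entry `(i, j)` is the
#' fraction of runs in which samples `i` and `j` received the same label.
#' Because co-membership ignores label identities, the matrix is invariant
#' to the component-permutation ambiguity of individual NMF runs.
#'
#' @param labelings list of integer label vectors over the same samples.
#' @return Symmetric sample x sample matrix with unit diagonal and entries
#'   `count / T`; the number of runs is attached as attribute `"runs"`.
#' @export
consensus_matrix <- function(labelings) {
  if (length(labelings) == 0L) stop("no labelings given")
  n <- length(labelings[[1L]])
  if (!all(lengths(labelings) == n))
    stop("all labelings must cover the same samples")
  C <- matrix(0, n, n)
  for (l in labelings) C <- C + outer(l, l, "==")
  C <- C / length(labelings)
  dimnames(C) <- list(names(labelings[[1L]]), names(labelings[[1L]]))
  attr(C, "runs") <- length(labelings)
  C
}

#' Cut a consensus matrix into k clusters
#'
#' Agglomerative hierarchical clustering on the dissimilarity `1 - C`
#' (average linkage by default), cut at `k` groups.  Labels are renumbered
#' `1..k` by decreasing cluster size (ties by first appearance), so cluster
#' 1 is always the largest.
#'
#' @param C consensus matrix from [consensus_matrix].
#' @param k number of clusters, `1 <= k <= nrow(C)`.
#' @param method linkage passed to [stats::hclust] (default `"average"`;
#'   the consensus matrix is already a robust similarity, so the choice of
#'   linkage has little effect).
#' @return Integer label vector, named by sample.
#' @export
cut_clusters <- function(C, k, method = "average") {
  C <- as.matrix(C)
  if (k > nrow(C)) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be at least 1")
  if (k == nrow(C)) {
    labels <- seq_len(nrow(C))
  } else {
    hc <- hclust(as.dist(1 - C), method = method)
    labels <- cutree(hc, k = k)
  }
  relabel_by_size(labels)
}

#' Renumber cluster labels by decreasing cluster size
#'
#' @param labels integer label vector.
#' @return Labels mapped so cluster 1 is the largest; ties keep first-seen
#'   order.  Names are preserved.
#' @export
relabel_by_size <- function(labels) {
  ids <- unique(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  ord <- ids[order(-sizes, match(ids, ids))]
  out <- match(labels, ord)
  names(out) <- names(labels)
  out
}

#' Stability of the consensus matrix versus the number of runs
#'
#' For each prefix size `T` in `grid`, the root-mean-square difference of
#' off-diagonal entries between the consensus matrix of the first `T` runs
#' and a reference: the all-runs consensus matrix (default), or the
#' consensus matrix at the previous grid point (`reference =
#' "consecutive"`).  Small values mean additional runs would no longer
#' change the similarity structure appreciably.
#'
#' @param labelings list of label vectors (one per run, in run order).
#' @param grid increasing integer vector of prefix sizes, each at most
#'   `length(labelings)`.
#' @param reference `"all"` or `"consecutive"`.
#' @return data frame with columns `T` and `rms`.
#' @export
stability_curve <- function(labelings, grid = seq_along(labelings),
                            reference = c("all", "consecutive")) {
  reference <- match.arg(reference)
  if (any(grid > length(labelings)))
    stop("grid values exceed the number of runs")
  if (any(grid < 1)) stop("grid values must be positive")
  off <- function(M) M[lower.tri(M) | upper.tri(M)]
  rms <- numeric(length(grid))
  C_all <- consensus_matrix(labelings)
  prev <- NULL
  for (i in seq_along(grid)) {
    C_T <- consensus_matrix(labelings[seq_len(grid[i])])
    ref <- if (reference == "all") C_all else if (is.null(prev)) C_T else prev
    rms[i] <- sqrt(mean((off(C_T) - off(ref))^2))
    prev <- C_T
  }
  data.frame(T = grid, rms = rms)
}

#' Consensus clustering over seeded NMF restarts
#'
#' Runs `T` factorizations of the (compacted) matrix with consecutive seeds
#' `base_seed .. base_seed + T - 1`, assigns each sample to its dominant
#' component per run, aggregates the co-clustering fractions into a
#' consensus matrix and cuts it hierarchically at `k` groups.  Fully
#' deterministic given `(V, k, T, base_seed)`.
#'
#' @param V non-negative matrix, [feature_matrix] or [compact_matrix].
#' @param k rank / number of clusters.
#' @param T number of restarts (the stability curve flattens by a few
#'   hundred runs on real data; use [stability_curve] to check).
#' @param base_seed first seed.
#' @param max_iter,tol passed to [nmf_factorize].
#' @param linkage linkage method for [cut_clusters].
#' @return List with `consensus` (matrix), `labels` (integer vector),
#'   `runs` (per-run data frame: seed, iterations, divergence, converged),
#'   `labelings` (per-run label list), `k`.
#' @export
run_consensus <- function(V, k, T = 300L, base_seed = 1L,
                          max_iter = 2000L, tol = 1e-6,
                          linkage = "average") {
  stopifnot(T >= 1)
  seeds <- base_seed + seq_len(T) - 1L
  fits <- lapply(seeds, function(s)
    nmf_factorize(V, k, seed = s, max_iter = max_iter, tol = tol))
  labelings <- lapply(fits, function(f) assign_clusters(f$W))
  C <- consensus_matrix(labelings)
  labels <- cut_clusters(C, k, method = linkage)
  runs <- data.frame(seed = seeds,
                     iterations = vapply(fits, `[[`, integer(1), "iterations"),
                     divergence = vapply(fits, `[[`, numeric(1), "divergence"),
                     converged = vapply(fits, `[[`, logical(1), "converged"))
  list(consensus = C, labels = labels, runs = runs,
       labelings = labelings, k = as.integer(k))
}
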