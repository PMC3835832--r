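.check_labels <- function(C, labels) {
  C <- as.matrix(C)
  if (length(labels) != nrow(C))
    stop("clustering does not match the consensus matrix samples")
  k <- max(labels)
  missing <- setdiff(seq_len(k), unique(labels))
  if (length(missing))
    stop("empty cluster id(s): ", paste(missing, collapse = ", "))
  C
}

#' Intra-cluster similarity S(k)
#'
#' For each cluster the average consensus value over its unordered sample
#' pairs — the mean probability that two of its members are co-clustered
#' across restarts — aggregated over clusters by the mean (default),
#' median or maximum.  The maximum aggregator scores the single most
#' robust subgroup, useful when one biologically coherent cluster is
#' embedded in an otherwise weak partition; note it ignores inter-cluster
#' similarity, and singleton clusters (similarity 1 by the self-pairing
#' convention) can inflate it, hence `exclude_singletons`.
#'
#' @param C consensus matrix.
#' @param labels integer cluster labels (ids `1..k`, all nonempty).
#' @param aggregator `"mean"`, `"median"` or `"max"`.
#' @param exclude_singletons drop size-1 clusters before aggregating.
#' @return List with `value` (the aggregate), `per_cluster` (named vector
#'   of per-cluster averages) and `sizes`.
#' @export
intra_cluster_similarity <- function(C, labels,
                                     aggregator = c("mean", "median", "max"),
                                     exclude_singletons = FALSE) {
  aggregator <- match.arg(aggregator)
  C <- .check_labels(C, labels)
  ids <- sort(unique(labels))
  per <- vapply(ids, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(1)   # an element always co-clusters with itself
    sub <- C[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  sizes <- vapply(ids, function(cl) sum(labels == cl), integer(1))
  names(per) <- names(sizes) <- ids
  keep <- if (exclude_singletons) sizes > 1L else rep(TRUE, length(ids))
  if (!any(keep)) stop("no clusters left after excluding singletons")
  agg <- switch(aggregator, mean = mean(per[keep]),
                median = stats::median(per[keep]), max = max(per[keep]))
  list(value = agg, per_cluster = per, sizes = sizes)
}

#' Cophenetic correlation of the consensus dendrogram
#'
#' Pearson correlation between the condensed dissimilarities `1 - C` and
#' the cophenetic distances of the hierarchical tree built on them; values
#' near 1 indicate the tree (and hence the chosen rank) represents the
#' consensus structure faithfully.
#'
#' @param C consensus matrix of at least 3 samples.
#' @param method linkage for [stats::hclust] (default `"average"`).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(C, method = "average") {
  C <- as.matrix(C)
  if (nrow(C) < 3L) stop("need at least 3 samples")
  d <- as.dist(1 - C)
  hc <- hclust(d, method = method)
  cp <- cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cp) == 0)
    stop("degenerate (constant) dissimilarities; cophenetic correlation undefined")
  cor(d, cp)
}

#' Mean silhouette width on the consensus dissimilarity
#'
#' Standard silhouette computed on `1 - C`, averaged over samples;
#' singleton-cluster samples have silhouette 0.
#'
#' @param C consensus matrix.
#' @param labels integer cluster labels with `k >= 2` nonempty clusters.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(C, labels) {
  C <- .check_labels(C, labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(as.integer(labels), dist = as.dist(1 - C))
  mean(sil[, "sil_width"])
}

#' Rank-selection report over consensus runs
#'
#' For each candidate rank, runs the full consensus procedure and
#' tabulates the intra-cluster similarity family (mean/median/max), the
#' cophenetic correlation and the mean silhouette, together with cluster
#' sizes.  The recommended rank is the argmax of the mean intra-cluster
#' similarity (ties to the smaller rank) — a reporting default only: the
#' measures capture different aspects and are meant to be weighed
#' together.  The cophenetic coefficient is also available as the
#' criterion, but it saturates near 1 whenever the consensus matrix is
#' close to block-diagonal at several ranks, where S(k) still
#' discriminates.
#'
#' @param V non-negative matrix, [feature_matrix] or [compact_matrix].
#' @param ranks integer vector of candidate ranks (each in
#'   `[2, samples - 1]`).
#' @param T restarts per rank.
#' @param base_seed first seed (shared across ranks).
#' @param criterion measure whose argmax is reported as the recommended
#'   rank: `"S_mean"` (default) or `"cophenetic"`.
#' @param ... passed to [run_consensus] (`max_iter`, `tol`, `linkage`).
#' @return Object of class `"rank_report"`: list with `table` (one row per
#'   rank), `recommended` (rank), `labels` (per-rank label vectors),
#'   `consensus` (per-rank consensus matrices), `details` (per-rank
#'   per-cluster similarities and sizes).
#' @export
rank_report <- function(V, ranks, T = 300L, base_seed = 1L,
                        criterion = c("S_mean", "cophenetic"), ...) {
  criterion <- match.arg(criterion)
  n <- nrow(.values_of(V))
  ranks <- sort(unique(as.integer(ranks)))
  if (any(ranks < 2L) || any(ranks > n - 1L))
    stop("ranks must lie in [2, samples - 1]")
  rows <- vector("list", length(ranks))
  labels <- consensus <- details <- setNames(vector("list", length(ranks)),
                                             ranks)
  for (i in seq_along(ranks)) {
    k <- ranks[i]
    cr <- run_consensus(V, k, T = T, base_seed = base_seed, ...)
    s_mean <- intra_cluster_similarity(cr$consensus, cr$labels, "mean")
    s_med <- intra_cluster_similarity(cr$consensus, cr$labels, "median")
    s_max <- intra_cluster_similarity(cr$consensus, cr$labels, "max")
    coph <- tryCatch(cophenetic_coefficient(cr$consensus),
                     error = function(e) NA_real_)
    sil <- tryCatch(silhouette_mean(cr$consensus, cr$labels),
                    error = function(e) NA_real_)
    rows[[i]] <- data.frame(rank = k, S_mean = s_mean$value,
                            S_median = s_med$value, S_max = s_max$value,
                            cophenetic = coph, silhouette = sil,
                            n_clusters = length(unique(cr$labels)))
    labels[[i]] <- cr$labels
    consensus[[i]] <- cr$consensus
    details[[i]] <- list(per_cluster = s_mean$per_cluster,
                         sizes = s_mean$sizes)
  }
  tab <- do.call(rbind, rows)
  crit <- tab[[criterion]]
  recommended <- if (all(is.na(crit))) ranks[1L] else
    tab$rank[which.max(crit)]   # which.max takes the first, i.e. smallest rank
  structure(list(table = tab, recommended = recommended,
                 criterion = criterion, labels = labels,
                 consensus = consensus, details = details,
                 T = as.integer(T), base_seed = as.integer(base_seed)),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, digits = 3, ...) {
  cat("Rank-selection report (", x$T, " restarts per rank)\n", sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat("Recommended rank (", x$criterion, " argmax): ", x$recommended,
      "\n", sep = "")
  invisible(x)
}

#' Exact test of independence for an r x c contingency table
#'
#' Conditional on the observed margins, enumerates every non-negative
#' integer table with those margins, computes each table's multivariate
#' hypergeometric probability, and sums the probabilities of all tables no
#' more probable than the observed one (the probability-ordering two-sided
#' convention).  Intended for associating cluster labels with external
#' categorical annotations such as molecular subtypes.
#'
#' @param tab r x c matrix of non-negative integer counts, `r, c >= 2`.
#' @param max_tables enumeration guard: error if more than this many
#'   candidate tables would be visited (default 1e6); larger problems need
#'   a Monte-Carlo approximation, which this function does not provide.
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(13, 15, 7, 14, 7, 1), 3, 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab, max_tables = 1e6) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2")
  N <- sum(tab)
  if (N == 0) stop("table is empty")
  rs <- rowSums(tab); cs <- colSums(tab)
  log_const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logp_obs <- log_const - sum(lfactorial(tab))
  r <- nrow(tab); cc <- ncol(tab)
  tol <- 1e-7
  env <- new.env()
  env$p <- 0
  env$count <- 0L
  cell <- matrix(0L, r, cc)
  recurse <- function(i, j, row_left, col_left) {
    env$count <- env$count + 1L
    if (env$count > max_tables)
      stop("more than ", max_tables, " candidate tables; enumeration ",
           "infeasible - use a Monte-Carlo approximation instead")
    if (i == r) {
      # last row is determined by the column remainders
      if (any(col_left < 0)) return(invisible())
      lp <- log_const - sum(lfactorial(cell[seq_len(r - 1L), , drop = FALSE])) -
        sum(lfactorial(col_left))
      if (lp <= logp_obs + tol) env$p <- env$p + exp(lp)
      return(invisible())
    }
    if (j == cc) {
      # last cell of the row is the row remainder
      if (row_left > col_left[cc]) return(invisible())
      cell[i, cc] <<- row_left
      recurse(i + 1L, 1L, rs[i + 1L],
              col_left - c(rep(0L, cc - 1L), row_left))
      return(invisible())
    }
    for (v in 0:min(row_left, col_left[j])) {
      cell[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
  }
  recurse(1L, 1L, rs[1L], cs)
  min(1, env$p)
}
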