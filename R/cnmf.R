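#' Consensus compact-NMF subgrouping of copy-number profiles
#'
#' The package's main fitting function.  Encodes copy-number calls as a
#' two-channel non-negative matrix (skipped when `x` already is one),
#' merges similar columns into bins by Hamming distance under a genomic
#' locality window, sums each bin into one column, and factorizes the
#' compacted matrix by KL-divergence NMF from `runs` seeded restarts.
#' Restart labelings are aggregated into a consensus matrix, which is cut
#' hierarchically into `k` subgroups.  Because binned columns are summed
#' (not dropped), the factorization minimizes the divergence to the full
#' encoded matrix, not to a submatrix of it.
#'
#' @param x a [cn_profiles], [feature_matrix], a synthetic cohort from
#'   [generate_cn], or a plain non-negative matrix of features.
#' @param k number of subgroups (factorization rank); use [rank_report]
#'   to choose it.
#' @param delta Hamming merging threshold; `"auto"` = 1% of the sample
#'   count ([default_delta]).
#' @param window locality window in probes (default 500), see
#'   [build_partition].
#' @param scheme encoding scheme for [encode_cn] when `x` holds raw calls.
#' @param runs number of seeded NMF restarts.
#' @param base_seed first restart seed.
#' @param max_iter,tol NMF convergence controls ([nmf_factorize]).
#' @param linkage linkage for the consensus cut ([cut_clusters]).
#' @return Object of class `"cnmf"` with components `labels` (subgroup per
#'   sample, numbered by decreasing size), `consensus`, `partition`,
#'   `compact`, `best` (lowest-divergence restart), `H_full` (expanded H
#'   over original features), `full_divergence`, `runs` (per-restart log)
#'   and `feature` (the encoded matrix).  Methods: `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' \donttest{
#' cohort <- generate_cn(synthetic_spec(seed = 42))
#' fit <- cnmf(cohort, k = 3, runs = 20)
#' fit
#' table(predict(fit), cohort$labels)
#' }
#' @export
cnmf <- function(x, k, delta = "auto", window = 500,
                 scheme = c("ordinal", "binary"),
                 runs = 50L, base_seed = 1L,
                 max_iter = 2000L, tol = 1e-6, linkage = "average") {
  cl <- match.call()
  scheme <- match.arg(scheme)
  if (inherits(x, "cn_synthetic")) x <- x$profiles
  F <- if (inherits(x, "cn_profiles")) encode_cn(x, scheme)
       else if (inherits(x, "feature_matrix")) x
       else feature_matrix(as.matrix(x), .fm_meta(as.matrix(x)))
  P <- build_partition(F, delta = delta, window = window)
  Vc <- compact_columns(F, P)
  cons <- run_consensus(Vc, k, T = runs, base_seed = base_seed,
                        max_iter = max_iter, tol = tol, linkage = linkage)
  best_seed <- cons$runs$seed[which.min(cons$runs$divergence)]
  best <- nmf_factorize(Vc, k, seed = best_seed, max_iter = max_iter,
                        tol = tol)
  H_full <- expand_h(best$H, P)
  colnames(H_full) <- colnames(F$values)
  structure(list(call = cl, labels = cons$labels, k = as.integer(k),
                 consensus = cons$consensus, runs = cons$runs,
                 partition = P, compact = Vc, feature = F,
                 best = best, H_full = H_full,
                 full_divergence = kl_divergence(F$values, best$W, H_full),
                 options = list(delta = P$delta, window = window,
                                scheme = scheme, runs = runs,
                                base_seed = base_seed, max_iter = max_iter,
                                tol = tol, linkage = linkage)),
            class = "cnmf")
}

#' @export
print.cnmf <- function(x, ...) {
  cat("Consensus compact-NMF fit\n")
  cat("  ", nrow(x$feature$values), " samples, ", ncol(x$feature$values),
      " features compacted to ", ncol(x$compact$values),
      " bins (delta = ", x$options$delta, ", window = ",
      format(x$options$window), ")\n", sep = "")
  cat("  rank k = ", x$k, ", ", x$options$runs, " restarts (seeds ",
      x$options$base_seed, "..",
      x$options$base_seed + x$options$runs - 1L, ")\n", sep = "")
  sizes <- table(x$labels)
  cat("  subgroup sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  best full-matrix divergence:",
      format(x$full_divergence, digits = 6), "\n")
  invisible(x)
}

#' @describeIn cnmf Quality summary: intra-cluster similarity family,
#'   cophenetic correlation, mean silhouette, subgroup sizes and restart
#'   divergence spread.
#' @param object,... method arguments.
#' @export
summary.cnmf <- function(object, ...) {
  s_mean <- intra_cluster_similarity(object$consensus, object$labels, "mean")
  out <- list(
    k = object$k,
    sizes = s_mean$sizes,
    per_cluster_similarity = s_mean$per_cluster,
    S_mean = s_mean$value,
    S_median = intra_cluster_similarity(object$consensus, object$labels,
                                        "median")$value,
    S_max = intra_cluster_similarity(object$consensus, object$labels,
                                     "max")$value,
    cophenetic = tryCatch(cophenetic_coefficient(object$consensus),
                          error = function(e) NA_real_),
    silhouette = tryCatch(silhouette_mean(object$consensus, object$labels),
                          error = function(e) NA_real_),
    divergence = summary(object$runs$divergence),
    full_divergence = object$full_divergence)
  class(out) <- "summary.cnmf"
  out
}

#' @export
print.summary.cnmf <- function(x, digits = 3, ...) {
  cat("Consensus compact-NMF: k =", x$k, "\n")
  cat("Subgroup sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("Per-subgroup consensus similarity:",
      paste(format(x$per_cluster_similarity, digits = digits),
            collapse = ", "), "\n")
  cat("S_mean = ", format(x$S_mean, digits = digits),
      ", S_median = ", format(x$S_median, digits = digits),
      ", S_max = ", format(x$S_max, digits = digits), "\n", sep = "")
  cat("Cophenetic correlation:", format(x$cophenetic, digits = digits), "\n")
  cat("Mean silhouette:", format(x$silhouette, digits = digits), "\n")
  cat("Restart divergence (on compacted matrix):\n")
  print(x$divergence, digits = digits)
  cat("Best full-matrix divergence:",
      format(x$full_divergence, digits = digits), "\n")
  invisible(x)
}

#' @describeIn cnmf Factor matrices of the best restart; with
#'   `expand = TRUE` (default) `H` is expanded to original feature columns.
#' @param expand return `H` over original features rather than bins.
#' @export
coef.cnmf <- function(object, expand = TRUE, ...) {
  list(W = object$best$W,
       H = if (expand) object$H_full else object$best$H)
}

#' @describeIn cnmf Model approximation `W %*% H` of the full encoded
#'   matrix.
#' @export
fitted.cnmf <- function(object, ...) {
  object$best$W %*% object$H_full
}

#' @describeIn cnmf Raw residuals `V - W %*% H` on the full encoded matrix.
#' @export
residuals.cnmf <- function(object, ...) {
  object$feature$values - fitted(object)
}

#' @describeIn cnmf Subgroup labels; for `newdata` (profiles or feature
#'   matrix of new samples over the same probes), new samples are folded in
#'   by optimizing their `W` rows against the fixed compact `H` and
#'   assigned to their dominant component.
#' @param newdata optional new samples to classify.
#' @param fold_iter multiplicative W-update steps for fold-in.
#' @export
predict.cnmf <- function(object, newdata = NULL, fold_iter = 200L, ...) {
  if (is.null(newdata)) return(object$labels)
  if (inherits(newdata, "cn_synthetic")) newdata <- newdata$profiles
  Fn <- if (inherits(newdata, "cn_profiles"))
    encode_cn(newdata, object$options$scheme)
  else if (inherits(newdata, "feature_matrix")) newdata
  else feature_matrix(as.matrix(newdata), object$feature$meta)
  if (ncol(Fn$values) != ncol(object$feature$values))
    stop("newdata features do not match the fitted feature space")
  Vc <- compact_columns(Fn, object$partition)$values
  H <- object$best$H
  W <- .with_seed(object$best$seed,
                  matrix(runif(nrow(Vc) * object$k), nrow(Vc), object$k))
  hs <- rowSums(H)
  for (i in seq_len(fold_iter)) {
    WH <- pmax(W %*% H, .EPS)
    W <- pmax(W * tcrossprod(Vc / WH, H) / rep(hs, each = nrow(W)), .EPS)
  }
  rownames(W) <- rownames(Vc)
  assign_clusters(W)
}

#' @describeIn cnmf Heatmap of the consensus matrix, samples ordered by
#'   the hierarchical tree used for the cut, with subgroup boundaries.
#' @export
plot.cnmf <- function(x, ...) {
  C <- x$consensus
  hc <- hclust(as.dist(1 - C), method = x$options$linkage)
  ord <- hc$order
  n <- nrow(C)
  graphics::image(seq_len(n), seq_len(n), C[ord, rev(ord)],
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "samples", ylab = "samples",
                  main = sprintf("Consensus matrix (k = %d, %d runs)",
                                 x$k, x$options$runs), ...)
  bounds <- cumsum(table(x$labels[ord]))
  graphics::abline(v = bounds[-length(bounds)] + 0.5,
                   h = n - bounds[-length(bounds)] + 0.5, col = "red")
  invisible(x)
}
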