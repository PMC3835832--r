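# extract a plain numeric matrix from any of the package's containers
.values_of <- function(x) {
  if (inherits(x, "feature_matrix") || inherits(x, "compact_matrix"))
    x$values
  else as.matrix(x)
}

#' Kullback-Leibler divergence of a factorization
#'
#' The generalized KL (I-)divergence
#' \deqn{D(V \| WH) = \sum_{i\mu} V_{i\mu} \log\frac{V_{i\mu}}{(WH)_{i\mu}}
#'   - V_{i\mu} + (WH)_{i\mu},}
#' with the convention \eqn{0 \log 0 = 0}.  This is the NMF objective under
#' a Poisson model of the counts, the natural choice for discrete
#' copy-number severities.  Entries of `WH` that are exactly zero where
#' `V > 0` give `+Inf` (the limiting value); otherwise `WH` is floored at a
#' tiny epsilon before the division/log.
#'
#' @param V non-negative matrix (or [feature_matrix]/[compact_matrix]).
#' @param W,H non-negative factor matrices with conformable dimensions.
#' @return Non-negative scalar divergence (possibly `Inf`).
#' @examples
#' kl_divergence(matrix(2), matrix(1), matrix(1))  # 2*log(2) - 1
#' @export
kl_divergence <- function(V, W, H) {
  V <- .values_of(V)
  W <- as.matrix(W); H <- as.matrix(H)
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H))
    stop("non-conformable dimensions for V = W %*% H")
  if (any(V < 0) || any(W < 0) || any(H < 0))
    stop("all matrices must be non-negative")
  .kl_divergence_cpp(V, W, H, .EPS)
}

#' One multiplicative-update step for KL-divergence NMF
#'
#' Applies the classic multiplicative updates: `H` first, using the current
#' `W`,
#' \deqn{H_{a\mu} \leftarrow H_{a\mu}
#'   \frac{\sum_i W_{ia} V_{i\mu}/(WH)_{i\mu}}{\sum_i W_{ia}},}
#' then `W` symmetrically using the freshly updated `H`.  Both factors are
#' floored at a tiny epsilon, which also protects the `(WH)` denominators.
#' The step never increases the divergence.
#'
#' @inheritParams kl_divergence
#' @return List with updated `W` and `H`.
#' @export
nmf_update <- function(V, W, H) {
  V <- .values_of(V)
  W <- as.matrix(W); H <- as.matrix(H)
  WH <- pmax(W %*% H, .EPS)
  H <- H * crossprod(W, V / WH) / colSums(W)
  H <- pmax(H, .EPS)
  WH <- pmax(W %*% H, .EPS)
  W <- W * tcrossprod(V / WH, H) / rep(rowSums(H), each = nrow(W))
  W <- pmax(W, .EPS)
  list(W = W, H = H)
}

#' Fit a KL-divergence NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` as `W %*% H` of rank `k` by
#' iterating [nmf_update] from a seeded uniform random start until the
#' relative divergence improvement per step falls below `tol` or `max_iter`
#' steps have been run.  The divergence sequence is non-increasing; the
#' optimization is local, so multiple seeded restarts are the intended use
#' (see [run_consensus]).
#'
#' @param V non-negative matrix (or [feature_matrix]/[compact_matrix]).
#' @param k factorization rank, `1 <= k <= min(dim(V))`.
#' @param seed integer seed for the uniform (0, 1] initialization of `W`
#'   and `H`; the fit is fully deterministic given `(V, k, seed)`.
#' @param max_iter maximum number of full update steps (default 2000).
#' @param tol relative divergence-improvement threshold (default 1e-6).
#' @param track if `TRUE`, record the divergence after every step.
#' @return Object of class `"nmf_fit"`: list with `W`, `H`, `rank`, `seed`,
#'   `iterations`, `divergence` (achieved on `V`), `converged`, and
#'   `trace` (if tracked).
#' @examples
#' v <- outer(1:3, c(2, 1, 4, 3))      # exactly rank 1
#' fit <- nmf_factorize(v, k = 1, seed = 7)
#' fit$divergence                      # ~ 0
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          track = FALSE) {
  V <- .values_of(V)
  if (!all(is.finite(V))) stop("V must be finite")
  if (any(V < 0)) stop("V must be non-negative")
  m <- nrow(V); n <- ncol(V)
  if (k < 1 || k > min(m, n))
    stop("rank k must satisfy 1 <= k <= min(dim(V)) = ", min(m, n))
  init <- .with_seed(seed, list(W = matrix(runif(m * k), m, k),
                                H = matrix(runif(k * n), k, n)))
  W <- init$W
  H <- init$H
  res <- .nmf_mu_cpp(V, W, H, as.integer(max_iter), tol, .EPS, track)
  rownames(res$W) <- rownames(V)
  colnames(res$H) <- colnames(V)
  structure(list(W = res$W, H = res$H, rank = as.integer(k),
                 seed = as.integer(seed), iterations = res$iterations,
                 divergence = res$divergence, converged = res$converged,
                 trace = if (track) res$trace else NULL),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("KL-NMF fit: rank ", x$rank, ", ", nrow(x$W), " x ", ncol(x$H),
      " matrix; divergence ", format(x$divergence, digits = 6),
      " after ", x$iterations, " iterations (seed ", x$seed,
      if (x$converged) ", converged" else ", not converged", ")\n", sep = "")
  invisible(x)
}

#' Expand a compact H factor back to original feature columns
#'
#' Each original feature's column is its bin's compact `H` column divided
#' by the bin size, so that `W %*% expand_h(Hc, P)` approximates the full
#' matrix when `W, Hc` were fitted to the bin-summed matrix.
#'
#' @param Hc rank x bin matrix from a factorization of the compacted matrix.
#' @param P the [bin_partition] used for compaction.
#' @return rank x feature matrix.
#' @export
expand_h <- function(Hc, P) {
  Hc <- as.matrix(Hc)
  if (ncol(Hc) != length(P$bins))
    stop("ncol(Hc) [", ncol(Hc), "] != number of bins [", length(P$bins), "]")
  binof <- .bin_of(P)
  sizes <- lengths(P$bins)
  out <- Hc[, binof, drop = FALSE] / rep(sizes[binof], each = nrow(Hc))
  colnames(out) <- NULL
  out
}

#' Divergence of a reduced-matrix factorization against the full matrix
#'
#' Evaluates how well a factorization obtained on a column-reduced matrix
#' models the *full* feature matrix.  In `"compact"` mode the compact `H`
#' is expanded by [expand_h] (bin column divided by bin size over its
#' members); in `"standard"` mode each bin representative's `H` column is
#' replicated to every member without division — the dropped columns were
#' never seen by the optimizer, and this is the baseline whose degraded
#' accuracy the compacted formulation avoids.
#'
#' @param F_full the full [feature_matrix] (or plain matrix).
#' @param W sample x rank factor.
#' @param Hc rank x bin factor fitted on [compact_columns]` (compact mode)
#'   or on [reduce_standard] (standard mode).
#' @param P the [bin_partition] used.
#' @param mode `"compact"` or `"standard"`.
#' @return Non-negative divergence to the full matrix.
#' @export
full_divergence <- function(F_full, W, Hc, P,
                            mode = c("compact", "standard")) {
  mode <- match.arg(mode)
  V <- .values_of(F_full)
  Hc <- as.matrix(Hc)
  if (ncol(Hc) != length(P$bins))
    stop("ncol(Hc) != number of bins")
  H_full <- if (mode == "compact") expand_h(Hc, P)
            else Hc[, .bin_of(P), drop = FALSE]
  kl_divergence(V, W, H_full)
}

#' Mean divergence ratio of a reduced run over the lossless reference
#'
#' Runs seeded factorizations of the compacted (or representative-reduced)
#' matrix and of the lossless reference (delta = 0 compaction of the same
#' matrix), evaluates each against the full matrix, and returns the ratio
#' of mean full-matrix divergences.  Values near 1 mean no accuracy was
#' lost by the reduction; the ratio for compact mode at delta = 0 is 1 by
#' construction.
#'
#' @param F_full full [feature_matrix] (or plain matrix).
#' @param P [bin_partition] describing the reduction under test.
#' @param k factorization rank.
#' @param seeds integer vector of seeds; the same seeds are used for the
#'   reduced and the reference runs.
#' @param mode `"compact"` or `"standard"`.
#' @param ref_partition lossless reference partition; defaults to
#'   `build_partition(F_full, 0, P$window)`.
#' @param ... passed to [nmf_factorize] (`max_iter`, `tol`).
#' @return Scalar ratio (mean reduced divergence / mean reference divergence).
#' @export
divergence_ratio <- function(F_full, P, k, seeds, mode = c("compact", "standard"),
                             ref_partition = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(ref_partition))
    ref_partition <- build_partition(F_full, 0, P$window)
  Vred <- if (mode == "compact") compact_columns(F_full, P)
          else reduce_standard(F_full, P)
  Vref <- compact_columns(F_full, ref_partition)
  red <- vapply(seeds, function(s) {
    fit <- nmf_factorize(Vred, k, seed = s, ...)
    full_divergence(F_full, fit$W, fit$H, P, mode)
  }, numeric(1))
  ref <- vapply(seeds, function(s) {
    fit <- nmf_factorize(Vref, k, seed = s, ...)
    full_divergence(F_full, fit$W, fit$H, ref_partition, "compact")
  }, numeric(1))
  if (mean(ref) == 0) stop("reference divergence is zero; ratio undefined")
  mean(red) / mean(ref)
}
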