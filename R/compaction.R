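#' Hamming distance between two columns
#'
#' Number of positions at which two equal-length vectors differ.  Comparison
#' is exact: 0, 0.5, 1 and 2 are four distinct values.
#'
#' @param col_a,col_b numeric vectors of equal length.
#' @return Non-negative integer count of differing positions.
#' @export
hamming_distance <- function(col_a, col_b) {
  if (length(col_a) != length(col_b))
    stop("columns have different lengths (", length(col_a), " vs ",
         length(col_b), ")")
  sum(col_a != col_b)
}

#' Default Hamming threshold: 1% of the sample count
#'
#' Columns are considered equivalent when they differ in at most 1% of
#' their entries, i.e. the merging threshold is `ceiling(0.01 * m)` for
#' `m` samples.
#'
#' @param m number of samples (rows), at least 1.
#' @return Integer threshold.
#' @examples
#' default_delta(533)  # 6
#' @export
default_delta <- function(m) {
  stopifnot(m >= 1)
  as.integer(ceiling(0.01 * m))
}

.fm_values <- function(F) if (inherits(F, "feature_matrix")) F$values else as.matrix(F)
.fm_meta <- function(F) {
  if (inherits(F, "feature_matrix")) return(F$meta)
  v <- as.matrix(F)
  # a plain matrix is treated as a single channel/chromosome block
  data.frame(probe = if (is.null(colnames(v))) paste0("c", seq_len(ncol(v))) else colnames(v),
             chrom = "block1", position = seq_len(ncol(v)),
             ordinal = seq_len(ncol(v)), channel = "gain",
             stringsAsFactors = FALSE)
}

#' Greedy Hamming-distance column partition
#'
#' Groups similar columns of a feature matrix into bins by a single
#' left-to-right greedy pass within each (channel, chromosome) block, in
#' genomic order.  The first unassigned column seeds a bin; every later
#' unassigned column of the same block joins it if its probe ordinal is
#' within `window` of the seed's and its Hamming distance to the *seed*
#' column is at most `delta`.  Columns are never merged across channels or
#' chromosomes, which keeps bins genomically interpretable.
#'
#' @param F a [feature_matrix], or a plain matrix (treated as one block
#'   with ordinals `1..ncol`).
#' @param delta maximum Hamming distance to the bin seed; `"auto"` uses
#'   [default_delta] of the row count.
#' @param window maximum probe-ordinal gap between a member and its bin
#'   seed (`Inf` disables the locality constraint).  Defaults to 500
#'   probes, which keeps the whole genomic profile represented.
#' @return An object of class `"bin_partition"`: list with `bins` (ordered
#'   list of integer index vectors), `representative` (seed index per bin),
#'   `delta`, `window`.
#' @export
build_partition <- function(F, delta = "auto", window = 500) {
  vals <- .fm_values(F)
  meta <- .fm_meta(F)
  if (identical(delta, "auto")) delta <- default_delta(nrow(vals))
  stopifnot(delta >= 0, window >= 0)
  block <- paste(meta$channel, meta$chrom, sep = "\r")
  # blocks visited in column order
  block_ids <- unique(block)
  bins <- list()
  reps <- integer(0)
  for (b in block_ids) {
    idx <- which(block == b)
    unassigned <- idx
    while (length(unassigned)) {
      seed <- unassigned[1L]
      cand <- unassigned[-1L]
      cand <- cand[meta$ordinal[cand] - meta$ordinal[seed] <= window]
      if (length(cand)) {
        d <- colSums(vals[, cand, drop = FALSE] != vals[, seed])
        members <- c(seed, cand[d <= delta])
      } else members <- seed
      bins[[length(bins) + 1L]] <- members
      reps[length(reps) + 1L] <- seed
      unassigned <- setdiff(unassigned, members)
    }
  }
  structure(list(bins = bins, representative = reps,
                 delta = delta, window = window),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  sizes <- lengths(x$bins)
  cat("Bin partition: ", length(x$bins), " bins over ", sum(sizes),
      " features (delta = ", x$delta, ", window = ", x$window, ")\n",
      sep = "")
  cat("Bin sizes: min ", min(sizes), ", median ", stats::median(sizes),
      ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
length.bin_partition <- function(x) length(x$bins)

# map: original feature index -> bin index
.bin_of <- function(P) {
  n <- sum(lengths(P$bins))
  out <- integer(n)
  for (b in seq_along(P$bins)) out[P$bins[[b]]] <- b
  out
}

.check_partition_indices <- function(P, ncol) {
  all_idx <- unlist(P$bins, use.names = FALSE)
  if (any(all_idx < 1L | all_idx > ncol))
    stop("partition refers to column indices outside 1..", ncol)
  if (anyDuplicated(all_idx) || length(all_idx) != ncol)
    stop("partition is not a partition of the ", ncol, " columns")
}

#' Verify a partition against the matrix it was built from
#'
#' Checks disjoint coverage, the per-bin channel/chromosome homogeneity,
#' the ordinal window and that every member is within the Hamming
#' threshold of its bin seed.
#'
#' @param P a [bin_partition].
#' @param F the matrix it partitions.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_partition <- function(P, F) {
  vals <- .fm_values(F)
  meta <- .fm_meta(F)
  .check_partition_indices(P, ncol(vals))
  for (b in seq_along(P$bins)) {
    m <- P$bins[[b]]
    s <- P$representative[b]
    if (!(s %in% m)) stop("bin ", b, ": representative not a member")
    if (length(unique(meta$channel[m])) > 1L ||
        length(unique(meta$chrom[m])) > 1L)
      stop("bin ", b, " mixes channels or chromosomes")
    if (any(abs(meta$ordinal[m] - meta$ordinal[s]) > P$window))
      stop("bin ", b, " violates the ordinal window")
    d <- colSums(vals[, m, drop = FALSE] != vals[, s])
    if (any(d > P$delta)) stop("bin ", b, " member beyond delta of its seed")
  }
  invisible(TRUE)
}

#' Sum binned columns into a compacted matrix
#'
#' Each output column is the elementwise sum of the original columns in one
#' bin, so the compacted matrix conserves per-sample row sums and the NMF
#' run on it minimizes the divergence to the full matrix.
#'
#' @param F a [feature_matrix] or plain matrix.
#' @param P a [bin_partition] of its columns.
#' @return An object of class `"compact_matrix"`: list with `values`
#'   (sample x bin matrix), `partition`, and `bin_meta` (seed probe,
#'   chromosome, channel, bin size).
#' @export
compact_columns <- function(F, P) {
  vals <- .fm_values(F)
  meta <- .fm_meta(F)
  .check_partition_indices(P, ncol(vals))
  out <- matrix(0, nrow(vals), length(P$bins))
  for (b in seq_along(P$bins))
    out[, b] <- rowSums(vals[, P$bins[[b]], drop = FALSE])
  rownames(out) <- rownames(vals)
  bin_meta <- data.frame(bin = seq_along(P$bins),
                         seed_probe = meta$probe[P$representative],
                         chrom = meta$chrom[P$representative],
                         channel = meta$channel[P$representative],
                         size = lengths(P$bins),
                         stringsAsFactors = FALSE)
  colnames(out) <- paste0("bin", bin_meta$bin)
  structure(list(values = out, partition = P, bin_meta = bin_meta),
            class = "compact_matrix")
}

#' @export
print.compact_matrix <- function(x, ...) {
  cat("Compacted matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " bins (from ", sum(lengths(x$partition$bins)), " features, delta = ",
      x$partition$delta, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.compact_matrix <- function(x) dim(x$values)

#' Keep one representative column per bin
#'
#' The baseline reduction: instead of summing, keep only each bin's seed
#' column and drop the rest.  An NMF run on this submatrix optimizes the
#' divergence to the submatrix, not to the full matrix, which is the
#' source of the baseline's degraded full-matrix accuracy.
#'
#' @inheritParams compact_columns
#' @return Object of the same kind as `F` restricted to the seed columns.
#' @export
reduce_standard <- function(F, P) {
  vals <- .fm_values(F)
  .check_partition_indices(P, ncol(vals))
  keep <- P$representative
  if (inherits(F, "feature_matrix"))
    feature_matrix(vals[, keep, drop = FALSE], F$meta[keep, , drop = FALSE])
  else vals[, keep, drop = FALSE]
}

#' Compaction summary over a grid of Hamming thresholds
#'
#' Tabulates how many columns remain after compaction for each threshold,
#' i.e. the matrix-size-versus-delta curve.
#'
#' @param F a [feature_matrix] or plain matrix.
#' @param deltas integer vector of Hamming thresholds.
#' @param window locality window (see [build_partition]).
#' @return data frame with columns `delta` and `n_columns`.
#' @export
compaction_summary <- function(F, deltas, window = 500) {
  data.frame(delta = deltas,
             n_columns = vapply(deltas, function(d)
               length(build_partition(F, d, window)$bins), integer(1)))
}
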