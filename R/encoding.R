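#' Probe-level copy-number profiles
#'
#' Container for discrete copy-number calls of a set of samples over an
#' ordered set of probes, optionally with copy-neutral LOH flags.  Calls are
#' either integer copy numbers (`type = "cn"`: 0 = homozygous deletion,
#' 1 = heterozygous loss, 2 = normal, 3-4 = gain, >4 = amplification) or
#' discrete states (`type = "state"`: `"loss"`, `"normal"`, `"gain"`).
#'
#' @param calls sample x probe matrix of calls; a non-negative integer matrix
#'   (copy numbers) or a character matrix with values `"loss"`, `"normal"`,
#'   `"gain"`.  Row names are sample ids, column names probe ids.
#' @param probes data frame with columns `probe`, `chrom`, `position`
#'   (base-pair integer), one row per column of `calls`, sorted by
#'   chromosome and strictly increasing position within each chromosome.
#' @param loh optional logical sample x probe matrix flagging copy-neutral
#'   LOH (loss of heterozygosity at normal copy number).
#'
#' @return An object of class `"cn_profiles"`: a list with elements `calls`,
#'   `probes`, `loh` and `type`.
#' @examples
#' probes <- data.frame(probe = c("p1", "p2"), chrom = "chr1",
#'                      position = c(100L, 200L))
#' calls <- matrix(c(2L, 3L, 0L, 2L), 2, 2,
#'                 dimnames = list(c("s1", "s2"), c("p1", "p2")))
#' cn_profiles(calls, probes)
#' @export
cn_profiles <- function(calls, probes, loh = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  probes <- as.data.frame(probes)
  need <- c("probe", "chrom", "position")
  if (!all(need %in% names(probes)))
    stop("'probes' must have columns probe, chrom, position")
  if (nrow(probes) == 0L) stop("probe annotation is empty")
  if (ncol(calls) != nrow(probes))
    stop("ncol(calls) [", ncol(calls), "] != number of probes [",
         nrow(probes), "]")
  if (anyNA(calls)) stop("missing calls are not allowed; profiles must be complete")
  if (is.numeric(calls)) {
    if (any(calls < 0)) stop("negative copy numbers are not allowed")
    if (any(calls != round(calls))) stop("copy numbers must be integers")
    storage.mode(calls) <- "integer"
    type <- "cn"
  } else if (is.character(calls)) {
    bad <- setdiff(unique(as.vector(calls)), c("loss", "normal", "gain"))
    if (length(bad))
      stop("unknown call states: ", paste(bad, collapse = ", "))
    type <- "state"
  } else stop("'calls' must be an integer or character matrix")
  # probes must be strictly ordered by position within each chromosome
  for (ch in unique(probes$chrom)) {
    pos <- probes$position[probes$chrom == ch]
    if (any(diff(pos) <= 0))
      stop("probes not strictly ordered by position on chromosome ", ch)
  }
  if (!is.null(loh)) {
    loh <- as.matrix(loh)
    if (!identical(dim(loh), dim(calls)))
      stop("'loh' must have the same dimensions as 'calls'")
    if (anyNA(loh) || !is.logical(loh)) stop("'loh' must be a complete logical matrix")
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  colnames(calls) <- probes$probe
  structure(list(calls = calls, probes = probes, loh = loh, type = type),
            class = "cn_profiles")
}

#' @export
print.cn_profiles <- function(x, ...) {
  cat("Copy-number profiles: ", nrow(x$calls), " samples x ",
      ncol(x$calls), " probes (", x$type, " calls",
      if (!is.null(x$loh)) ", with LOH flags", ")\n", sep = "")
  cat("Chromosomes:", paste(unique(x$probes$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Expand segment-level calls to probe-level profiles
#'
#' Projects SEG-like segment records onto a probe annotation: every probe
#' whose position falls inside a segment (1-based, inclusive ends) takes the
#' segment's state; probes covered by no segment are normal.
#'
#' @param segments data frame with columns `sample`, `chrom`, `start`,
#'   `end`, `state`; `state` is either a discrete state (`"loss"`,
#'   `"normal"`, `"gain"`) or an integer copy number.  Segments of one
#'   sample must not overlap within a chromosome.
#' @param probes probe annotation data frame (`probe`, `chrom`, `position`).
#' @param samples optional character vector of sample ids to emit (defaults
#'   to the samples present in `segments`); samples without segments get
#'   all-normal profiles.
#'
#' @return A [cn_profiles] object.
#' @export
expand_segments <- function(segments, probes, samples = NULL) {
  segments <- as.data.frame(segments)
  need <- c("sample", "chrom", "start", "end", "state")
  if (!all(need %in% names(segments)))
    stop("'segments' must have columns ", paste(need, collapse = ", "))
  probes <- as.data.frame(probes)
  if (nrow(probes) == 0L) stop("probe annotation is empty")
  if (is.null(samples)) samples <- unique(as.character(segments$sample))
  if (length(samples) == 0L) stop("no samples to expand")

  numeric_states <- is.numeric(segments$state)
  normal <- if (numeric_states) 2L else "normal"
  calls <- matrix(normal, nrow = length(samples), ncol = nrow(probes),
                  dimnames = list(samples, probes$probe))

  for (s in samples) {
    seg_s <- segments[as.character(segments$sample) == s, , drop = FALSE]
    for (ch in unique(seg_s$chrom)) {
      seg <- seg_s[seg_s$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
        stop("overlapping segments for sample ", s, " on chromosome ", ch)
      on_chr <- which(probes$chrom == ch)
      for (r in seq_len(nrow(seg))) {
        hit <- on_chr[probes$position[on_chr] >= seg$start[r] &
                        probes$position[on_chr] <= seg$end[r]]
        if (length(hit))
          calls[s, hit] <- if (numeric_states) as.integer(seg$state[r]) else
            as.character(seg$state[r])
      }
    }
  }
  cn_profiles(calls, probes)
}

#' Discretize integer copy numbers into loss/normal/gain states
#'
#' @param calls integer copy-number matrix or vector.
#' @return Character object of the same shape with values `"loss"`
#'   (CN <= 1), `"normal"` (CN == 2) or `"gain"` (CN >= 3).
#' @export
discretize_cn <- function(calls) {
  if (any(calls < 0)) stop("negative copy numbers are not allowed")
  out <- ifelse(calls <= 1, "loss", ifelse(calls == 2, "normal", "gain"))
  if (is.matrix(calls)) dim(out) <- dim(calls)
  dimnames(out) <- dimnames(calls)
  out
}

#' Two-channel feature matrix
#'
#' Non-negative sample x feature matrix with per-feature probe metadata.
#' Each probe contributes two features (channels): one for losses, one for
#' gains, so that the asymmetric Poisson-divergence objective treats both
#' aberration directions fairly.  All loss-channel columns come first, in
#' genomic order, followed by all gain-channel columns; the layout is
#' recorded in `meta` so downstream code never relies on it.
#'
#' @param values non-negative numeric sample x feature matrix.
#' @param meta data frame with one row per feature: `probe`, `chrom`,
#'   `position`, `ordinal` (probe index in genomic order) and `channel`
#'   (`"loss"` or `"gain"`).
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, meta) {
  values <- as.matrix(values)
  meta <- as.data.frame(meta)
  need <- c("probe", "chrom", "position", "ordinal", "channel")
  if (!all(need %in% names(meta)))
    stop("'meta' must have columns ", paste(need, collapse = ", "))
  if (ncol(values) != nrow(meta))
    stop("ncol(values) != nrow(meta)")
  if (any(values < 0)) stop("feature values must be non-negative")
  if (!all(meta$channel %in% c("loss", "gain")))
    stop("channel must be 'loss' or 'gain'")
  structure(list(values = values, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", sum(x$meta$channel == "loss"), " loss / ",
      sum(x$meta$channel == "gain"), " gain)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Encode copy-number profiles as a two-channel non-negative matrix
#'
#' Splits each probe's call into a loss feature and a gain feature.  Under
#' the ordinal scheme the encoding counts aberration severity: heterozygous
#' loss / gain is 1, homozygous deletion / amplification is 2, normal is 0,
#' and copy-neutral LOH is 0.5 in the loss feature.  Under the binary scheme
#' presence of the aberration is 1 and normal is 0 in each channel (used
#' when only loss/normal/gain states are available).
#'
#' @param profiles a [cn_profiles] object.
#' @param scheme `"ordinal"` (requires integer copy-number calls) or
#'   `"binary"` (accepts either representation).
#' @return A [feature_matrix] with `2 * n_probes` columns: the loss channel
#'   for all probes in genomic order, then the gain channel.
#' @examples
#' probes <- data.frame(probe = "p1", chrom = "chr1", position = 100L)
#' pr <- cn_profiles(matrix(c(0L, 5L), 2, 1), probes)
#' encode_cn(pr, "ordinal")$values  # loss (2,0); gain (0,2)
#' @export
encode_cn <- function(profiles, scheme = c("ordinal", "binary")) {
  stopifnot(inherits(profiles, "cn_profiles"))
  scheme <- match.arg(scheme)
  calls <- profiles$calls
  loh <- profiles$loh
  if (scheme == "ordinal") {
    if (profiles$type != "cn")
      stop("ordinal encoding requires integer copy-number calls")
    gain <- ifelse(calls > 4, 2, ifelse(calls >= 3, 1, 0))
    loss <- ifelse(calls == 0, 2, ifelse(calls == 1, 1, 0))
    if (!is.null(loh)) loss[loh & calls == 2L] <- 0.5
  } else {
    if (!is.null(loh)) {
      warning("copy-neutral LOH flags are ignored under the binary scheme")
      loh <- NULL
    }
    if (profiles$type == "cn") {
      gain <- (calls >= 3) * 1
      loss <- (calls <= 1) * 1
    } else {
      gain <- (calls == "gain") * 1
      loss <- (calls == "loss") * 1
    }
  }
  p <- profiles$probes
  meta <- rbind(
    data.frame(probe = p$probe, chrom = p$chrom, position = p$position,
               ordinal = seq_len(nrow(p)), channel = "loss",
               stringsAsFactors = FALSE),
    data.frame(probe = p$probe, chrom = p$chrom, position = p$position,
               ordinal = seq_len(nrow(p)), channel = "gain",
               stringsAsFactors = FALSE))
  values <- cbind(loss, gain)
  colnames(values) <- paste(meta$probe, meta$channel, sep = ":")
  rownames(values) <- rownames(calls)
  feature_matrix(values, meta)
}
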