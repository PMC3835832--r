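#' Read a probe-level call matrix with its annotation
#'
#' The matrix file is tab-delimited with a header row of probe ids and the
#' first column holding sample ids; the annotation file is tab-delimited
#' with columns `probe`, `chrom`, `position`.  An optional LOH file has the
#' same layout as the matrix with 0/1 flags.
#'
#' @param matrix_file,annotation_file,loh_file file paths.
#' @return A [cn_profiles] object.
#' @export
read_probe_matrix <- function(matrix_file, annotation_file, loh_file = NULL) {
  ann <- read.delim(annotation_file, stringsAsFactors = FALSE)
  raw <- read.delim(matrix_file, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- samples
  if (!identical(colnames(mat), as.character(ann$probe)))
    mat <- mat[, as.character(ann$probe), drop = FALSE]
  if (is.numeric(mat)) storage.mode(mat) <- "integer"
  loh <- NULL
  if (!is.null(loh_file)) {
    lraw <- read.delim(loh_file, check.names = FALSE, stringsAsFactors = FALSE)
    loh <- as.matrix(lraw[, -1L, drop = FALSE]) != 0
    rownames(loh) <- lraw[[1L]]
    loh <- loh[samples, as.character(ann$probe), drop = FALSE]
  }
  cn_profiles(mat, ann, loh = loh)
}

#' Write a probe-level call matrix and annotation
#'
#' Inverse of [read_probe_matrix]; emits the formats the reader accepts.
#'
#' @param profiles a [cn_profiles].
#' @param matrix_file,annotation_file,loh_file output paths (`loh_file`
#'   only written when the profiles carry LOH flags).
#' @return Invisibly, the matrix file path.
#' @export
write_probe_matrix <- function(profiles, matrix_file, annotation_file,
                               loh_file = NULL) {
  df <- data.frame(sample = rownames(profiles$calls),
                   profiles$calls, check.names = FALSE)
  write.table(df, matrix_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(profiles$probes, annotation_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(profiles$loh) && !is.null(loh_file)) {
    ldf <- data.frame(sample = rownames(profiles$calls),
                      profiles$loh * 1L, check.names = FALSE)
    write.table(ldf, loh_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_file)
}

#' Read SEG-like segment records
#'
#' Tab-delimited with columns `sample`, `chrom`, `start`, `end`, `state`
#' (1-based inclusive coordinates).
#'
#' @param file path.
#' @return data frame of segments, ready for [expand_segments].
#' @export
read_segments <- function(file) {
  seg <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "state")
  if (!all(need %in% names(seg)))
    stop("segment file must have columns ", paste(need, collapse = ", "))
  seg
}

#' Serialize a bin partition as tab-delimited text
#'
#' One row per bin: bin id, seed feature index, comma-separated member
#' indices.
#'
#' @param P a [bin_partition].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_partition <- function(P, file) {
  df <- data.frame(bin = seq_along(P$bins),
                   seed = P$representative,
                   members = vapply(P$bins, paste, character(1), collapse = ","))
  header <- sprintf("# delta=%d window=%s", P$delta, format(P$window))
  writeLines(header, file)
  suppressWarnings(
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(file)
}

#' Read a bin partition written by [write_partition]
#' @param file path.
#' @return A [bin_partition].
#' @export
read_partition <- function(file) {
  header <- readLines(file, n = 1L)
  delta <- as.integer(sub(".*delta=([0-9]+).*", "\\1", header))
  window <- as.numeric(sub(".*window=([0-9.eInf+]+).*", "\\1", header))
  df <- read.delim(file, skip = 1L, stringsAsFactors = FALSE)
  bins <- lapply(strsplit(df$members, ","), as.integer)
  structure(list(bins = bins, representative = as.integer(df$seed),
                 delta = delta, window = window),
            class = "bin_partition")
}

#' Write a factorization as W/H tables plus a JSON run-metadata sidecar
#'
#' @param fit an `nmf_fit` from [nmf_factorize].
#' @param prefix path prefix; writes `<prefix>_W.tsv`, `<prefix>_H.tsv`
#'   and `<prefix>_meta.json`.
#' @return Invisibly, the three paths.
#' @export
write_factorization <- function(fit, prefix) {
  wf <- paste0(prefix, "_W.tsv"); hf <- paste0(prefix, "_H.tsv")
  mf <- paste0(prefix, "_meta.json")
  write.table(fit$W, wf, sep = "\t", quote = FALSE, col.names = NA)
  write.table(fit$H, hf, sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(list(rank = fit$rank, seed = fit$seed,
                            iterations = fit$iterations,
                            divergence = fit$divergence,
                            converged = fit$converged),
                       mf, auto_unbox = TRUE, digits = NA)
  invisible(c(wf, hf, mf))
}

#' Write a square consensus matrix with sample ids
#' @param C consensus matrix.
#' @param file path.
#' @return Invisibly, `file`.
#' @export
write_consensus <- function(C, file) {
  write.table(as.matrix(C), file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

#' Write cluster labels as a two-column table
#' @param labels named integer vector.
#' @param file path.
#' @return Invisibly, `file`.
#' @export
write_labels <- function(labels, file) {
  df <- data.frame(sample = if (is.null(names(labels)))
    seq_along(labels) else names(labels), cluster = as.integer(labels))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
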