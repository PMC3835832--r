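.config_defaults <- function() list(
  matrix_file = NULL, annotation_file = NULL, loh_file = NULL,
  segments_file = NULL, scheme = "ordinal", delta = "auto", window = 500,
  ranks = 2:5, T = 300L, base_seed = 1L, max_iter = 2000L, tol = 1e-6,
  linkage = "average", ratio_runs = 5L, output_dir = "cnmf_out")

#' Build a run configuration
#'
#' Assembles and checks the configuration driving [run_subgrouping] and
#' [run_comparison].  Unknown fields are rejected rather than ignored, so
#' a typo in `delta` or `window` fails loudly instead of silently running
#' with defaults.
#'
#' @param ... configuration fields: `matrix_file`, `annotation_file`,
#'   `loh_file` (probe-matrix input) or `segments_file` +
#'   `annotation_file` (segment input); `scheme` (`"ordinal"`/`"binary"`),
#'   `delta` (integer or `"auto"`), `window`, `ranks`, `T` (restarts,
#'   default 300), `base_seed`, `max_iter`, `tol`, `linkage`,
#'   `ratio_runs` (seeds per ratio estimate in [run_comparison]),
#'   `output_dir`.
#' @return List of class `"run_config"` with defaults filled in.
#' @export
run_config <- function(...) {
  fields <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(fields), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, fields)
  if (length(cfg$ranks) == 0L) stop("'ranks' must be nonempty")
  if (!identical(cfg$delta, "auto") && cfg$delta < 0)
    stop("'delta' must be non-negative or \"auto\"")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a plain-text key = value file
#'
#' One `key = value` pair per line; `#` starts a comment.  Comma-separated
#' values become vectors (e.g. `ranks = 2,3,4`).
#'
#' @param path file path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed configuration line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- lapply(kv, function(p) {
    v <- trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  do.call(run_config, setNames(vals, keys))
}

.load_profiles <- function(config) {
  if (!is.null(config$matrix_file)) {
    read_probe_matrix(config$matrix_file, config$annotation_file,
                      config$loh_file)
  } else if (!is.null(config$segments_file)) {
    ann <- read.delim(config$annotation_file, stringsAsFactors = FALSE)
    expand_segments(read_segments(config$segments_file), ann)
  } else stop("configuration names no input (matrix_file or segments_file)")
}

#' End-to-end subgrouping pipeline
#'
#' Loads calls, encodes, compacts, scans the configured ranks with
#' consensus runs, and writes all primary outputs to the configured
#' directory: per-rank consensus matrices and labels, the quality report
#' (TSV + JSON), the bin partition and compaction summary, and a
#' provenance manifest.  Outputs are deterministic given the configuration
#' and inputs.
#'
#' @param config a [run_config] (or path to a configuration file).
#' @param profiles optionally, already-loaded [cn_profiles] (skips the
#'   file input).
#' @return Invisibly, a list with the [rank_report], the partition, the
#'   output paths and the manifest.
#' @export
run_subgrouping <- function(config, profiles = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  res <- tryCatch({
    if (is.null(profiles)) profiles <- .load_profiles(config)
    stage <- "encode"
    F <- encode_cn(profiles, config$scheme)
    stage <- "compact"
    P <- build_partition(F, delta = config$delta, window = config$window)
    Vc <- compact_columns(F, P)
    write_partition(P, file.path(out, "partition.tsv"))
    write.table(data.frame(delta = P$delta, window = config$window,
                           n_features = ncol(F$values),
                           n_bins = length(P$bins)),
                file.path(out, "compaction_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stage <- "rank_scan"
    report <- rank_report(Vc, config$ranks, T = config$T,
                       base_seed = config$base_seed,
                       max_iter = config$max_iter, tol = config$tol,
                       linkage = config$linkage)
    for (i in seq_along(report$labels)) {
      k <- report$table$rank[i]
      write_consensus(report$consensus[[i]],
                      file.path(out, sprintf("consensus_k%d.tsv", k)))
      write_labels(report$labels[[i]],
                   file.path(out, sprintf("labels_k%d.tsv", k)))
    }
    write.table(report$table, file.path(out, "quality_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(table = report$table,
                              recommended_rank = report$recommended),
                         file.path(out, "quality_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(report = report, partition = P)
  }, error = function(e) {
    manifest <- list(complete = FALSE, failed_stage = stage,
                     error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  cfg <- unclass(config)
  manifest <- list(complete = TRUE,
                   package_version = as.character(utils::packageVersion("cnmf")),
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   delta_used = res$partition$delta,
                   seeds = c(config$base_seed,
                             config$base_seed + config$T - 1L),
                   recommended_rank = res$report$recommended)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(output_dir = out, manifest = manifest)))
}

#' Compare compact and representative-only reductions against the
#' lossless reference
#'
#' For each Hamming threshold, builds the partition, records the resulting
#' column count, and estimates the mean full-matrix divergence ratio over
#' the lossless (delta = 0) reference for each requested rank and mode.
#'
#' @param F a [feature_matrix] (or plain matrix); alternatively pass a
#'   [run_config] as `config` with file inputs.
#' @param deltas integer vector of Hamming thresholds.
#' @param ranks integer vector of factorization ranks.
#' @param modes subset of `c("compact", "standard")`.
#' @param seeds seeds for the averaged runs (shared across modes and the
#'   reference).
#' @param window locality window.
#' @param ... passed to [nmf_factorize].
#' @return data frame with columns `delta`, `n_columns`, `rank`, `mode`,
#'   `ratio`.
#' @export
run_comparison <- function(F, deltas = c(0L, 1L, 2L, 5L), ranks = 2:4,
                           modes = c("compact", "standard"),
                           seeds = 1:5, window = 500, ...) {
  modes <- match.arg(modes, several.ok = TRUE)
  ref <- build_partition(F, 0, window)
  rows <- list()
  for (d in deltas) {
    P <- if (d == 0) ref else build_partition(F, d, window)
    for (k in ranks) for (mode in modes) {
      ratio <- divergence_ratio(F, P, k, seeds, mode = mode,
                                ref_partition = ref, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(delta = d, n_columns = length(P$bins), rank = k,
                   mode = mode, ratio = ratio)
    }
  }
  do.call(rbind, rows)
}
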