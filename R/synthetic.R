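#' Specification of a synthetic copy-number cohort with planted subgroups
#'
#' Describes a cohort in which each subgroup carries characteristic
#' contiguous aberration blocks (mirroring per-cluster gain/loss frequency
#' profiles of real cohorts) on top of sparse background noise.  Contiguous
#' blocks produce the runs of near-identical feature columns that the
#' compaction step exploits.
#'
#' The defaults describe the validation design used throughout the package:
#' 3 groups of 20 samples, 4 chromosomes of 500 probes (2,000 probes), two
#' 150-probe severity-1 blocks per group with penetrance 0.9, and a 0.02
#' per-probe background aberration rate — a desk-scale analogue of a
#' several-hundred-sample SNP-array cohort.
#'
#' @param samples_per_group integer vector; its length defines the number
#'   of planted groups.
#' @param probes_per_chrom integer vector of probes per chromosome.
#' @param blocks data frame with columns `group`, `chrom` (chromosome
#'   index), `start`, `end` (probe ordinals within the chromosome,
#'   inclusive), `channel` (`"gain"` or `"loss"`), `penetrance` in `[0,1]`,
#'   `severity` (1 = gain/heterozygous loss, 2 = amplification/homozygous
#'   deletion).
#' @param background per-probe probability of flipping to a random
#'   severity-1 aberrant state, independently per sample and probe.
#' @param loh_blocks optional data frame (`group`, `chrom`, `start`, `end`,
#'   `penetrance`) of copy-neutral LOH blocks.
#' @param seed integer seed.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(samples_per_group = c(20L, 20L, 20L),
                           probes_per_chrom = rep(500L, 4L),
                           blocks = default_blocks(),
                           background = 0.02,
                           loh_blocks = NULL,
                           seed = 1L) {
  blocks <- as.data.frame(blocks)
  problems <- character(0)
  if (any(samples_per_group < 1))
    problems <- c(problems, "samples_per_group must be positive")
  if (any(probes_per_chrom < 1))
    problems <- c(problems, "probes_per_chrom must be positive")
  k <- length(samples_per_group)
  if (any(blocks$group < 1 | blocks$group > k))
    problems <- c(problems, "block group outside 1..k")
  if (any(blocks$chrom < 1 | blocks$chrom > length(probes_per_chrom)))
    problems <- c(problems, "block chromosome outside the annotation")
  else {
    bad <- blocks$start < 1 | blocks$end > probes_per_chrom[blocks$chrom] |
      blocks$start > blocks$end
    if (any(bad)) problems <- c(problems, "block outside chromosome bounds")
  }
  if (!all(blocks$channel %in% c("gain", "loss")))
    problems <- c(problems, "block channel must be 'gain' or 'loss'")
  if (any(blocks$penetrance < 0 | blocks$penetrance > 1))
    problems <- c(problems, "penetrance must be in [0, 1]")
  if (!all(blocks$severity %in% c(1, 2)))
    problems <- c(problems, "severity must be 1 or 2")
  if (background < 0 || background > 1)
    problems <- c(problems, "background rate must be in [0, 1]")
  if (!is.null(loh_blocks)) {
    loh_blocks <- as.data.frame(loh_blocks)
    if (any(loh_blocks$chrom < 1 | loh_blocks$chrom > length(probes_per_chrom)) ||
        any(loh_blocks$start < 1) ||
        any(loh_blocks$end > probes_per_chrom[loh_blocks$chrom]))
      problems <- c(problems, "LOH block outside chromosome bounds")
    if (any(loh_blocks$penetrance < 0 | loh_blocks$penetrance > 1))
      problems <- c(problems, "LOH penetrance must be in [0, 1]")
  }
  if (length(problems))
    stop("invalid synthetic spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(samples_per_group = as.integer(samples_per_group),
                 probes_per_chrom = as.integer(probes_per_chrom),
                 blocks = blocks, background = background,
                 loh_blocks = loh_blocks, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default planted aberration blocks for the validation design
#'
#' Two 150-probe severity-1 blocks per group at penetrance 0.9, on
#' distinct chromosome regions so each group has a characteristic profile.
#'
#' @param penetrance block penetrance (default 0.9).
#' @return data frame usable as the `blocks` argument of [synthetic_spec].
#' @export
default_blocks <- function(penetrance = 0.9) {
  data.frame(
    group = c(1L, 1L, 2L, 2L, 3L, 3L),
    chrom = c(1L, 2L, 2L, 3L, 3L, 4L),
    start = c(51L, 251L, 101L, 301L, 51L, 151L),
    end = c(200L, 400L, 250L, 450L, 200L, 300L),
    channel = c("gain", "loss", "gain", "loss", "gain", "loss"),
    penetrance = penetrance,
    severity = 1L)
}

#' Generate a synthetic cohort from a specification
#'
#' Every sample of a group carries each of the group's blocks independently
#' with probability equal to the block penetrance; background noise then
#' flips individual probes to a random severity-1 aberrant state (CN 1 or
#' 3, equiprobable) independently at the background rate.  Deterministic
#' given the spec's seed.
#'
#' @param spec a [synthetic_spec].
#' @return Object of class `"cn_synthetic"`: list with `profiles` (a
#'   [cn_profiles]), `labels` (true group per sample) and `spec`.
#' @export
generate_cn <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_cn_impl(spec))
}

.generate_cn_impl <- function(spec) {
  n_chrom <- length(spec$probes_per_chrom)
  probes <- do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(probe = sprintf("c%d_p%04d", ch, seq_len(spec$probes_per_chrom[ch])),
               chrom = paste0("chr", ch),
               position = seq_len(spec$probes_per_chrom[ch]) * 1000L,
               stringsAsFactors = FALSE)))
  chrom_offset <- c(0L, cumsum(spec$probes_per_chrom))[seq_len(n_chrom)]
  n <- sum(spec$samples_per_group)
  p <- nrow(probes)
  labels <- rep(seq_along(spec$samples_per_group), spec$samples_per_group)
  calls <- matrix(2L, n, p)
  loh <- if (is.null(spec$loh_blocks)) NULL else matrix(FALSE, n, p)
  for (i in seq_len(n)) {
    g <- labels[i]
    blk <- spec$blocks[spec$blocks$group == g, , drop = FALSE]
    for (b in seq_len(nrow(blk))) {
      if (runif(1) <= blk$penetrance[b]) {
        cols <- chrom_offset[blk$chrom[b]] + blk$start[b]:blk$end[b]
        cn <- if (blk$channel[b] == "gain") {
          if (blk$severity[b] == 2L) 5L else 3L
        } else {
          if (blk$severity[b] == 2L) 0L else 1L
        }
        calls[i, cols] <- cn
      }
    }
    if (!is.null(loh)) {
      lb <- spec$loh_blocks[spec$loh_blocks$group == g, , drop = FALSE]
      for (b in seq_len(nrow(lb))) {
        if (runif(1) <= lb$penetrance[b]) {
          cols <- chrom_offset[lb$chrom[b]] + lb$start[b]:lb$end[b]
          loh[i, cols] <- calls[i, cols] == 2L
        }
      }
    }
    if (spec$background > 0) {
      flip <- which(runif(p) <= spec$background)
      if (length(flip))
        calls[i, flip] <- ifelse(runif(length(flip)) < 0.5, 1L, 3L)
    }
  }
  rownames(calls) <- sprintf("s%03d", seq_len(n))
  names(labels) <- rownames(calls)
  profiles <- cn_profiles(calls, probes, loh = loh)
  structure(list(profiles = profiles, labels = labels, spec = spec),
            class = "cn_synthetic")
}

#' @export
print.cn_synthetic <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$labels), " samples in ",
      length(x$spec$samples_per_group), " planted groups, ",
      nrow(x$profiles$probes), " probes\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same samples; 1 for identical partitions (up to label permutation),
#' about 0 for independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
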