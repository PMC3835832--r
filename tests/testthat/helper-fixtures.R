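# Small builders and independent oracles used across the test files.

# tiny probe annotation: `per_chrom` probes on each of `n_chrom` chromosomes
tiny_probes <- function(n_chrom = 2, per_chrom = 5) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(probe = paste0("c", ch, "_p", seq_len(per_chrom)),
               chrom = paste0("chr", ch),
               position = seq_len(per_chrom) * 100L,
               stringsAsFactors = FALSE)))
}

# feature matrix from a plain value matrix, one gain channel, one chromosome
plain_fm <- function(values) {
  values <- as.matrix(values)
  feature_matrix(values,
                 data.frame(probe = paste0("p", seq_len(ncol(values))),
                            chrom = "chr1",
                            position = seq_len(ncol(values)) * 100L,
                            ordinal = seq_len(ncol(values)),
                            channel = "gain", stringsAsFactors = FALSE))
}

# consensus-like matrix with two blocks: within/between similarity + jitter
block_consensus <- function(sizes = c(5, 5), within = 0.95, between = 0.05,
                            jitter = 0.01, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  C <- ifelse(outer(lab, lab, "=="), within, between)
  set.seed(seed)
  noise <- matrix(runif(n * n, -jitter, jitter), n, n)
  noise <- (noise + t(noise)) / 2
  C <- pmin(pmax(C + noise, 0), 1)
  diag(C) <- 1
  C
}

# independent KL divergence (no shared code with the package internals)
kl_ref <- function(V, W, H) {
  WH <- W %*% H
  term <- ifelse(V > 0, V * log(V / pmax(WH, 1e-12)), 0)
  sum(term - V + WH)
}

# brute-force NMF oracle: alternating exact 1-D minimization of every
# entry of W and H via optimize(), multiple random starts, best divergence
oracle_nmf <- function(V, k, starts = 3, sweeps = 400, seed0 = 1000) {
  m <- nrow(V); n <- ncol(V); best <- Inf
  upper <- 2 * max(V) + 1
  for (s in seq_len(starts)) {
    set.seed(seed0 + s)
    W <- matrix(runif(m * k), m, k)
    H <- matrix(runif(k * n), k, n)
    d_prev <- Inf
    for (it in seq_len(sweeps)) {
      for (a in seq_len(k)) for (i in seq_len(m)) {
        f <- function(w) { Wt <- W; Wt[i, a] <- w; kl_ref(V, Wt, H) }
        W[i, a] <- optimize(f, c(0, upper))$minimum
      }
      for (a in seq_len(k)) for (j in seq_len(n)) {
        f <- function(h) { Ht <- H; Ht[a, j] <- h; kl_ref(V, W, Ht) }
        H[a, j] <- optimize(f, c(0, upper))$minimum
      }
      d <- kl_ref(V, W, H)
      if (is.finite(d_prev) && (d_prev - d) < 1e-10 * max(d_prev, 1)) break
      d_prev <- d
    }
    best <- min(best, d)
  }
  best
}

# brute-force adjusted Rand: explicit enumeration of all sample pairs
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# two-sided (probability-ordering) exact p for a 2x2 table, closed form
fisher2x2_ref <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- dhyper(support, m, n, kk)
  p_obs <- dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# desk-scale cohort for module-level recovery tests (smaller than the
# acceptance design so unit files stay fast)
small_cohort <- function(seed = 11) {
  generate_cn(synthetic_spec(samples_per_group = c(10L, 10L, 10L),
                             probes_per_chrom = rep(120L, 4L),
                             blocks = data.frame(
                               group = c(1L, 1L, 2L, 2L, 3L, 3L),
                               chrom = c(1L, 2L, 2L, 3L, 3L, 4L),
                               start = c(11L, 61L, 31L, 71L, 11L, 41L),
                               end = c(50L, 100L, 70L, 110L, 50L, 80L),
                               channel = c("gain", "loss", "gain", "loss",
                                           "gain", "loss"),
                               penetrance = 0.9, severity = 1L),
                             background = 0.02, seed = seed))
}
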