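test_that("intra-cluster similarity averages consensus over within-cluster pairs", {
  # constant off-diagonal 0.5 -> every aggregate is 0.5
  C <- matrix(0.5, 6, 6); diag(C) <- 1
  labs <- rep(1:2, each = 3)
  expect_equal(intra_cluster_similarity(C, labs, "mean")$value, 0.5)
  expect_equal(intra_cluster_similarity(C, labs, "max")$value, 0.5)

  # hand evaluation with a singleton cluster
  C2 <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3, 3)
  s <- intra_cluster_similarity(C2, c(1, 1, 2), "mean")
  expect_equal(unname(s$per_cluster), c(0.8, 1))
  expect_equal(s$value, 0.9)
  expect_equal(intra_cluster_similarity(C2, c(1, 1, 2), "max")$value, 1)
  expect_equal(intra_cluster_similarity(C2, c(1, 1, 2), "max",
                                        exclude_singletons = TRUE)$value, 0.8)

  # permutation invariance of the labels
  s_perm <- intra_cluster_similarity(C2, c(2, 2, 1), "mean")
  expect_equal(sort(unname(s_perm$per_cluster)), sort(unname(s$per_cluster)))
  expect_equal(s_perm$value, s$value)
  expect_error(intra_cluster_similarity(C2, c(1, 1, 3)), "empty cluster")
})

test_that("similarity aggregates stay in [0,1] with max >= mean", {
  set.seed(5)
  for (i in 1:5) {
    C <- block_consensus(c(4, 4, 3), jitter = 0.2, seed = i)
    labs <- sample(1:3, 11, replace = TRUE)
    labs <- relabel_by_size(labs)
    s_mean <- intra_cluster_similarity(C, labs, "mean")
    s_max <- intra_cluster_similarity(C, labs, "max")
    expect_true(all(s_mean$per_cluster >= 0 & s_mean$per_cluster <= 1))
    expect_gte(s_max$value, s_mean$value)
    expect_gte(s_mean$value, min(s_mean$per_cluster))
  }
})

test_that("cophenetic correlation is high for block structure and errors when degenerate", {
  C <- block_consensus(c(5, 5), within = 0.95, between = 0.05,
                       jitter = 0.01, seed = 3)
  expect_gt(cophenetic_coefficient(C), 0.95)
  perm <- sample(10)
  expect_equal(cophenetic_coefficient(C[perm, perm]),
               cophenetic_coefficient(C), tolerance = 1e-12)
  Cc <- matrix(0.5, 4, 4); diag(Cc) <- 1
  expect_error(cophenetic_coefficient(Cc), "degenerate|constant")
  expect_error(cophenetic_coefficient(matrix(1, 2, 2)), "3 samples")
})

test_that("silhouette behaves at its reference points", {
  C <- matrix(0, 6, 6); C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  labs <- rep(1:2, each = 3)
  expect_equal(silhouette_mean(C, labs), 1)
  # labels orthogonal to the block structure score negative
  expect_lt(silhouette_mean(C, rep(1:2, 3)), 0)
  # all dissimilarities equal -> 0
  Cc <- matrix(0.5, 6, 6); diag(Cc) <- 1
  expect_equal(silhouette_mean(Cc, labs), 0)
  expect_error(silhouette_mean(C, rep(1, 6)), "2 clusters")
})

test_that("rank report tabulates measures and recommends the planted rank", {
  coh <- small_cohort(seed = 12)
  F <- encode_cn(coh$profiles, "ordinal")
  Vc <- compact_columns(F, build_partition(F, "auto", 500))
  rep3 <- rank_report(Vc, 2:4, T = 15, base_seed = 1)
  expect_equal(rep3$recommended, 3)
  s <- rep3$table$S_mean
  expect_gt(s[rep3$table$rank == 3], s[rep3$table$rank == 2])
  expect_gt(s[rep3$table$rank == 3], s[rep3$table$rank == 4])
  # deterministic given seeds
  rep3b <- rank_report(Vc, 2:4, T = 15, base_seed = 1)
  expect_identical(rep3$table, rep3b$table)
  # single requested rank: report it and recommend it
  rep1 <- rank_report(Vc, 3, T = 5, base_seed = 1)
  expect_equal(rep1$recommended, 3)
  expect_equal(nrow(rep1$table), 1L)
  expect_error(rank_report(Vc, 1, T = 5), "ranks")
})

test_that("exact contingency test matches closed forms on 2x2 tables", {
  expect_equal(fisher_exact(matrix(5, 2, 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2, 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  # sweep all 2x2 tables with total <= 30 and positive margins
  for (N in c(5L, 12L, 30L)) {
    tabs <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    tabs <- tabs[tabs$a + tabs$b + tabs$c <= N, ]
    set.seed(N)
    tabs <- tabs[sample(nrow(tabs), min(150, nrow(tabs))), ]
    for (r in seq_len(nrow(tabs))) {
      tab <- matrix(c(tabs$a[r], tabs$b[r], tabs$c[r],
                      N - tabs$a[r] - tabs$b[r] - tabs$c[r]), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), fisher2x2_ref(tab), tolerance = 1e-9)
    }
  }
})

test_that("exact test is permutation invariant and agrees with the network algorithm", {
  tab <- matrix(c(4, 1, 2, 5, 3, 0), 3, 2)
  expect_equal(fisher_exact(tab), fisher_exact(tab[c(2, 3, 1), ]),
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab), fisher_exact(tab[, 2:1]),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 4), 3, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
  expect_error(fisher_exact(matrix(1:2, 2, 1)), "2 x 2")
  expect_error(fisher_exact(matrix(50L, 3, 3), max_tables = 10), "Monte-Carlo")
})

test_that("cluster/subtype association on the reconstructed cohort table is ~0.031", {
  tab <- matrix(c(13, 15, 7, 14, 7, 1), 3, 2, byrow = TRUE)
  p <- fisher_exact(tab)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  expect_lt(abs(p - 0.031), 0.001)
})
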