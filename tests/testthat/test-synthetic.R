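test_that("generator is deterministic and honors degenerate penetrance settings", {
  spec <- synthetic_spec(samples_per_group = c(4L, 4L),
                         probes_per_chrom = c(30L, 30L),
                         blocks = data.frame(group = 1:2, chrom = 1:2,
                                             start = 5L, end = 20L,
                                             channel = c("gain", "loss"),
                                             penetrance = 1, severity = 1L),
                         background = 0, seed = 3)
  a <- generate_cn(spec); b <- generate_cn(spec)
  expect_identical(a$profiles$calls, b$profiles$calls)
  # penetrance 1, background 0: samples of one group are identical
  g1 <- a$profiles$calls[a$labels == 1, ]
  expect_true(all(apply(g1, 2, function(x) length(unique(x))) == 1))
  # within-block feature columns are identical -> delta=0 merges each run
  F <- encode_cn(a$profiles, "ordinal")
  P <- build_partition(F, 0, 500)
  expect_lte(length(P$bins), 8)  # few bins: 2 channels x 2 chroms (+ block edges)

  # penetrance 0, background 0: all-normal, all-zero features
  spec0 <- synthetic_spec(samples_per_group = c(3L, 3L),
                          probes_per_chrom = 20L,
                          blocks = data.frame(group = 1L, chrom = 1L,
                                              start = 2L, end = 5L,
                                              channel = "gain",
                                              penetrance = 0, severity = 1L),
                          background = 0, seed = 1)
  d0 <- generate_cn(spec0)
  expect_true(all(d0$profiles$calls == 2L))
  expect_true(all(encode_cn(d0$profiles, "ordinal")$values == 0))
})

test_that("invalid specifications are rejected with the violations listed", {
  expect_error(synthetic_spec(blocks = data.frame(group = 9L, chrom = 1L,
                                                  start = 1L, end = 5L,
                                                  channel = "gain",
                                                  penetrance = 0.5,
                                                  severity = 1L)),
               "group outside")
  expect_error(synthetic_spec(background = 1.5), "background")
  expect_error(synthetic_spec(blocks = data.frame(group = 1L, chrom = 1L,
                                                  start = 400L, end = 600L,
                                                  channel = "gain",
                                                  penetrance = 0.5,
                                                  severity = 1L)),
               "bounds")
})

test_that("within-block aberration frequency approximates the penetrance", {
  spec <- synthetic_spec(samples_per_group = 500L,
                         probes_per_chrom = 40L,
                         blocks = data.frame(group = 1L, chrom = 1L,
                                             start = 11L, end = 30L,
                                             channel = "gain",
                                             penetrance = 0.9,
                                             severity = 1L),
                         background = 0, seed = 21)
  d <- generate_cn(spec)
  freq <- mean(d$profiles$calls[, 11:30] >= 3)
  expect_lt(abs(freq - 0.9), 3 * sqrt(0.9 * 0.1 / 500))
})

test_that("LOH blocks mark copy-neutral probes and encode to 0.5", {
  spec <- synthetic_spec(samples_per_group = 5L, probes_per_chrom = 20L,
                         blocks = data.frame(group = 1L, chrom = 1L,
                                             start = 1L, end = 5L,
                                             channel = "gain",
                                             penetrance = 0, severity = 1L),
                         background = 0,
                         loh_blocks = data.frame(group = 1L, chrom = 1L,
                                                 start = 10L, end = 15L,
                                                 penetrance = 1),
                         seed = 2)
  d <- generate_cn(spec)
  expect_true(all(d$profiles$loh[, 10:15]))
  F <- encode_cn(d$profiles, "ordinal")
  loss <- F$values[, F$meta$channel == "loss"]
  expect_true(all(loss[, 10:15] == 0.5))
})

test_that("adjusted Rand matches its pair-counting definition", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(33)
  for (i in 1:8) {
    n <- sample(6:14, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand(a, b), ari_bruteforce(a, b),
                 tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
  }
  expect_error(adjusted_rand(1:3, 1:4), "lengths")
})
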