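test_that("KL divergence matches the closed form and its conventions", {
  # exact factorization -> 0
  W <- matrix(c(1, 2)); H <- matrix(c(1, 2), 1)
  expect_equal(kl_divergence(W %*% H, W, H), 0, tolerance = 1e-12)
  # single entry: 2*log(2) - 2 + 1
  expect_equal(kl_divergence(matrix(2), matrix(1), matrix(1)),
               2 * log(2) - 1, tolerance = 1e-12)
  # 0 log 0 term vanishes: V=0, WH=1 -> 1
  expect_equal(kl_divergence(matrix(0), matrix(1), matrix(1)), 1)
  # V > 0 over an exactly-zero (WH) -> +Inf by limit
  expect_equal(kl_divergence(matrix(1), matrix(0), matrix(0)), Inf)
  expect_error(kl_divergence(matrix(1, 2, 2), matrix(1, 3, 1), matrix(1)),
               "conformable")
})

test_that("KL divergence agrees with an independent reference on random inputs", {
  set.seed(7)
  for (i in 1:10) {
    m <- sample(2:6, 1); n <- sample(2:8, 1); k <- sample(1:3, 1)
    V <- matrix(rpois(m * n, 2), m, n)
    W <- matrix(runif(m * k, 0.1, 2), m, k)
    H <- matrix(runif(k * n, 0.1, 2), k, n)
    expect_equal(kl_divergence(V, W, H), kl_ref(V, W, H),
                 tolerance = 1e-10)
  }
})

test_that("multiplicative update fixes exact factorizations and matches a hand trace", {
  # exact rank-1 factorization is a fixed point
  V <- matrix(c(1, 2, 2, 4), 2, 2)
  W <- matrix(c(1, 2)); H <- matrix(c(1, 2), 1)
  up <- nmf_update(V, W, H)
  expect_equal(up$W, W, tolerance = 1e-12)
  expect_equal(up$H, H, tolerance = 1e-12)

  # one-step hand trace on the 2x2 identity
  V2 <- diag(2)
  up2 <- nmf_update(V2, matrix(c(1, 1)), matrix(c(1, 1), 1))
  expect_equal(unname(up2$H), matrix(c(0.5, 0.5), 1), tolerance = 1e-12)
  expect_equal(unname(up2$W), matrix(c(1, 1)), tolerance = 1e-12)
  expect_equal(kl_divergence(V2, up2$W, up2$H), 2 * log(2),
               tolerance = 1e-12)
})

test_that("update step never increases the divergence", {
  set.seed(13)
  for (i in 1:10) {
    m <- sample(3:10, 1); n <- sample(3:15, 1); k <- sample(1:3, 1)
    V <- matrix(rpois(m * n, 3), m, n)
    W <- matrix(runif(m * k), m, k); H <- matrix(runif(k * n), k, n)
    for (it in 1:20) {
      d0 <- kl_divergence(V, W, H)
      up <- nmf_update(V, W, H); W <- up$W; H <- up$H
      d1 <- kl_divergence(V, W, H)
      expect_lte(d1, d0 * (1 + 1e-12) + 1e-12)
    }
  }
})

test_that("compiled loop agrees with the R update step", {
  set.seed(21)
  V <- matrix(rpois(30, 2), 5, 6)
  fit1 <- nmf_factorize(V, 2, seed = 3, max_iter = 1L, tol = 0)
  init <- cnmf:::.with_seed(3, list(W = matrix(runif(10), 5, 2),
                                    H = matrix(runif(12), 2, 6)))
  up <- nmf_update(V, init$W, init$H)
  expect_equal(unname(fit1$W), unname(up$W), tolerance = 1e-12)
  expect_equal(unname(fit1$H), unname(up$H), tolerance = 1e-12)
})

test_that("factorization recovers exact low-rank structure and is deterministic", {
  V <- outer(c(1, 2, 3), c(2, 1, 4, 3))
  fit <- nmf_factorize(V, 1, seed = 5)
  expect_lte(fit$divergence, 1e-6)
  fit2 <- nmf_factorize(V, 1, seed = 5)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$H, fit2$H)
  expect_identical(fit$divergence, fit2$divergence)
  # achieved divergence is reported on the factorized matrix
  expect_equal(fit$divergence, kl_divergence(V, fit$W, fit$H),
               tolerance = 1e-10)
  expect_error(nmf_factorize(V, 10, seed = 1), "rank")
  expect_error(nmf_factorize(matrix(c(1, NA), 1, 2), 1), "finite")
})

test_that("divergence trace is non-increasing on random problems", {
  set.seed(31)
  for (i in 1:5) {
    V <- matrix(rpois(20 * 30, 2), 20, 30)
    fit <- nmf_factorize(V, sample(2:4, 1), seed = i, max_iter = 100,
                         tol = 0, track = TRUE)
    d <- fit$trace
    expect_true(all(diff(d) <= 1e-12 * pmax(1, d[-length(d)])))
  }
})

test_that("compact H expansion divides bin columns by bin size", {
  P <- structure(list(bins = list(c(1L, 2L), 3L), representative = c(1L, 3L),
                      delta = 0L, window = Inf), class = "bin_partition")
  expect_equal(expand_h(matrix(c(2, 2), 1), P), matrix(c(1, 1, 2), 1))
  P2 <- structure(list(bins = list(c(1L, 2L)), representative = 1L,
                       delta = 0L, window = Inf), class = "bin_partition")
  expect_equal(expand_h(matrix(c(4, 6), 2, 1), P2),
               matrix(c(2, 3, 2, 3), 2, 2))
  Psing <- structure(list(bins = list(1L, 2L), representative = 1:2,
                          delta = 0L, window = Inf), class = "bin_partition")
  Hc <- matrix(1:4, 2)
  expect_equal(expand_h(Hc, Psing), unname(Hc))
  expect_error(expand_h(matrix(1:6, 2, 3), P), "bins")
})

test_that("full-matrix divergence identities hold for lossless bins", {
  # identical bin columns: expanded divergence equals compacted divergence
  v <- c(1, 2); u <- c(2, 0)
  F <- plain_fm(cbind(v, v, u))
  P <- build_partition(F, 0, Inf)
  W <- matrix(c(1, 2)); Hc <- matrix(c(2, 2), 1)
  expect_equal(full_divergence(F, W, Hc, P, "compact"),
               kl_divergence(compact_columns(F, P), W, Hc),
               tolerance = 1e-12)
  # all-singleton partition: compact and standard coincide
  Psing <- structure(list(bins = list(1L, 2L, 3L), representative = 1:3,
                          delta = 0L, window = Inf), class = "bin_partition")
  Hc3 <- matrix(c(1, 2, 1), 1)
  expect_equal(full_divergence(F, W, Hc3, Psing, "compact"),
               full_divergence(F, W, Hc3, Psing, "standard"))
  # standard mode replicates the representative column without division
  H_rep <- Hc[, c(1, 1, 2), drop = FALSE]
  expect_equal(full_divergence(F, W, matrix(c(2, 2), 1), P, "standard"),
               kl_divergence(F$values, W, H_rep))
})

test_that("full divergence is invariant under consistent column permutation", {
  set.seed(17)
  F <- plain_fm(matrix(rpois(6 * 8, 2), 6, 8))
  P <- build_partition(F, 1, Inf)
  fit <- nmf_factorize(compact_columns(F, P), 2, seed = 1)
  d <- full_divergence(F, fit$W, fit$H, P, "compact")
  perm <- sample(8)
  Fp <- plain_fm(F$values[, perm])
  inv <- order(perm)
  Pp <- structure(list(bins = lapply(P$bins, function(b) inv[b]),
                       representative = inv[P$representative],
                       delta = P$delta, window = Inf),
                  class = "bin_partition")
  expect_equal(full_divergence(Fp, fit$W, fit$H, Pp, "compact"), d,
               tolerance = 1e-12)
})

test_that("divergence ratio is 1 for the lossless compaction", {
  set.seed(19)
  F <- plain_fm(matrix(rpois(8 * 12, 2), 8, 12)[, rep(1:6, each = 2)])
  P0 <- build_partition(F, 0, Inf)
  expect_equal(divergence_ratio(F, P0, 2, seeds = 1:2, mode = "compact"),
               1, tolerance = 1e-9)
  # single seed, reference identical to the run under test -> exactly 1
  expect_equal(divergence_ratio(F, P0, 3, seeds = 5, mode = "compact"), 1)
})
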