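test_that("pair counts match the brute-force enumerator", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(4:12, 1))
    m1 <- withr::with_seed(s * 2, sample(1:3, n, replace = TRUE))
    m2 <- withr::with_seed(s * 3, sample(1:4, n, replace = TRUE))
    got <- pair_counts(m1, m2)
    ref <- oracle_pair_counts(m1, m2)
    expect_equal(got[c("a", "b", "c", "d")], ref)
    expect_equal(got$a + got$b + got$c + got$d, n * (n - 1) / 2)
  }
})

test_that("degenerate benchmark partitions produce the expected counts", {
  # identical partitions: no disagreeing pairs
  pc <- pair_counts(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(pc$b + pc$c, 0L)
  expect_equal(pc$a + pc$d, 6L)
  # all-singleton benchmark: no co-clustered pairs in partition 1
  pc2 <- pair_counts(1:4, c(1, 1, 2, 2))
  expect_equal(pc2$a, 0L)
  expect_equal(pc2$b, 0L)
  expect_error(pair_counts(1, 1), "at least 2")
  expect_error(pair_counts(c(a = 1, b = 2), c(a = 1, x = 2)),
               "different node sets")
})

test_that("the five indices follow their formulas, degenerate cases included", {
  perfect <- comparison_indices(list(a = 5, b = 0, c = 0, d = 3))
  expect_equal(unlist(perfect),
               c(rand = 1, jaccard = 1, dice = 1, fowlkes_mallows = 1,
                 minkowski = 0))
  mid <- comparison_indices(list(a = 2, b = 1, c = 1, d = 2))
  expect_equal(mid$rand, 4 / 6)
  expect_equal(mid$jaccard, 0.5)
  expect_equal(mid$dice, 2 / 3)
  expect_equal(mid$fowlkes_mallows, 2 / sqrt(9))
  expect_equal(mid$minkowski, sqrt(2 / 3))
  worst <- comparison_indices(list(a = 0, b = 1, c = 1, d = 1))
  expect_equal(worst$rand, 1 / 3)
  expect_equal(worst$jaccard, 0)
  expect_equal(worst$dice, 0)
  expect_equal(worst$fowlkes_mallows, 0)
  expect_equal(worst$minkowski, sqrt(2))
  # a + b = 0 leaves Minkowski undefined
  expect_true(is.na(comparison_indices(list(a = 0, b = 0, c = 2, d = 1))$minkowski))
})

test_that("indices agree with direct formula evaluation on random partitions", {
  for (s in 1:10) {
    n <- 12
    m1 <- withr::with_seed(s + 50, sample(1:3, n, replace = TRUE))
    m2 <- withr::with_seed(s + 90, sample(1:3, n, replace = TRUE))
    pc <- oracle_pair_counts(m1, m2)
    idx <- comparison_indices(pair_counts(m1, m2))
    with(pc, {
      expect_equal(idx$rand, (a + d) / (a + b + c + d))
      if (a + b + c > 0) expect_equal(idx$jaccard, a / (a + b + c))
      if (a > 0)
        expect_equal(idx$fowlkes_mallows, a / sqrt((a + b) * (a + c)))
    })
  }
})

test_that("a missing-free matrix validates every method as perfect", {
  sim <- simulate_bipartite(15, 12,
                            list(type = "modular", k = 2, mu_in = 8,
                                 mu_out = 1, sigma = 0.3), seed = 5)
  v <- validate_edge_prediction(sim$matrix, seed = 3)
  expect_true(all(v$indices$rand == 1))
  expect_true(all(v$indices$jaccard == 1))
  expect_true(all(v$indices$dice == 1))
  expect_true(all(v$indices$fowlkes_mallows == 1))
  expect_true(all(v$indices$minkowski == 0))
  expect_setequal(v$ranking, c("mean", "median", "ca", "als"))
})

test_that("method order does not change per-method indices, and runs reproduce", {
  sim <- simulate_bipartite(20, 15,
                            list(type = "modular", k = 2, mu_in = 10,
                                 mu_out = 1, sigma = 0.5), seed = 8)
  M <- apply_missingness(sim$matrix, list(type = "mcar", rate = 0.1), seed = 9)
  v1 <- validate_edge_prediction(M, methods = c("mean", "als"), seed = 13)
  v2 <- validate_edge_prediction(M, methods = c("als", "mean"), seed = 13)
  for (mth in c("mean", "als"))
    expect_equal(v1$indices[v1$indices$method == mth, -1],
                 v2$indices[v2$indices$method == mth, -1],
                 ignore_attr = TRUE)
  v3 <- validate_edge_prediction(M, methods = c("mean", "als"), seed = 13)
  expect_identical(v1$indices, v3$indices)
  expect_identical(v1$ranking, v3$ranking)
})
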