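# Packing, nestedness temperature, modularity.

staircase <- function(k, n) {
  t(vapply(k, function(ki) seq_len(n) <= ki, logical(n)))
}

test_that("an already packed staircase keeps identity permutations", {
  P <- staircase(c(4, 3, 2, 1), 4)
  pk <- pack_matrix(P)
  expect_equal(pk$row_order, 1:4)
  expect_equal(pk$col_order, 1:4)
  expect_equal(pk$fill, 10 / 16)
})

test_that("a reversed staircase packs by reversing rows and columns", {
  P <- staircase(c(4, 3, 2, 1), 4)
  pk <- pack_matrix(P[4:1, 4:1])
  expect_equal(pk$row_order, 4:1)
  expect_equal(pk$col_order, 4:1)
  expect_identical(pk$packed, P)
})

test_that("packing is deterministic under ties", {
  P <- matrix(c(1, 0, 1,
                0, 1, 1,
                1, 1, 0) == 1, 3, 3, byrow = TRUE)
  pk1 <- pack_matrix(P)
  pk2 <- pack_matrix(P)
  expect_identical(pk1$row_order, pk2$row_order)
  expect_identical(pk1$col_order, pk2$col_order)
  # marginal counts are non-increasing after packing
  expect_true(all(diff(rowSums(pk1$packed)) <= 0))
  expect_true(all(diff(colSums(pk1$packed)) <= 0))
})

test_that("temperature is 0 for full, empty-complement and canonical nested matrices", {
  expect_equal(nestedness_temperature(matrix(TRUE, 3, 4))$T, 0)
  sim <- simulate_bipartite(12, 9, list(type = "nested", p = 0.4), seed = 2)
  expect_equal(nestedness_temperature(sim$matrix)$T, 0)
  expect_equal(nestedness_temperature(incidence_mask(sim$matrix))$T, 0)
})

test_that("temperature matches the geometric brute-force oracle", {
  # 4x4 checkerboard plus assorted random masks
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_equal(nestedness_temperature(cb)$T, oracle_temperature(cb),
               tolerance = 1e-9)
  for (s in 1:25) {
    withr::with_seed(100 + s, {
      m <- sample(4:8, 1)
      n <- sample(4:8, 1)
      P <- matrix(runif(m * n) < runif(1, 0.2, 0.8), m, n)
    })
    if (sum(P) %in% c(0, m * n)) next
    expect_equal(nestedness_temperature(P)$T, oracle_temperature(P),
                 tolerance = 1e-9)
  }
})

test_that("temperature is invariant under row+column permutation and bounded", {
  for (s in 1:10) {
    P <- withr::with_seed(200 + s, matrix(runif(30) < 0.5, 5, 6))
    if (sum(P) %in% c(0, 30)) next
    t0 <- nestedness_temperature(P)$T
    Pp <- withr::with_seed(s, P[sample(5), sample(6)])
    expect_equal(nestedness_temperature(Pp)$T, t0, tolerance = 1e-9)
    expect_gte(t0, 0)
    expect_lte(t0, 100)
  }
})

test_that("perturbing a perfect staircase strictly raises the temperature", {
  for (p in c(0.3, 0.5, 0.7)) {
    sim <- simulate_bipartite(6, 6, list(type = "nested", p = p), seed = 300)
    P <- incidence_mask(sim$matrix)
    # swap the deep inside corner with the deep outside corner: the result
    # is not a row/column permutation of any staircase, so T must rise
    stopifnot(P[1, 1], !P[6, 6])
    P[1, 1] <- FALSE
    P[6, 6] <- TRUE
    t1 <- nestedness_temperature(P)$T
    expect_gt(t1, 0)
    expect_equal(t1, oracle_temperature(P), tolerance = 1e-9)
  }
})

test_that("temperature rejects degenerate one-line matrices", {
  expect_error(nestedness_temperature(matrix(c(TRUE, FALSE), 1, 2)),
               "degenerate")
})

test_that("modularity of hand-checked partitions", {
  # two disconnected 3-cliques: component partition has Q = 0.5, the
  # all-in-one partition 0
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::E(g)$weight <- 1
  mem <- rep(1:2, each = 3)
  expect_equal(network_modularity(g, mem), 0.5)
  expect_equal(network_modularity(g, rep(1, 6)), 0)
})

test_that("random balanced partitions of random graphs score near zero", {
  for (s in 1:5) {
    g <- withr::with_seed(s, igraph::sample_gnp(60, 0.2))
    igraph::E(g)$weight <- 1
    mem <- withr::with_seed(s, sample(rep(1:2, each = 30)))
    expect_lt(abs(network_modularity(g, mem)), 0.2)
  }
})
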