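test_that("identical spec and seed reproduce the matrix exactly", {
  spec <- list(type = "modular", k = 3, mu_in = 10, mu_out = 1, sigma = 0.5)
  a <- simulate_bipartite(25, 20, spec, seed = 7)
  b <- simulate_bipartite(25, 20, spec, seed = 7)
  expect_identical(a$matrix$A, b$matrix$A)
  expect_identical(a$truth, b$truth)
  c <- simulate_bipartite(25, 20, spec, seed = 8)
  expect_false(identical(a$matrix$A, c$matrix$A))
})

test_that("the nested generator is exactly the zero-temperature staircase", {
  sim <- simulate_bipartite(14, 10, list(type = "nested", p = 0.5), seed = 1)
  expect_equal(nestedness_temperature(sim$matrix)$T, 0)
  expect_equal(sum(incidence_mask(sim$matrix)), round(0.5 * 140))
  k <- rowSums(incidence_mask(sim$matrix))
  expect_true(all(diff(k) <= 0))  # non-increasing prefixes
})

test_that("random 30x30 matrices sit far from nestedness", {
  temps <- vapply(1:60, function(s) {
    sim <- simulate_bipartite(30, 30, list(type = "random", p = 0.5), seed = s)
    nestedness_temperature(sim$matrix)$T
  }, numeric(1))
  expect_gt(mean(temps), 20)
})

test_that("MCAR masking hits its nominal rate within binomial error", {
  sim <- simulate_bipartite(40, 30, list(type = "modular", k = 2, mu_in = 10,
                                         mu_out = 1, sigma = 0.5), seed = 3)
  for (rate in c(0.1, 0.3)) {
    masked <- apply_missingness(sim$matrix, list(type = "mcar", rate = rate),
                                seed = 17)
    n <- 40 * 30
    got <- sum(is.na(masked$A)) / n
    se <- sqrt(rate * (1 - rate) / n)
    expect_lt(abs(got - rate), 3 * se)
  }
  unchanged <- apply_missingness(sim$matrix, list(type = "mcar", rate = 0),
                                 seed = 17)
  expect_identical(unchanged$A, sim$matrix$A)
})

test_that("block masking removes exactly the listed region", {
  sim <- simulate_bipartite(40, 30, list(type = "modular", k = 2, mu_in = 10,
                                         mu_out = 1, sigma = 0.5), seed = 4)
  masked <- apply_missingness(sim$matrix,
                              list(type = "block",
                                   regions = list(list(rows = 1:10,
                                                       cols = 5:14))))
  expect_equal(sum(is.na(masked$A)), 100L)
  expect_true(all(is.na(masked$A[1:10, 5:14])))
  expect_error(
    apply_missingness(sim$matrix,
                      list(type = "block",
                           regions = list(list(rows = 1:40, cols = 1:30)))),
    "mask every")
})

test_that("value-threshold censoring concentrates missingness between blocks", {
  # tau between mu_out and mu_in censors (essentially only) the weak
  # between-block cells: missingness aligned with the planted structure,
  # i.e. MNAR, unlike an MCAR scatter at the same rate
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_bipartite(30, 24, list(type = "modular", k = 2, mu_in = 10,
                                           mu_out = 1, sigma = 0.5),
                              seed = 4000 + s)
    between <- outer(sim$truth$row_blocks, sim$truth$col_blocks, "!=")
    mnar <- apply_missingness(sim$matrix, list(type = "threshold", tau = 5))
    masked <- is.na(mnar$A)
    expect_gte(mean(between[masked]), 0.99)
    rate <- mean(masked)
    mcar <- apply_missingness(sim$matrix, list(type = "mcar", rate = rate),
                              seed = 5000 + s)
    # the MCAR control spreads its holes across both regions
    expect_lt(mean(between[is.na(mcar$A)]), 0.75)
  }
})

test_that("clustering the clean modular projection recovers the planted blocks", {
  for (s in 1:5) {
    sim <- simulate_bipartite(40, 30, list(type = "modular", k = 2, mu_in = 10,
                                           mu_out = 1, sigma = 0.5),
                              seed = 6000 + s)
    cl <- find_clusters(project(sim$matrix, "rows"), "multilevel", seed = 1)[[1]]
    truth <- setNames(sim$truth$row_blocks, rownames(sim$matrix$A))
    expect_equal(external_validation(cl$membership, truth)$rand, 1)
  }
})
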