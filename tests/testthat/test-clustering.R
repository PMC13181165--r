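two_cliques <- function(k = 5, bridge = FALSE, w_in = 10, w_bridge = 1) {
  g <- igraph::make_full_graph(k) + igraph::make_full_graph(k)
  igraph::E(g)$weight <- w_in
  if (bridge) g <- igraph::add_edges(g, c(1, k + 1), attr = list(weight = w_bridge))
  igraph::V(g)$name <- paste0("n", seq_len(2 * k))
  g
}

test_that("all seven methods recover the components of two disconnected cliques", {
  g <- two_cliques(5)
  res <- find_clusters(g, "all", seed = 11)
  expect_named(res, c("walktrap", "multilevel", "infomap", "label_propagation",
                      "leading_eigenvector", "spinglass", "fast_greedy"))
  truth <- rep(1:2, each = 5)
  for (r in res) {
    expect_equal(length(unique(r$membership)), 2L)
    ev <- external_validation(r$membership,
                              setNames(truth, igraph::V(g)$name))
    expect_equal(ev$rand, 1)
    expect_equal(ev$jaccard, 1)
    expect_equal(r$Q, 0.5)
  }
})

test_that("modularity-based methods split two bridged cliques at the bridge", {
  g <- two_cliques(5, bridge = TRUE)
  truth <- setNames(rep(1:2, each = 5), igraph::V(g)$name)
  for (mth in c("walktrap", "multilevel", "leading_eigenvector", "fast_greedy")) {
    r <- find_clusters(g, mth, seed = 2)[[1]]
    expect_equal(external_validation(r$membership, truth)$rand, 1,
                 info = mth)
  }
})

test_that("a uniform complete graph carries no community structure", {
  g <- igraph::make_full_graph(8)
  igraph::E(g)$weight <- 1
  for (mth in c("multilevel", "label_propagation")) {
    r <- find_clusters(g, mth, seed = 5)[[1]]
    expect_equal(length(unique(r$membership)), 1L, info = mth)
    expect_equal(r$Q, 0, info = mth)
    expect_true(is.na(r$asw))  # single cluster: silhouette undefined
  }
  # agglomerative merging may stop one step early on fully tied graphs,
  # but the modularity it finds stays pinned at (or just below) zero
  fg <- find_clusters(g, "fast_greedy", seed = 5)[[1]]
  expect_lte(fg$Q, 0)
  expect_gt(fg$Q, -0.05)
})

test_that("unknown methods are rejected and deterministic methods reproduce", {
  g <- two_cliques(4)
  expect_error(find_clusters(g, "kmeans"), "unknown clustering method")
  a <- find_clusters(g, c("fast_greedy", "multilevel", "walktrap"), seed = 3)
  b <- find_clusters(g, c("fast_greedy", "multilevel", "walktrap"), seed = 3)
  for (mth in names(a))
    expect_identical(a[[mth]]$membership, b[[mth]]$membership)
})

test_that("silhouette matches the reference implementation on the graph metric", {
  skip_if_not_installed("cluster")
  g <- two_cliques(5, bridge = TRUE)
  mem <- rep(1:2, each = 5)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  fin <- d[is.finite(d)]
  d[!is.finite(d)] <- 2 * max(fin)
  ref <- mean(cluster::silhouette(mem, dmatrix = d)[, "sil_width"])
  expect_equal(silhouette_score(g, mem), ref, tolerance = 1e-9)
  # disconnected cliques, clique partition: between-distance is the
  # unreachable penalty (2x diameter), within-distance 1/w
  g2 <- two_cliques(5)
  s2 <- silhouette_score(g2, mem)
  d2 <- igraph::distances(g2, weights = 1 / igraph::E(g2)$weight)
  fin2 <- d2[is.finite(d2)]
  d2[!is.finite(d2)] <- 2 * max(fin2)
  ref2 <- mean(cluster::silhouette(mem, dmatrix = d2)[, "sil_width"])
  expect_equal(s2, ref2, tolerance = 1e-9)
  expect_gt(s2, 0)
})

test_that("random partitions of a uniform complete graph never score positive", {
  g <- igraph::make_full_graph(10)
  igraph::E(g)$weight <- 1
  for (s in 1:5) {
    mem <- withr::with_seed(s, sample(rep(1:2, 5)))
    expect_lte(silhouette_score(g, mem), 0)
  }
})

test_that("all-singleton partitions score zero by convention", {
  g <- two_cliques(3)
  expect_equal(silhouette_score(g, seq_len(6)), 0)
})

test_that("external validation pair counting on hand-enumerated cases", {
  # {a,b}{c} vs {a}{b,c}: a=0, b=1, c=1, d=1
  ev <- external_validation(c(a = 1, b = 2, c = 2), c(a = 1, b = 1, c = 2))
  expect_equal(ev$rand, 1 / 3)
  expect_equal(ev$jaccard, 0)
  # one big cluster vs all singletons on 3 nodes
  ev2 <- external_validation(1:3, rep(1, 3))
  expect_equal(ev2$rand, 0)
  expect_equal(ev2$jaccard, 0)
  # identical partitions
  ev3 <- external_validation(c(1, 1, 2, 2), c(5, 5, 9, 9))
  expect_equal(ev3$rand, 1)
  expect_equal(ev3$jaccard, 1)
  # symmetry of both indices
  m1 <- c(1, 1, 2, 2, 3)
  m2 <- c(1, 2, 2, 3, 3)
  expect_equal(external_validation(m1, m2), external_validation(m2, m1))
})
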