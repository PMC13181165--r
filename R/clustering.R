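#' Community detection on a projected network
#'
#' Runs any subset of seven community-detection algorithms (walktrap,
#' multilevel/Louvain, infomap, label propagation, leading eigenvector,
#' spinglass, fast greedy) on a weighted projection graph and scores every
#' partition by its Newman modularity and average silhouette width.
#' Stochastic algorithms are run under `seed`, so results are reproducible;
#' the caller-visible RNG state is untouched. Spinglass requires a connected
#' graph and is therefore run per connected component, with cluster ids
#' offset across components.
#'
#' @param G a `projection_graph` from [project()] (or an igraph).
#' @param methods character vector drawn from `"walktrap"`, `"multilevel"`,
#'   `"infomap"`, `"label_propagation"`, `"leading_eigenvector"`,
#'   `"spinglass"`, `"fast_greedy"`, or `"all"`.
#' @param seed integer seed applied before each algorithm.
#' @return A named list of `clustering_result` objects, each with `method`,
#'   `membership` (named integer vector), `Q`, `asw`, `seed`.
#' @export
find_clusters <- function(G, methods = "all", seed = 1L) {
  g <- as_igraph(G)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  all_methods <- c("walktrap", "multilevel", "infomap", "label_propagation",
                   "leading_eigenvector", "spinglass", "fast_greedy")
  if (identical(methods, "all")) methods <- all_methods
  unknown <- setdiff(methods, all_methods)
  if (length(unknown) > 0L)
    stop("unknown clustering method(s): ", paste(unknown, collapse = ", "))
  out <- lapply(methods, function(mth) {
    mem <- with_seed(seed, run_method(g, mth))
    names(mem) <- igraph::V(g)$name
    Q <- if (igraph::ecount(g) > 0L)
      igraph::modularity(g, mem, weights = igraph::E(g)$weight)
    else NA_real_
    structure(list(method = mth, membership = mem, Q = Q,
                   asw = silhouette_score(g, mem), seed = seed),
              class = "clustering_result")
  })
  names(out) <- methods
  out
}

run_method <- function(g, method) {
  w <- if (igraph::ecount(g) > 0L) igraph::E(g)$weight else NULL
  cl <- switch(method,
    walktrap = igraph::cluster_walktrap(g, weights = w),
    multilevel = igraph::cluster_louvain(g, weights = w),
    infomap = igraph::cluster_infomap(g, e.weights = w),
    label_propagation = igraph::cluster_label_prop(g, weights = w),
    leading_eigenvector = igraph::cluster_leading_eigen(g, weights = w),
    fast_greedy = igraph::cluster_fast_greedy(g, weights = w),
    spinglass = return(spinglass_components(g))
  )
  as.integer(igraph::membership(cl))
}

# spinglass cannot handle disconnected graphs: run it per component and
# offset the cluster ids.
spinglass_components <- function(g) {
  comp <- igraph::components(g)
  mem <- integer(igraph::vcount(g))
  offset <- 0L
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    sub <- igraph::induced_subgraph(g, idx)
    sub_mem <- if (length(idx) == 1L || igraph::ecount(sub) == 0L)
      rep(1L, length(idx))
    else as.integer(igraph::membership(
      igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight)))
    mem[idx] <- sub_mem + offset
    offset <- offset + max(sub_mem)
  }
  mem
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("%s: %d clusters, Q = %.4f, asw = %s\n", x$method,
              length(unique(x$membership)), x$Q,
              ifelse(is.na(x$asw), "NA", sprintf("%.4f", x$asw))))
  invisible(x)
}

#' Average silhouette width of a graph partition
#'
#' Internal cluster validation on the graph's own metric space: pairwise
#' node distances are shortest-path lengths with edge length 1/weight
#' (strong edges are short); pairs in different components are assigned
#' twice the graph's finite diameter. Silhouette terms follow the standard
#' definition, with singleton clusters contributing 0 by convention.
#'
#' @param G a `projection_graph` or igraph.
#' @param membership cluster assignment (named or in vertex order).
#' @return The average silhouette width in \[-1, 1\], or `NA` when fewer
#'   than two clusters are present (a single cluster has no defined score).
#' @export
silhouette_score <- function(G, membership) {
  g <- as_igraph(G)
  mem <- align_membership(membership, g)
  if (length(unique(mem)) < 2L) return(NA_real_)
  w <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(w)) 1 / w else NULL)
  finite <- d[is.finite(d)]
  penalty <- if (length(finite) > 0L && max(finite) > 0) 2 * max(finite) else 1
  d[!is.finite(d)] <- penalty
  nv <- nrow(d)
  ids <- sort(unique(mem))
  # mean distance from every node to every cluster
  cl_mean <- vapply(ids, function(k) {
    idx <- mem == k
    rowSums(d[, idx, drop = FALSE]) / sum(idx)
  }, numeric(nv))
  sizes <- tabulate(match(mem, ids))
  s <- numeric(nv)
  for (v in seq_len(nv)) {
    k <- match(mem[v], ids)
    if (sizes[k] == 1L) { s[v] <- 0; next }
    a <- cl_mean[v, k] * sizes[k] / (sizes[k] - 1L)  # exclude self (d=0)
    b <- min(cl_mean[v, -k])
    s[v] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' External validation of a clustering against known labels
#'
#' Pair-counting comparison of a candidate partition with prior-knowledge
#' labels: over all node pairs, `a` co-clustered in both, `b` co-clustered
#' in the truth only, `c` in the candidate only, `d` in neither. Returns
#' Rand = (a+d)/(a+b+c+d) and Jaccard = a/(a+b+c).
#'
#' @param membership candidate partition (named vector or in node order).
#' @param truth_labels reference labels over the same nodes.
#' @return A list with `jaccard` and `rand`.
#' @export
external_validation <- function(membership, truth_labels) {
  pc <- pair_counts(truth_labels, membership)
  idx <- comparison_indices(pc)
  list(jaccard = idx$jaccard, rand = idx$rand)
}
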