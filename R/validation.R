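#' Pair counts between two partitions
#'
#' The contingency underlying all pair-counting agreement indices: over the
#' \eqn{n(n-1)/2} unordered node pairs, `a` are co-clustered in both
#' partitions, `b` only in the first (the benchmark), `c` only in the
#' second, `d` in neither.
#'
#' @param membership1 benchmark partition (named vector, or aligned with
#'   `membership2`).
#' @param membership2 candidate partition.
#' @param shared_nodes optional node names to restrict both partitions to.
#' @return A list of class `pair_counts` with integers `a`, `b`, `c`, `d`.
#' @export
pair_counts <- function(membership1, membership2, shared_nodes = NULL) {
  if (!is.null(shared_nodes)) {
    if (is.null(names(membership1)) || is.null(names(membership2)))
      stop("named memberships are required to use 'shared_nodes'")
    if (!all(shared_nodes %in% names(membership1)) ||
        !all(shared_nodes %in% names(membership2)))
      stop("'shared_nodes' not covered by both memberships")
    membership1 <- membership1[shared_nodes]
    membership2 <- membership2[shared_nodes]
  } else if (!is.null(names(membership1)) && !is.null(names(membership2))) {
    if (!setequal(names(membership1), names(membership2)))
      stop("memberships are defined on different node sets")
    membership2 <- membership2[names(membership1)]
  } else if (length(membership1) != length(membership2)) {
    stop("memberships are defined on different node sets")
  }
  n <- length(membership1)
  if (n < 2L) stop("need at least 2 shared nodes")
  upper <- upper.tri(matrix(0, n, n))
  same1 <- outer(membership1, membership1, "==")[upper]
  same2 <- outer(membership2, membership2, "==")[upper]
  structure(list(a = sum(same1 & same2), b = sum(same1 & !same2),
                 c = sum(!same1 & same2), d = sum(!same1 & !same2)),
            class = "pair_counts")
}

#' Pair-counting agreement indices
#'
#' The five indices used to compare a candidate clustering against the
#' complete-submatrix benchmark: Rand \eqn{(a+d)/(a+b+c+d)}, Jaccard
#' \eqn{a/(a+b+c)}, Sorensen-Dice \eqn{2a/(2a+b+c)}, Fowlkes-Mallows
#' \eqn{a/\sqrt{(a+b)(a+c)}} and Minkowski \eqn{\sqrt{(b+c)/(a+b)}} (the
#' only one where lower is better). Degenerate denominators yield 0 for
#' Jaccard/Dice/Fowlkes-Mallows and `NA` for Minkowski when `a + b = 0`.
#'
#' @param pc a `pair_counts` object (or list with `a`, `b`, `c`, `d`).
#' @return A list with `rand`, `jaccard`, `dice`, `fowlkes_mallows`,
#'   `minkowski`.
#' @export
comparison_indices <- function(pc) {
  a <- pc$a; b <- pc$b; cc <- pc$c; d <- pc$d
  stopifnot(all(c(a, b, cc, d) >= 0))
  list(
    rand = (a + d) / (a + b + cc + d),
    jaccard = if (a + b + cc == 0) 0 else a / (a + b + cc),
    dice = if (2 * a + b + cc == 0) 0 else 2 * a / (2 * a + b + cc),
    fowlkes_mallows = if (a == 0) 0 else a / sqrt((a + b) * (a + cc)),
    minkowski = if (a + b == 0) NA_real_ else sqrt((b + cc) / (a + b))
  )
}

#' Validate imputation methods by structure preservation
#'
#' Scores each imputation method by whether clustering the imputed network
#' reproduces the clustering of the complete-submatrix benchmark:
#' (1) extract the `Rectangular_element_max` complete submatrix;
#' (2) project its `part` and cluster it — the benchmark partition;
#' (3) impute the full matrix with each method, project, cluster with the
#' *same* algorithm and seed (so differences reflect imputation, not
#' algorithm stochasticity), and restrict the partition to the benchmark's
#' node set; (4) compute the five pair-counting indices per method;
#' (5) rank methods by `rank_index` (Minkowski inverted).
#'
#' A matrix without missing cells is allowed and yields perfect indices for
#' every method. If the benchmark clustering is degenerate (a single
#' cluster), indices are reported as `NA` and no ranking is produced.
#'
#' @param M an [incidence_matrix].
#' @param methods imputation methods to score.
#' @param part node set to project, `"rows"` or `"cols"`.
#' @param cluster_method one of the [find_clusters()] algorithms.
#' @param seed seed shared by the benchmark and every candidate clustering.
#' @param rank_index index used for the ranking (default `"jaccard"`).
#' @param ... extra parameters for the imputation methods.
#' @return A list of class `edge_validation`: `indices` (data frame, one
#'   row per method), `ranking` (methods best-first, or `NULL`),
#'   `benchmark` (node names, membership and submatrix dimensions).
#' @export
validate_edge_prediction <- function(M,
                                     methods = c("mean", "median", "ca", "als"),
                                     part = c("rows", "cols"),
                                     cluster_method = "multilevel",
                                     seed = 1L,
                                     rank_index = "jaccard", ...) {
  stopifnot(inherits(M, "incidence_matrix"))
  part <- match.arg(part)
  sub <- extract_submatrix(M, "Rectangular_element_max")
  bench_nodes <- if (part == "rows") sub$row_names else sub$col_names
  if (length(bench_nodes) < 3L)
    stop("complete-submatrix benchmark too small (< 3 nodes)")
  bench_cl <- find_clusters(project(sub$block, part), cluster_method,
                            seed = seed)[[1L]]
  bench_mem <- bench_cl$membership
  degenerate <- length(unique(bench_mem)) < 2L
  if (degenerate)
    warning("benchmark clustering is a single cluster; indices undefined")

  rows <- lapply(methods, function(mth) {
    comp <- impute_edges(M, mth, seed = seed, ...)
    # imputed values are continuous even for binary input
    Mi <- incidence_matrix(comp$values, weighted = TRUE)
    cl <- find_clusters(project(Mi, part), cluster_method, seed = seed)[[1L]]
    if (degenerate) {
      idx <- list(rand = NA_real_, jaccard = NA_real_, dice = NA_real_,
                  fowlkes_mallows = NA_real_, minkowski = NA_real_)
    } else {
      pc <- pair_counts(bench_mem, cl$membership, shared_nodes = bench_nodes)
      idx <- comparison_indices(pc)
    }
    data.frame(method = mth, rand = idx$rand, jaccard = idx$jaccard,
               dice = idx$dice, fowlkes_mallows = idx$fowlkes_mallows,
               minkowski = idx$minkowski)
  })
  indices <- do.call(rbind, rows)
  ranking <- if (degenerate) NULL else {
    key <- indices[[rank_index]]
    if (rank_index == "minkowski") key <- -key
    indices$method[order(-key, seq_along(key))]
  }
  structure(list(indices = indices, ranking = ranking,
                 benchmark = list(nodes = bench_nodes,
                                  membership = bench_mem,
                                  dims = dim(sub$block$A),
                                  cluster_method = cluster_method,
                                  seed = seed)),
            class = "edge_validation")
}

#' @export
print.edge_validation <- function(x, ...) {
  cat(sprintf("Imputation validation against a %d x %d complete-submatrix benchmark (%s):\n",
              x$benchmark$dims[1], x$benchmark$dims[2],
              x$benchmark$cluster_method))
  print(x$indices, row.names = FALSE)
  if (!is.null(x$ranking))
    cat("Ranking (best first):", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
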