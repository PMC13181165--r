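#' Project a bipartite incidence matrix onto one node set
#'
#' The unipartite projection on the rows has adjacency \eqn{A A^T} (on the
#' columns, \eqn{A^T A}): the edge weight between two nodes is the sum of
#' products of their weights to shared partners in the opposite set.
#' Missing cells contribute zero to every product — the projection measures
#' shared *observed* partners only. Diagonal entries (self-similarities) are
#' kept out of the graph and stored separately; zero-weight pairs carry no
#' edge; isolated nodes are retained.
#'
#' @param M an [incidence_matrix]. Unweighted matrices project with
#'   \eqn{A \in \{0, 1\}}, so weights count shared partners.
#' @param part `"rows"` (set V) or `"cols"` (set W).
#' @return A list of class `projection_graph`: `part`, `graph` (an
#'   undirected weighted [igraph::igraph] with named vertices) and
#'   `self_weights` (the product-matrix diagonal).
#' @examples
#' A <- matrix(c(1, 3, 2, 4), 2, 2)
#' project(incidence_matrix(A), "rows")
#' @export
project <- function(M, part = c("rows", "cols")) {
  stopifnot(inherits(M, "incidence_matrix"))
  part <- match.arg(part)
  A0 <- M$A
  A0[is.na(A0)] <- 0
  P <- if (part == "rows") A0 %*% t(A0) else t(A0) %*% A0
  P <- (P + t(P)) / 2  # exact symmetry despite floating-point summation order
  self <- diag(P)
  diag(P) <- 0
  g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(part = part, graph = g, self_weights = self),
            class = "projection_graph")
}

#' @export
print.projection_graph <- function(x, ...) {
  cat(sprintf("Projection on %s: %d nodes, %d edges\n", x$part,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Remove weak edges from a projection graph
#'
#' Drops edges whose weight is at or below an absolute threshold `t`, or at
#' or below the `q`-quantile of the edge weights. The node set is unchanged.
#'
#' @param G a `projection_graph` (or igraph).
#' @param t absolute weight threshold; edges with weight <= `t` are removed.
#' @param q quantile in (0, 1); used when `t` is `NULL`.
#' @return The pruned graph, same class as the input.
#' @export
prune_weak_edges <- function(G, t = NULL, q = NULL) {
  g <- as_igraph(G)
  w <- igraph::E(g)$weight
  if (is.null(t)) {
    if (is.null(q)) stop("supply an absolute threshold 't' or a quantile 'q'")
    if (length(w) == 0L) stop("quantile pruning needs at least one edge")
    t <- stats::quantile(w, q, names = FALSE)
  }
  g2 <- igraph::delete_edges(g, which(w <= t))
  if (igraph::ecount(g2) == 0L && length(w) > 0L)
    warning("pruning removed every edge")
  if (inherits(G, "projection_graph")) {
    G$graph <- g2
    G
  } else g2
}
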