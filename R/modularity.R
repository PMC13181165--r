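#' Newman-Girvan modularity of a partition
#'
#' Modularity \eqn{Q = \sum_c (e_{cc} - a_c^2)} compares the fraction of
#' edge weight falling within communities against the expectation under the
#' weighted configuration model; \eqn{Q \in [-0.5, 1]}, with 0 for a single
#' community and large positive values for strong community structure.
#' Computation delegates to [igraph::modularity()].
#'
#' @param G an [igraph::igraph] graph or a `projection_graph` from
#'   [project()].
#' @param membership community assignment: integer/factor vector over the
#'   graph's vertices (in vertex order, or named by vertex).
#' @return Numeric modularity score.
#' @export
network_modularity <- function(G, membership) {
  g <- as_igraph(G)
  if (igraph::ecount(g) == 0L) stop("modularity of an empty graph is undefined")
  mem <- align_membership(membership, g)
  w <- igraph::E(g)$weight
  igraph::modularity(g, mem, weights = w)
}

# Accept either a raw igraph or the package's projection wrapper.
as_igraph <- function(G) {
  if (inherits(G, "projection_graph")) return(G$graph)
  if (inherits(G, "igraph")) return(G)
  stop("'G' must be an igraph or projection_graph object")
}

# Coerce a (possibly named) membership vector to integer codes in the
# graph's vertex order.
align_membership <- function(membership, g) {
  vn <- igraph::V(g)$name
  if (!is.null(names(membership)) && !is.null(vn)) {
    if (!all(vn %in% names(membership)))
      stop("membership does not cover all graph vertices")
    membership <- membership[vn]
  }
  if (length(membership) != igraph::vcount(g))
    stop("membership length does not match the vertex count")
  as.integer(factor(membership))
}
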