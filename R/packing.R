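#' Pack a presence matrix
#'
#' Reorders rows and columns by decreasing marginal presence counts, the
#' canonical first step of nestedness analysis: a nested matrix packs its
#' presences into the upper-left corner. Ties on the count are broken by
#' the presence-weighted sum of the opposite margin's totals, then by a
#' colour-refinement pass (rows/columns repeatedly receive the sorted
#' multiset of their partners' current colours, until stable), then by
#' lexicographic pattern individualization, and finally by original index.
#' The refinement keys are graph invariants and the individualization
#' collapses automorphic layouts onto one representative, so packing — and
#' everything computed from it, notably the nestedness temperature — does
#' not depend on the input's row/column order.
#'
#' @param presence logical (or 0/1) matrix; for an [incidence_matrix] pass
#'   `incidence_mask(M)` to study the missingness pattern.
#' @param max_passes upper bound on refinement passes.
#' @return A list of class `packed_matrix`: `row_order`, `col_order`
#'   (permutations such that `presence[row_order, col_order]` is packed),
#'   `packed` (the reordered logical matrix) and `fill` (overall proportion
#'   of presences).
#' @export
pack_matrix <- function(presence, max_passes = 20L) {
  P <- presence_matrix(presence)
  if (!any(P)) stop("cannot pack an all-empty presence matrix")
  m <- nrow(P)
  n <- ncol(P)
  rt <- rowSums(P)
  ct <- colSums(P)
  r2 <- as.numeric(P %*% ct)   # opposite-margin weighted sum
  c2 <- as.numeric(rt %*% P)
  rcol <- rank_classes(list(-rt, -r2))
  ccol <- rank_classes(list(-ct, -c2))
  for (pass in seq_len(max_passes)) {
    rsig <- vapply(seq_len(m), function(i)
      paste(sort(ccol[P[i, ]]), collapse = ","), character(1))
    csig <- vapply(seq_len(n), function(j)
      paste(sort(rcol[P[, j]]), collapse = ","), character(1))
    new_r <- rank_classes(list(-rt, -r2, rsig))
    new_c <- rank_classes(list(-ct, -c2, csig))
    if (identical(new_r, rcol) && identical(new_c, ccol)) break
    rcol <- new_r
    ccol <- new_c
  }
  # individualize remaining tied lines by lexicographic pattern (presences
  # first) with respect to the evolving opposite order, so automorphic
  # layouts collapse onto one canonical representative
  ro <- order(rcol, seq_len(m))
  co <- order(ccol, seq_len(n))
  for (pass in seq_len(max_passes)) {
    rpat <- vapply(seq_len(m), function(i)
      paste(as.integer(P[i, co]), collapse = ""), character(1))
    new_ro <- order(rcol, rpat, method = "radix",
                    decreasing = c(FALSE, TRUE))
    cpat <- vapply(seq_len(n), function(j)
      paste(as.integer(P[new_ro, j]), collapse = ""), character(1))
    new_co <- order(ccol, cpat, method = "radix",
                    decreasing = c(FALSE, TRUE))
    stable <- identical(new_ro, ro) && identical(new_co, co)
    ro <- new_ro
    co <- new_co
    if (stable) break
  }
  structure(list(row_order = ro, col_order = co,
                 packed = P[ro, co, drop = FALSE],
                 fill = mean(P)),
            class = "packed_matrix")
}

# Integer colour classes for lexicographic sorting on a list of key
# vectors; tied elements share a colour, so the classes are invariant
# under input permutation.
rank_classes <- function(keys) {
  o <- do.call(order, keys)
  n <- length(o)
  cls <- integer(n)
  cls[o[1L]] <- 1L
  cur <- 1L
  for (t in seq_len(n - 1L)) {
    differs <- any(vapply(keys, function(k)
      !identical(k[o[t + 1L]], k[o[t]]), logical(1)))
    if (differs) cur <- t + 1L
    cls[o[t + 1L]] <- cur
  }
  cls
}

#' @export
print.packed_matrix <- function(x, ...) {
  cat(sprintf("Packed %d x %d presence matrix, fill %.3f\n",
              nrow(x$packed), ncol(x$packed), x$fill))
  invisible(x)
}

# Coerce logical/0-1/incidence input to a logical presence matrix.
presence_matrix <- function(x, presence = c("mask", "positive")) {
  presence <- match.arg(presence)
  if (inherits(x, "incidence_matrix")) {
    if (presence == "mask") return(incidence_mask(x))
    return(!is.na(x$A) & x$A > 0)
  }
  if (!is.matrix(x)) stop("'presence' must be a matrix")
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (anyNA(x)) return(!is.na(x))
    return(x != 0)
  }
  stop("cannot interpret 'presence' input")
}

# Canonical perfectly nested arrangement of N presences in an m x n grid:
# cells filled in increasing (i-0.5)/m + (j-0.5)/n (distance from the
# top-left corner along the packing diagonal), ties by row then column.
# Returns the vector of row prefix lengths k_i (non-increasing).
nested_prefix_lengths <- function(m, n, N) {
  stopifnot(N >= 0, N <= m * n)
  i <- rep(seq_len(m), each = n)
  j <- rep(seq_len(n), times = m)
  s <- (i - 0.5) / m + (j - 0.5) / n
  ord <- order(s, i, j)
  sel <- ord[seq_len(N)]
  tabulate(i[sel], nbins = m)
}
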