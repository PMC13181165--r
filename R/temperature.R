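#' Nestedness temperature of a presence matrix
#'
#' The Atmar-Patterson "temperature" measures how far a packed presence
#' matrix departs from perfect nestedness: 0 for a perfectly nested
#' (staircase) arrangement, up to 100 for maximal disorder. Applied to the
#' observation mask of an incidence matrix it quantifies how *structured*
#' the missingness is: low temperature means the holes are tidily organised
#' rather than scattered.
#'
#' The matrix is packed ([pack_matrix()]), every cell centre is mapped into
#' the unit square at \eqn{(x, y) = ((j - 0.5)/n,\ 1 - (i - 0.5)/m)}, and an
#' isocline is drawn: the boundary of the canonical perfectly nested
#' arrangement with the same fill, a continuous monotone staircase curve
#' extended along the square's edges so that every diagonal of slope -1
#' crosses it exactly once. A presence below-right of the isocline, or an
#' absence above-left of it, is *unexpected*; its contribution is
#' \eqn{u_{ij} = (d_{ij}/D_{ij})^2}, where \eqn{d_{ij}} is the distance from
#' the cell centre to the isocline along the slope -1 diagonal through it
#' and \eqn{D_{ij}} the length of that diagonal inside the unit square. The
#' matrix temperature is \eqn{T = 100\, U / U_{max}} with \eqn{U} the mean
#' of \eqn{u_{ij}} over all cells (expected cells contribute 0) and
#' \eqn{U_{max} = 0.04145}, the classic scaling constant, clipped to
#' \eqn{[0, 100]}.
#'
#' @param x an [incidence_matrix] or a logical/0-1 presence matrix. For an
#'   incidence matrix the presence pattern defaults to the observation mask.
#' @param presence for incidence matrices: `"mask"` (observed vs missing,
#'   default) or `"positive"` (observed weight > 0, the ecological binary
#'   reading).
#' @return A list of class `temperature_result`: `T`, `U`, `fill`,
#'   `unexpected` (data frame of packed-coordinate cells `i`, `j` and their
#'   `u`), and the packing orders.
#' @examples
#' stair <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
#'                   TRUE, FALSE, FALSE), 3, 3, byrow = TRUE)
#' nestedness_temperature(stair)$T
#' @export
nestedness_temperature <- function(x, presence = c("mask", "positive")) {
  P <- presence_matrix(x, match.arg(presence))
  m <- nrow(P)
  n <- ncol(P)
  if (m < 2L || n < 2L)
    stop("temperature is undefined for degenerate 1 x n / m x 1 matrices")
  N <- sum(P)
  if (N == 0L || N == m * n) {
    return(structure(list(T = 0, U = 0, fill = N / (m * n),
                          unexpected = data.frame(i = integer(), j = integer(),
                                                  u = numeric()),
                          row_order = seq_len(m), col_order = seq_len(n)),
                     class = "temperature_result"))
  }
  pk <- pack_matrix(P)
  Pp <- pk$packed
  k <- nested_prefix_lengths(m, n, N)
  iso <- isocline_segments(k, m, n)

  # unexpected cells: packed presence differs from the canonical arrangement
  canon <- outer(k, seq_len(n), function(ki, j) j <= ki)
  ux <- which(Pp != canon, arr.ind = TRUE)
  u <- numeric(nrow(ux))
  if (nrow(ux) > 0L) {
    x0 <- (ux[, 2] - 0.5) / n
    y0 <- 1 - (ux[, 1] - 0.5) / m
    cc <- x0 + y0
    seg <- findInterval(cc, iso$s_lo, rightmost.closed = TRUE)
    seg[seg < 1L] <- 1L
    seg[seg > nrow(iso)] <- nrow(iso)
    # intersection of x + y = cc with the (axis-parallel) segment
    xi <- ifelse(iso$vertical[seg], iso$const[seg], cc - iso$const[seg])
    d_over_D <- abs(x0 - xi) / pmin(cc, 2 - cc)
    u <- pmin(1, d_over_D)^2
  }
  U <- sum(u) / (m * n)
  structure(list(T = max(0, min(100, 100 * U / 0.04145)),
                 U = U,
                 fill = pk$fill,
                 unexpected = data.frame(i = as.integer(ux[, 1]),
                                         j = as.integer(ux[, 2]), u = u),
                 row_order = pk$row_order, col_order = pk$col_order),
            class = "temperature_result")
}

#' @export
print.temperature_result <- function(x, ...) {
  cat(sprintf("Nestedness temperature T = %.3f (U = %.5f, fill = %.3f, %d unexpected cells)\n",
              x$T, x$U, x$fill, nrow(x$unexpected)))
  invisible(x)
}

# Isocline of the canonical nested arrangement with row prefix lengths k,
# as a table of axis-parallel segments ordered by s = x + y, which is
# strictly increasing along the curve. The staircase is extended along the
# bottom edge (y = 0) and the top edge (y = 1) so s spans [0, 2] and every
# slope -1 diagonal x + y = c crosses exactly one segment.
# Columns: vertical flag, const (x for vertical, y for horizontal), s_lo.
isocline_segments <- function(k, m, n) {
  segs <- vector("list", 2L * m + 2L)
  p <- 0L
  add <- function(vertical, const, s_lo) {
    p <<- p + 1L
    segs[[p]] <<- c(vertical, const, s_lo)
  }
  k_ext <- c(k, 0L)  # k_{m+1} = 0 anchors the bottom extension at x = 0
  # bottom edge extension: y = 0, x from 0 to k_m/n
  add(FALSE, 0, 0)
  for (i in m:1) {
    y_lo <- 1 - i / m
    # horizontal step at y = 1 - i/m from k_{i+1}/n to k_i/n (may be empty)
    if (i < m && k[i] > k[i + 1L]) add(FALSE, y_lo, k_ext[i + 1L] / n + y_lo)
    # vertical run at x = k_i/n across row band i
    add(TRUE, k[i] / n, k[i] / n + y_lo)
  }
  # top edge extension: y = 1, x from k_1/n to 1
  add(FALSE, 1, k[1L] / n + 1)
  out <- do.call(rbind, segs[seq_len(p)])
  data.frame(vertical = as.logical(out[, 1]), const = out[, 2],
             s_lo = out[, 3])
}
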