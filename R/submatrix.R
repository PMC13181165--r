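#' Extract a large complete submatrix
#'
#' Finds a large rectangular block of an incidence matrix that contains no
#' missing cell. The general problem (largest complete submatrix) is
#' NP-hard; the solver used depends on the matrix shape:
#'
#' * when the smaller dimension has at most 16 lines, the optimum for
#'   `Rectangular_element_max` and `Square` is computed *exactly* by
#'   enumerating the subsets of the smaller dimension with a subset-sum
#'   (superset-count) dynamic program — exponential only in the bounded
#'   dimension, so cheap;
#' * otherwise a deterministic greedy heuristic peels the matrix: while the
#'   working block contains a missing cell, remove the single admissible
#'   row or column whose removal leaves the best objective (remaining
#'   observed cells for `Rectangular_element_max`, squared minimum
#'   dimension for `Square`), ties going to the line with the most missing
#'   cells, then the larger dimension (rows when equal), then the lowest
#'   index; a re-add pass then restores any removed line that is fully
#'   observed on the survivors, and a local-improvement pass repeatedly
#'   tries to force one outside line in (dropping its conflicts, then
#'   re-adding) while that grows the block.
#'
#' Either way the result is *maximal*: no removed row or column can be
#' added back without introducing a missing cell.
#'
#' Modes: `Rectangular_element_max` maximizes retained cells, removing rows
#' or columns; `Square` returns a square block maximizing the side length;
#' `Rectangular_row` keeps all columns and removes rows only (equivalently,
#' retains exactly the fully observed rows); `Rectangular_col` is the
#' transpose case. When `Rectangular_row` is infeasible because no row is
#' fully observed, columns are dropped first (with a warning), worst-missing
#' first, until a complete row exists; `Rectangular_col` likewise.
#'
#' @param M an [incidence_matrix] with at least one observed cell.
#' @param mode one of `"Rectangular_element_max"` (default), `"Square"`,
#'   `"Rectangular_row"`, `"Rectangular_col"`.
#' @param max_passes bound on re-add / local-improvement sweeps.
#' @return A list of class `submatrix_result`: `mode`, `rows`, `cols`
#'   (original indices, in packed order), `row_names`, `col_names`,
#'   `n_cells`, `proportion_of_rows`, and `block` (the complete
#'   [incidence_matrix]).
#' @export
extract_submatrix <- function(M,
                              mode = c("Rectangular_element_max", "Square",
                                       "Rectangular_row", "Rectangular_col"),
                              max_passes = 50L) {
  stopifnot(inherits(M, "incidence_matrix"))
  mode <- match.arg(mode)
  obs <- incidence_mask(M)
  if (!any(obs)) stop("no fully observed cell to start from")
  m <- nrow(obs)
  n <- ncol(obs)

  res <- switch(mode,
    Rectangular_row = rowwise_block(obs),
    Rectangular_col = {
      r <- rowwise_block(t(obs))
      list(rows = r$cols, cols = r$rows)
    },
    if (min(m, n) <= 16L) exact_block(obs, mode)
    else greedy_block(obs, mode, max_passes)
  )

  rows <- unname(res$rows)
  cols <- unname(res$cols)
  stopifnot(all(obs[rows, cols]))  # the block must be complete
  # report in packed order of the original missingness pattern
  pk <- pack_matrix(obs)
  rows <- rows[order(match(rows, pk$row_order))]
  cols <- cols[order(match(cols, pk$col_order))]
  block <- incidence_matrix(M$A[rows, cols, drop = FALSE],
                            weighted = M$weighted)
  structure(list(mode = mode, rows = rows, cols = cols,
                 row_names = rownames(M$A)[rows],
                 col_names = colnames(M$A)[cols],
                 n_cells = length(rows) * length(cols),
                 proportion_of_rows = length(rows) / m,
                 block = block),
            class = "submatrix_result")
}

# Rows-only removal: the optimum is exactly the set of fully observed rows.
# If none exists, drop worst-missing columns (with a warning) until one does.
rowwise_block <- function(obs) {
  n <- ncol(obs)
  keep_c <- seq_len(n)
  if (!any(rowSums(obs) == n)) {
    warning("no fully observed line; dropping worst-missing opposite lines first")
    while (!any(rowSums(obs[, keep_c, drop = FALSE]) == length(keep_c))) {
      miss <- colSums(!obs[, keep_c, drop = FALSE])
      keep_c <- keep_c[-which.max(miss)]
    }
  }
  rows <- which(rowSums(obs[, keep_c, drop = FALSE]) == length(keep_c))
  list(rows = rows, cols = keep_c)
}

# Exact optimum by enumerating subsets of the smaller dimension.
# For every column subset C, the compatible rows are those observed on all
# of C; their count is a superset sum over the rows' observed-column masks,
# computed by an n-bit DP in O(n 2^n) independent of m.
exact_block <- function(obs, mode) {
  transposed <- nrow(obs) < ncol(obs)
  B <- if (transposed) t(obs) else obs
  m <- nrow(B)
  n <- ncol(B)
  bits <- 2L^(seq_len(n) - 1L)
  allowed <- as.integer(B %*% bits)        # per-row mask of observed columns
  f <- tabulate(allowed + 1L, nbins = 2L^n)  # rows per exact allowed-mask
  masks <- 0:(2L^n - 1L)
  for (b in bits) {                        # superset-count DP
    no_bit <- which(bitwAnd(masks, b) == 0L)
    f[no_bit] <- f[no_bit] + f[no_bit + b]
  }
  pc <- integer(2L^n)                      # popcounts
  for (b in bits) pc <- pc + as.integer(bitwAnd(masks, b) > 0L)

  if (mode == "Square") {
    side <- pmin(f, pc)
    best <- which.max(side)                # first (lowest mask) on ties
    C <- which(bitwAnd(masks[best], bits) > 0L)
    R <- which(bitwAnd(allowed, masks[best]) == masks[best])
    s <- side[best]
    if (s == 0L) {  # fall back to the largest single observed cell
      cell <- which(B, arr.ind = TRUE)[1L, ]
      R <- cell[1L]; C <- cell[2L]; s <- 1L
    }
    rows <- R[seq_len(s)]
    cols <- C[seq_len(s)]
  } else {
    cells <- f * pc
    best <- which(cells == max(cells))
    best <- best[order(-pc[best], masks[best])][1L]  # prefer keeping columns
    cols <- which(bitwAnd(masks[best], bits) > 0L)
    rows <- which(bitwAnd(allowed, masks[best]) == masks[best])
    if (length(cols) == 0L || length(rows) == 0L) {
      cell <- which(B, arr.ind = TRUE)[1L, ]
      rows <- cell[1L]; cols <- cell[2L]
    }
  }
  if (transposed) list(rows = cols, cols = rows)
  else list(rows = rows, cols = cols)
}

# Greedy peel + re-add + local improvement on a logical mask.
greedy_block <- function(obs, mode, max_passes = 50L) {
  m <- nrow(obs)
  n <- ncol(obs)
  rows <- seq_len(m)
  cols <- seq_len(n)

  repeat {
    blk <- obs[rows, cols, drop = FALSE]
    miss_r <- rowSums(!blk)
    miss_c <- colSums(!blk)
    if (sum(miss_r) == 0L) break
    nr <- length(rows)
    nc <- length(cols)
    if (nr == 1L && nc == 1L) stop("peeling exhausted the matrix")

    cand <- NULL  # (is_row, local_index, objective, n_missing)
    if (nr > 1L) {
      o <- if (mode == "Square") min(nr - 1L, nc)^2
           else sum(blk) - (nc - miss_r)  # remaining observed cells
      cand <- rbind(cand, cbind(1, seq_len(nr), o, miss_r))
    }
    if (nc > 1L) {
      o <- if (mode == "Square") min(nr, nc - 1L)^2
           else sum(blk) - (nr - miss_c)
      cand <- rbind(cand, cbind(0, seq_len(nc), o, miss_c))
    }
    cand <- cand[cand[, 4] > 0, , drop = FALSE]  # only lines carrying misses
    if (nrow(cand) == 0L) break
    dim_size <- ifelse(cand[, 1] == 1, nr, nc)
    pick <- order(-cand[, 3], -cand[, 4], -dim_size, -cand[, 1], cand[, 2])[1L]
    if (cand[pick, 1] == 1) rows <- rows[-cand[pick, 2]]
    else cols <- cols[-cand[pick, 2]]
  }

  if (mode == "Square") {
    s <- min(length(rows), length(cols))
    rows <- rows[seq_len(s)]
    cols <- cols[seq_len(s)]
    # grow the square by complete row/column pairs
    repeat {
      grown <- FALSE
      for (r in setdiff(seq_len(m), rows)) {
        if (!all(obs[r, cols])) next
        for (cc in setdiff(seq_len(n), cols)) {
          if (all(obs[rows, cc]) && obs[r, cc]) {
            rows <- c(rows, r)
            cols <- c(cols, cc)
            grown <- TRUE
            break
          }
        }
        if (grown) break
      }
      if (!grown) break
    }
    return(list(rows = rows, cols = cols))
  }

  readd <- function(rows, cols) {
    for (pass in seq_len(max_passes)) {
      grown <- FALSE
      for (r in setdiff(seq_len(m), rows))
        if (all(obs[r, cols])) { rows <- sort(c(rows, r)); grown <- TRUE }
      for (cc in setdiff(seq_len(n), cols))
        if (all(obs[rows, cc])) { cols <- sort(c(cols, cc)); grown <- TRUE }
      if (!grown) break
    }
    list(rows = rows, cols = cols)
  }
  st <- readd(rows, cols)
  cells <- function(s) length(s$rows) * length(s$cols)
  for (pass in seq_len(max_passes)) {
    best <- st
    for (r in setdiff(seq_len(m), st$rows)) {
      keep <- st$cols[obs[r, st$cols]]
      if (length(keep) == 0L) next
      cand <- readd(sort(c(st$rows, r)), keep)
      if (cells(cand) > cells(best)) best <- cand
    }
    for (cc in setdiff(seq_len(n), st$cols)) {
      keep <- st$rows[obs[st$rows, cc]]
      if (length(keep) == 0L) next
      cand <- readd(keep, sort(c(st$cols, cc)))
      if (cells(cand) > cells(best)) best <- cand
    }
    if (cells(best) > cells(st)) st <- best else break
  }
  st
}

#' @export
print.submatrix_result <- function(x, ...) {
  cat(sprintf("Complete submatrix (%s): %d x %d = %d cells (%.1f%% of rows)\n",
              x$mode, length(x$rows), length(x$cols), x$n_cells,
              100 * x$proportion_of_rows))
  invisible(x)
}

#' Summarize complete-submatrix extractions
#'
#' Tabulates, per extraction mode, the block dimensions and two proportions:
#' `prop_observed`, the total number of observed cells of the original
#' matrix divided by its total cell count, and `prop_submatrix`, the block's
#' cell count divided by the original total (for row-wise modes this equals
#' rows retained x n / (m x n)).
#'
#' @param M the [incidence_matrix] the results came from.
#' @param results a list of [extract_submatrix()] results (or a single one).
#' @return A data frame with one row per result.
#' @export
submatrix_report <- function(M, results) {
  stopifnot(inherits(M, "incidence_matrix"))
  if (inherits(results, "submatrix_result")) results <- list(results)
  total <- prod(dim(M))
  obs <- sum(incidence_mask(M))
  do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "submatrix_result"))
    data.frame(mode = r$mode,
               n_rows = length(r$rows), n_cols = length(r$cols),
               n_cells = r$n_cells,
               prop_observed = obs / total,
               prop_submatrix = r$n_cells / total)
  }))
}
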