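#' Incidence matrix of a bipartite network
#'
#' An `incidence_matrix` holds the biadjacency matrix of a bipartite network
#' over two disjoint nominal node sets: rows (set V) and columns (set W).
#' Missing edge weights are stored as `NA` and are treated throughout the
#' package as *unknown* interactions, never as true zeros; an observed weight
#' of zero is a valid value distinct from missing.
#'
#' @param A numeric matrix; `NA` marks an unobserved (missing) cell. Row and
#'   column names are used as node labels (defaults are generated when
#'   absent).
#' @param weighted logical; `FALSE` declares the network unweighted, in which
#'   case every observed cell must equal 1.
#' @return An object of class `incidence_matrix`: a list with elements `A`
#'   (the numeric matrix, `NA` = missing) and `weighted`.
#' @examples
#' A <- matrix(c(1, 3, 2, NA), 2, 2,
#'             dimnames = list(c("r1", "r2"), c("c1", "c2")))
#' M <- incidence_matrix(A)
#' summary(M)
#' @export
incidence_matrix <- function(A, weighted = TRUE) {
  if (!is.matrix(A) || !is.numeric(A))
    stop("'A' must be a numeric matrix")
  if (nrow(A) < 1L || ncol(A) < 1L)
    stop("'A' must have at least one row and one column")
  if (!any(is.finite(A)))
    stop("incidence matrix has no observed cell")
  if (any(is.infinite(A)))
    stop("observed weights must be finite")
  if (is.null(rownames(A))) rownames(A) <- paste0("v", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("w", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("row and column names must be unique")
  if (!weighted && any(A[!is.na(A)] != 1))
    stop("unweighted incidence matrices must have all observed cells equal 1")
  structure(list(A = A, weighted = isTRUE(weighted)),
            class = "incidence_matrix")
}

#' @export
dim.incidence_matrix <- function(x) dim(x$A)

# Observation mask: TRUE where the edge weight is observed.
#' Observation mask of an incidence matrix
#' @param M an [incidence_matrix].
#' @return Logical matrix, `TRUE` for observed cells.
#' @export
incidence_mask <- function(M) {
  stopifnot(inherits(M, "incidence_matrix"))
  !is.na(M$A)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Incidence matrix: %d x %d (%s)\n", s$n_rows, s$n_cols,
              if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  observed: %d / %d cells (%.1f%% non-missing)\n",
              s$n_observed, s$n_rows * s$n_cols, 100 * s$prop_nonmissing))
  if (x$weighted && s$n_observed > 0)
    cat(sprintf("  weight range: [%g, %g]\n",
                s$weight_range[1], s$weight_range[2]))
  invisible(x)
}

#' Summarize an incidence matrix
#'
#' Reports dimensions, the number of observed and missing cells, the
#' proportion of non-missing values, and (for weighted networks) the range
#' of observed weights.
#'
#' @param object an [incidence_matrix].
#' @param ... unused.
#' @return A list of class `incidence_summary` with fields `n_rows`,
#'   `n_cols`, `n_observed`, `n_missing`, `prop_nonmissing`, `weighted`,
#'   `weight_range`.
#' @export
summary.incidence_matrix <- function(object, ...) {
  obs <- incidence_mask(object)
  n_obs <- sum(obs)
  out <- list(
    n_rows = nrow(object$A),
    n_cols = ncol(object$A),
    n_observed = n_obs,
    n_missing = length(obs) - n_obs,
    prop_nonmissing = n_obs / length(obs),
    weighted = object$weighted,
    weight_range = if (n_obs > 0) range(object$A, na.rm = TRUE) else NULL
  )
  class(out) <- "incidence_summary"
  out
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf(
    "%d x %d incidence matrix (%s): %d observed, %d missing (%.4f non-missing)\n",
    x$n_rows, x$n_cols, if (x$weighted) "weighted" else "unweighted",
    x$n_observed, x$n_missing, x$prop_nonmissing))
  invisible(x)
}

#' Convert an incidence matrix to a long-format table
#'
#' Produces one row per *observed* cell, so
#' `build_incidence(as.data.frame(M))` round-trips `M` exactly (up to the
#' first-appearance ordering of labels).
#'
#' @param x an [incidence_matrix].
#' @param row.names,optional,... unused, present for method compatibility.
#' @return A data frame with columns `row_label`, `col_label`, and (for
#'   weighted matrices) `weight`, in row-major cell order.
#' @export
as.data.frame.incidence_matrix <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  obs <- which(t(incidence_mask(x)))  # row-major order
  n <- ncol(x$A)
  i <- (obs - 1L) %/% n + 1L
  j <- (obs - 1L) %% n + 1L
  out <- data.frame(
    row_label = rownames(x$A)[i],
    col_label = colnames(x$A)[j],
    stringsAsFactors = FALSE
  )
  if (x$weighted) out$weight <- x$A[cbind(i, j)]
  out
}

#' Build an incidence matrix from a nominal long table
#'
#' Rows of the matrix are the distinct values of the first nominal column in
#' first-appearance order, columns likewise for the second; the observed
#' cells are exactly the pairs present in the table. Duplicate pairs are
#' aggregated.
#'
#' @param table a `nominal_table` from [read_nominal_table()], or any data
#'   frame with columns `row_label`, `col_label` and optionally `weight`.
#' @param agg aggregation for duplicated (row, col) pairs: `"mean"`
#'   (default), `"median"`, `"sum"` or `"first"`.
#' @return An [incidence_matrix]. Unweighted input yields 1 on observed
#'   cells.
#' @export
build_incidence <- function(table, agg = c("mean", "median", "sum", "first")) {
  agg <- match.arg(agg)
  if (!is.data.frame(table) ||
      !all(c("row_label", "col_label") %in% names(table)))
    stop("'table' must have columns 'row_label' and 'col_label'")
  if (nrow(table) < 1L) stop("empty nominal table")
  weighted <- "weight" %in% names(table)
  rl <- as.character(table$row_label)
  cl <- as.character(table$col_label)
  rn <- unique(rl)
  cn <- unique(cl)
  A <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  i <- match(rl, rn)
  j <- match(cl, cn)
  w <- if (weighted) as.numeric(table$weight) else rep(1, nrow(table))
  key <- (i - 1L) * length(cn) + j
  dup <- anyDuplicated(key) > 0L
  if (dup) {
    f <- switch(agg,
      mean = tapply(w, key, mean),
      median = tapply(w, key, stats::median),
      sum = tapply(w, key, sum),
      first = tapply(w, key, function(v) v[1L])
    )
    k <- as.integer(names(f))
    A[cbind((k - 1L) %/% length(cn) + 1L, (k - 1L) %% length(cn) + 1L)] <- f
    message(sprintf("build_incidence: aggregated %d duplicated pair(s) by %s",
                    sum(duplicated(key)), agg))
  } else {
    A[cbind(i, j)] <- w
  }
  incidence_matrix(A, weighted = weighted)
}

#' Filter an incidence matrix by node degree
#'
#' The degree of a row (column) is its count of *observed* cells. Rows below
#' `min_row_deg` and columns below `min_col_deg` are removed; with
#' `iterative = TRUE` (default) removal repeats, with degrees recomputed
#' after every pass, until the surviving core satisfies both thresholds, so
#' the operation is idempotent.
#'
#' @param M an [incidence_matrix].
#' @param min_row_deg,min_col_deg non-negative integer thresholds.
#' @param iterative repeat removal until stable (`TRUE`) or apply a single
#'   pass on the original degrees (`FALSE`).
#' @return The filtered [incidence_matrix].
#' @export
filter_by_degree <- function(M, min_row_deg = 0L, min_col_deg = 0L,
                             iterative = TRUE) {
  stopifnot(inherits(M, "incidence_matrix"),
            min_row_deg >= 0, min_col_deg >= 0)
  A <- M$A
  repeat {
    obs <- !is.na(A)
    keep_r <- rowSums(obs) >= min_row_deg
    keep_c <- colSums(obs) >= min_col_deg
    if (!any(keep_r) || !any(keep_c))
      stop("degree filtering removed every row or column")
    done <- all(keep_r) && all(keep_c)
    A <- A[keep_r, keep_c, drop = FALSE]
    if (done || !iterative) break
  }
  incidence_matrix(A, weighted = M$weighted)
}
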