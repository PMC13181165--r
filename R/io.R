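#' Read a long-format nominal table
#'
#' Reads a delimited text file whose rows are (row label, column label)
#' pairs, optionally followed by a numeric edge weight. Records whose
#' weight token is a missing-value sentinel (`""`, `"NA"`, `"NaN"`,
#' `"null"`) are dropped: the pair is treated as unobserved, because an
#' absent weight is an unknown interaction, not a zero.
#'
#' @param path path to a CSV/TSV file.
#' @param col_spec names or integer positions of the two (or three) columns
#'   to use, in order (row label, column label, weight). `NULL` takes the
#'   first two or three columns as they appear.
#' @param sep field delimiter; `NULL` guesses `","` for `.csv` and tab
#'   otherwise.
#' @param header does the file carry a header line?
#' @return A data frame of class `nominal_table` with columns `row_label`,
#'   `col_label` and, when a weight column is present, `weight`; attribute
#'   `weighted` flags the latter.
#' @export
read_nominal_table <- function(path, col_spec = NULL, sep = NULL,
                               header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = character(0))
  if (ncol(raw) < 2L) stop("need at least 2 columns, got ", ncol(raw))
  if (is.null(col_spec)) col_spec <- seq_len(min(3L, ncol(raw)))
  if (length(col_spec) < 2L || length(col_spec) > 3L)
    stop("'col_spec' must select 2 or 3 columns")
  cols <- if (is.character(col_spec)) {
    idx <- match(col_spec, names(raw))
    if (anyNA(idx)) stop("column(s) not found: ",
                         paste(col_spec[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(col_spec)
  out <- data.frame(row_label = trimws(raw[[cols[1]]]),
                    col_label = trimws(raw[[cols[2]]]),
                    stringsAsFactors = FALSE)
  weighted <- length(cols) == 3L
  keep <- nzchar(out$row_label) & nzchar(out$col_label)
  if (weighted) {
    tok <- trimws(raw[[cols[3]]])
    na_tok <- tok %in% c("", "NA", "NaN", "null", "NULL", "na")
    w <- suppressWarnings(as.numeric(tok))
    bad <- !na_tok & (is.na(w) | !is.finite(w))
    if (any(bad))
      stop("non-numeric weight token(s), e.g. '", tok[which(bad)[1]], "'")
    keep <- keep & !na_tok
    out$weight <- w
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all rows dropped while reading ", path)
  rownames(out) <- NULL
  attr(out, "weighted") <- weighted
  class(out) <- c("nominal_table", "data.frame")
  out
}

#' Write an incidence matrix as TSV
#'
#' Tab-separated values with row and column headers; missing cells are
#' written as empty fields.
#'
#' @param M an [incidence_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(M, path) {
  stopifnot(inherits(M, "incidence_matrix"))
  A <- M$A
  txt <- ifelse(is.na(A), "", formatC(A, format = "g", digits = 15))
  dim(txt) <- dim(A)
  dimnames(txt) <- dimnames(A)
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     col.names = NA, na = "")
  invisible(path)
}

#' Read an incidence matrix from TSV
#'
#' Inverse of [write_incidence()]: row/column headers, empty cells (or `NA`)
#' as missing.
#'
#' @param path input file path.
#' @param weighted declare the matrix weighted (default) or binary.
#' @return An [incidence_matrix].
#' @export
read_incidence <- function(path, weighted = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  A <- as.matrix(raw)
  storage.mode(A) <- "double"
  incidence_matrix(A, weighted = weighted)
}

#' Read an incidence matrix from MatrixMarket plus a sidecar mask
#'
#' The MTX file carries the edge weights in sparse coordinate form; the
#' sidecar (same format) marks observed cells with non-zero entries. Without
#' a sidecar, the non-zero pattern of the weight file is taken as observed
#' (so explicitly stored zeros are observed zeros).
#'
#' @param path MatrixMarket file of weights.
#' @param mask_path optional MatrixMarket file whose non-zero pattern marks
#'   observed cells.
#' @param weighted declare the matrix weighted.
#' @return An [incidence_matrix]; node labels are `v<i>` / `w<j>`.
#' @export
read_incidence_mtx <- function(path, mask_path = NULL, weighted = TRUE) {
  W <- as.matrix(Matrix::readMM(path))
  if (is.null(mask_path)) {
    S <- as.matrix(Matrix::readMM(path) != 0)
    # entries explicitly stored as zero are still observed: recover pattern
    S <- S | explicit_pattern(path, dim(W))
  } else {
    S <- as.matrix(Matrix::readMM(mask_path)) != 0
    if (!all(dim(S) == dim(W)))
      stop("mask dimensions do not match the weight matrix")
  }
  A <- ifelse(S, W, NA_real_)
  incidence_matrix(A, weighted = weighted)
}

# Pattern of explicitly stored entries in a coordinate MatrixMarket file.
explicit_pattern <- function(path, dims) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  if (length(lines) < 2L) return(matrix(FALSE, dims[1], dims[2]))
  ij <- utils::read.table(text = lines[-1])
  out <- matrix(FALSE, dims[1], dims[2])
  out[cbind(ij[[1]], ij[[2]])] <- TRUE
  out
}
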