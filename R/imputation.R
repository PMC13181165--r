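#' Simple marginal imputation of missing edge weights
#'
#' A missing cell (i, j) is filled with the average of the row-i statistic
#' and the column-j statistic (mean or median over observed cells), which is
#' symmetric in the two nominal variables. Rows or columns without any
#' observation fall back to the global statistic. Observed cells are never
#' modified.
#'
#' @param M an [incidence_matrix].
#' @param statistic `"mean"` or `"median"`.
#' @return A list of class `completed_matrix`: `values` (fully observed
#'   numeric matrix), `method`, `params`, `fit_info`.
#' @export
impute_simple <- function(M, statistic = c("mean", "median")) {
  stopifnot(inherits(M, "incidence_matrix"))
  statistic <- match.arg(statistic)
  A <- M$A
  fn <- if (statistic == "mean") mean else stats::median
  g <- fn(A[!is.na(A)])
  rs <- apply(A, 1, function(v) if (all(is.na(v))) g else fn(v[!is.na(v)]))
  cs <- apply(A, 2, function(v) if (all(is.na(v))) g else fn(v[!is.na(v)]))
  miss <- which(is.na(A), arr.ind = TRUE)
  A[miss] <- (rs[miss[, 1]] + cs[miss[, 2]]) / 2
  completed_matrix(A, M, statistic, params = list(),
                   fit_info = list(n_imputed = nrow(miss)))
}

#' Alternating-least-squares matrix completion
#'
#' Fits a rank-`r` factorisation \eqn{A_{ij} \approx u_i \cdot v_j} to the
#' observed cells only, minimising the ridge-penalised squared error
#' \eqn{\sum_{obs}(A_{ij} - u_i v_j)^2 + \lambda(\|U\|^2 + \|V\|^2)} by
#' exact alternating ridge solves, which makes the penalised loss
#' non-increasing across iterations. Missing cells are filled with the
#' fitted values; observed cells are untouched.
#'
#' @param M an [incidence_matrix].
#' @param rank factor rank `r <= min(m, n)`.
#' @param lambda ridge penalty (> 0 keeps the solves well posed).
#' @param max_iter,tol stopping rule: stop when the observed-cell RMSE
#'   improves by less than `tol`, or after `max_iter` sweeps.
#' @param seed seed for the small random initial factors.
#' @return A `completed_matrix`; `fit_info` records iterations, the final
#'   RMSE delta, and the penalised-loss trace.
#' @export
impute_als <- function(M, rank = 2L, lambda = 0.01, max_iter = 100L,
                       tol = 1e-6, seed = 1L) {
  stopifnot(inherits(M, "incidence_matrix"))
  A <- M$A
  m <- nrow(A)
  n <- ncol(A)
  r <- as.integer(rank)
  if (r > min(m, n)) stop("rank must not exceed min(nrow, ncol)")
  obs <- !is.na(A)
  if (any(rowSums(obs) < r) || any(colSums(obs) < r))
    warning("some rows/columns have fewer observed cells than the rank; ",
            "their factors are determined mostly by the ridge penalty")
  UV <- with_seed(seed, list(U = matrix(rnorm(m * r, sd = 0.1), m, r),
                             V = matrix(rnorm(n * r, sd = 0.1), n, r)))
  U <- UV$U; V <- UV$V
  ridge <- diag(lambda, r)
  loss <- function() {
    E <- (A - U %*% t(V))[obs]
    sum(E^2) + lambda * (sum(U^2) + sum(V^2))
  }
  rmse <- function() sqrt(mean(((A - U %*% t(V))[obs])^2))
  loss_trace <- loss()
  last_rmse <- rmse()
  iters <- 0L
  delta <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(m)) {
      jj <- which(obs[i, ])
      if (length(jj) == 0L) { U[i, ] <- 0; next }
      Vo <- V[jj, , drop = FALSE]
      U[i, ] <- solve(crossprod(Vo) + ridge, crossprod(Vo, A[i, jj]))
    }
    for (j in seq_len(n)) {
      ii <- which(obs[, j])
      if (length(ii) == 0L) { V[j, ] <- 0; next }
      Uo <- U[ii, , drop = FALSE]
      V[j, ] <- solve(crossprod(Uo) + ridge, crossprod(Uo, A[ii, j]))
    }
    loss_trace <- c(loss_trace, loss())
    new_rmse <- rmse()
    delta <- last_rmse - new_rmse
    last_rmse <- new_rmse
    iters <- it
    if (abs(delta) < tol) break
  }
  fit <- U %*% t(V)
  A[!obs] <- fit[!obs]
  completed_matrix(A, M, "als",
                   params = list(rank = r, lambda = lambda, seed = seed),
                   fit_info = list(iterations = iters, delta = delta,
                                   rmse = last_rmse, loss_trace = loss_trace))
}

#' Iterative correspondence-analysis imputation
#'
#' Treats the (non-negative) weighted incidence matrix as a contingency-like
#' table. Missing cells are initialised with the simple mean imputation,
#' then the cycle \{run CA on the completed matrix (row/column masses,
#' truncated SVD of the mass-standardised table), reconstruct the expected
#' table from the leading `n_dims` singular dimensions, overwrite missing
#' cells with the reconstruction clipped at 0\} repeats until the largest
#' absolute change on a missing cell drops below `tol`. Observed cells are
#' never modified.
#'
#' @param M an [incidence_matrix] with non-negative observed weights
#'   (negative weights belong to [impute_als()]).
#' @param n_dims number of singular dimensions kept in the reconstruction;
#'   the first is CA's trivial axis, which alone reproduces the
#'   independence model, so `n_dims = 2` (default) keeps one association
#'   axis on top of it.
#' @param max_iter,tol stopping rule on the missing-cell changes.
#' @return A `completed_matrix`.
#' @export
impute_ca <- function(M, n_dims = 2L, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(M, "incidence_matrix"))
  A <- M$A
  if (any(A[!is.na(A)] < 0))
    stop("CA imputation needs non-negative weights; use impute_als() instead")
  if (all(A[!is.na(A)] == 0)) stop("all-zero matrix")
  obs <- !is.na(A)
  miss <- !obs
  k <- as.integer(n_dims)
  X <- impute_simple(M, "mean")$values
  X[X < 0] <- 0
  iters <- 0L
  delta <- Inf
  for (it in seq_len(max_iter)) {
    rec <- ca_reconstruct(X, k)
    rec[rec < 0] <- 0
    delta <- if (any(miss)) max(abs(X[miss] - rec[miss])) else 0
    X[miss] <- rec[miss]
    iters <- it
    if (delta < tol) break
  }
  completed_matrix(X, M, "ca", params = list(n_dims = k),
                   fit_info = list(iterations = iters, delta = delta))
}

# Rank-k CA reconstruction of a complete non-negative table: truncated SVD
# of the mass-standardized table, mapped back to the original scale. The
# first singular dimension is the trivial CA axis, which alone reproduces
# the independence model r c' N; each further dimension adds one
# association axis.
ca_reconstruct <- function(X, k) {
  N <- sum(X)
  P <- X / N
  r <- rowSums(P)
  cc <- colSums(P)
  r[r == 0] <- .Machine$double.eps
  cc[cc == 0] <- .Machine$double.eps
  Q <- P / outer(sqrt(r), sqrt(cc))
  k <- max(1L, min(k, nrow(X), ncol(X)))
  sv <- svd(Q, nu = k, nv = k)
  Qk <- sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v))
  outer(sqrt(r), sqrt(cc)) * Qk * N
}

# Shared constructor: pins observed cells to their original values and
# validates the result.
completed_matrix <- function(values, M, method, params, fit_info) {
  obs <- incidence_mask(M)
  values[obs] <- M$A[obs]
  if (any(!is.finite(values)))
    stop("imputation produced non-finite values")
  structure(list(values = values, method = method, params = params,
                 fit_info = fit_info),
            class = "completed_matrix")
}

#' @export
print.completed_matrix <- function(x, ...) {
  cat(sprintf("Completed %d x %d matrix (method: %s)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Impute missing edge weights
#'
#' Dispatcher over the four imputation strategies; see [impute_simple()],
#' [impute_ca()] and [impute_als()] for the method details and parameters.
#'
#' @param M an [incidence_matrix].
#' @param method `"mean"`, `"median"`, `"ca"` or `"als"`.
#' @param seed seed for the stochastic methods (only ALS uses one).
#' @param ... passed to the method-specific function.
#' @return A `completed_matrix`.
#' @export
impute_edges <- function(M, method = c("mean", "median", "ca", "als"),
                         seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         mean = impute_simple(M, "mean"),
         median = impute_simple(M, "median"),
         ca = impute_ca(M, ...),
         als = impute_als(M, seed = seed, ...))
}
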