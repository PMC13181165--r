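#' Simulate a bipartite incidence matrix with planted structure
#'
#' Generates weighted bipartite matrices whose structure is known by
#' construction, so every pipeline stage can be tested against ground
#' truth.
#'
#' * `modular`: rows and columns are split into `k` contiguous, equal-sized
#'   blocks; cell weights are Normal(`mu_in`, `sigma`) when the row and
#'   column block match and Normal(`mu_out`, `sigma`) otherwise, clipped at
#'   0 (which keeps the weights usable as a contingency-like table). The
#'   matrix is fully observed; truth carries the planted row/column blocks.
#' * `nested`: the canonical perfectly nested presence staircase at fill
#'   `p` — exactly the arrangement whose isocline
#'   [nestedness_temperature()] uses, so its temperature is 0 — with
#'   weights Uniform(0.5, 1.5) on presences and absences missing; truth is
#'   the nesting (row) order.
#' * `random`: i.i.d. Bernoulli(`p`) presences with Uniform(0.5, 1.5)
#'   weights; no planted structure.
#'
#' @param m,n matrix dimensions.
#' @param structure a list with element `type` (`"modular"`, `"nested"`,
#'   `"random"`) and the type's parameters: `k`, `mu_in`, `mu_out`, `sigma`
#'   for modular (`mu_in > mu_out >= 0`); `p` in (0, 1) for nested/random.
#' @param seed integer seed; identical spec + seed reproduce the output
#'   exactly.
#' @return A list with `matrix` (an [incidence_matrix]) and `truth`
#'   (`row_blocks`/`col_blocks` for modular, `row_order` for nested, `NULL`
#'   for random).
#' @examples
#' sim <- simulate_bipartite(20, 15,
#'                           list(type = "modular", k = 2, mu_in = 10,
#'                                mu_out = 1, sigma = 0.5), seed = 1)
#' table(sim$truth$row_blocks)
#' @export
simulate_bipartite <- function(m, n, structure, seed = 1L) {
  stopifnot(m >= 2, n >= 2, is.list(structure), !is.null(structure$type))
  with_seed(seed, {
    switch(structure$type,
      modular = {
        k <- structure$k
        mu_in <- structure$mu_in
        mu_out <- structure$mu_out
        sigma <- structure$sigma
        stopifnot(k >= 2, mu_in > mu_out, mu_out >= 0, sigma >= 0)
        rb <- sort(rep_len(seq_len(k), m))
        cb <- sort(rep_len(seq_len(k), n))
        mu <- ifelse(outer(rb, cb, "=="), mu_in, mu_out)
        A <- matrix(pmax(0, rnorm(m * n, mean = mu, sd = sigma)), m, n)
        dimnames(A) <- default_dimnames(m, n)
        list(matrix = incidence_matrix(A),
             truth = list(row_blocks = rb, col_blocks = cb))
      },
      nested = {
        p <- structure$p
        stopifnot(p > 0, p < 1)
        N <- max(1L, round(p * m * n))
        kk <- nested_prefix_lengths(m, n, N)
        P <- outer(kk, seq_len(n), function(ki, j) j <= ki)
        A <- matrix(NA_real_, m, n, dimnames = default_dimnames(m, n))
        A[P] <- runif(sum(P), 0.5, 1.5)
        list(matrix = incidence_matrix(A),
             truth = list(row_order = seq_len(m)))
      },
      random = {
        p <- structure$p
        stopifnot(p > 0, p < 1)
        P <- matrix(runif(m * n) < p, m, n)
        if (!any(P)) P[sample.int(m * n, 1L)] <- TRUE
        A <- matrix(NA_real_, m, n, dimnames = default_dimnames(m, n))
        A[P] <- runif(sum(P), 0.5, 1.5)
        list(matrix = incidence_matrix(A), truth = NULL)
      },
      stop("unknown structure type: ", structure$type)
    )
  })
}

default_dimnames <- function(m, n) {
  list(sprintf("v%03d", seq_len(m)), sprintf("w%03d", seq_len(n)))
}

#' Mask observed cells under a chosen missingness mechanism
#'
#' Turns observed cells of an incidence matrix into missing ones:
#'
#' * `mcar`: every observed cell is masked independently with probability
#'   `rate` — missing completely at random.
#' * `block`: the listed rectangular regions (each a list with integer
#'   vectors `rows` and `cols`) are masked entirely, emulating the
#'   block-like missingness of nominal datasets where whole subgroups go
#'   unmeasured.
#' * `threshold`: cells with weight below `tau` are masked — missingness
#'   that depends on the unobserved value itself (MNAR, as when weak
#'   signals fall below a detection limit).
#'
#' @param M an [incidence_matrix].
#' @param mechanism a list with `type` (`"mcar"`, `"block"`, `"threshold"`)
#'   and its parameter: `rate` in (0, 1), `regions`, or `tau`.
#' @param seed seed for the MCAR draws (the other mechanisms are
#'   deterministic).
#' @return The masked [incidence_matrix]; errors if nothing would remain
#'   observed.
#' @export
apply_missingness <- function(M, mechanism, seed = 1L) {
  stopifnot(inherits(M, "incidence_matrix"), is.list(mechanism))
  A <- M$A
  obs <- !is.na(A)
  drop <- switch(mechanism$type,
    mcar = {
      rate <- mechanism$rate
      stopifnot(rate >= 0, rate < 1)
      with_seed(seed, obs & matrix(runif(length(A)) < rate, nrow(A)))
    },
    block = {
      d <- matrix(FALSE, nrow(A), ncol(A))
      for (reg in mechanism$regions) d[reg$rows, reg$cols] <- TRUE
      d & obs
    },
    threshold = {
      obs & A < mechanism$tau
    },
    stop("unknown missingness mechanism: ", mechanism$type)
  )
  if (all(!obs | drop)) stop("mechanism would mask every observed cell")
  A[drop] <- NA_real_
  incidence_matrix(A, weighted = M$weighted)
}
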