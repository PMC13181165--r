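# Independent oracles used to cross-check the package's implementations.
# These deliberately take the slow, direct route: explicit cell loops,
# explicit geometry, exhaustive enumeration.

# Geometric brute-force nestedness temperature: builds the canonical nested
# staircase by sorting cell centres, walks the boundary polyline segment by
# segment to intersect each slope -1 diagonal, and accumulates (d/D)^2.
oracle_temperature <- function(P) {
  m <- nrow(P)
  n <- ncol(P)
  N <- sum(P)
  if (N == 0 || N == m * n) return(0)
  Pp <- pack_matrix(P)$packed
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  s <- (cells$i - 0.5) / m + (cells$j - 0.5) / n
  ord <- order(s, cells$i, cells$j)
  canon <- matrix(FALSE, m, n)
  canon[cbind(cells$i[ord[seq_len(N)]], cells$j[ord[seq_len(N)]])] <- TRUE
  k <- rowSums(canon)
  # boundary vertex chain, bottom-left extension -> staircase -> top-right
  verts <- list(c(0, 0), c(k[m] / n, 0))
  for (i in m:1)
    verts <- c(verts, list(c(k[i] / n, 1 - i / m), c(k[i] / n, 1 - (i - 1) / m)))
  verts <- c(verts, list(c(1, 1)))
  V <- do.call(rbind, verts)
  U <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (Pp[i, j] == canon[i, j]) next
    x0 <- (j - 0.5) / n
    y0 <- 1 - (i - 0.5) / m
    c0 <- x0 + y0
    xi <- NA_real_
    for (q in seq_len(nrow(V) - 1)) {
      s1 <- sum(V[q, ])
      s2 <- sum(V[q + 1, ])
      if (s2 > s1 && s1 <= c0 && c0 <= s2) {
        t <- (c0 - s1) / (s2 - s1)
        xi <- V[q, 1] + t * (V[q + 1, 1] - V[q, 1])
        break
      }
    }
    d <- sqrt(2) * abs(x0 - xi)
    D <- sqrt(2) * min(c0, 2 - c0)
    U <- U + (d / D)^2
  }
  max(0, min(100, 100 * (U / (m * n)) / 0.04145))
}

# Exhaustive largest complete submatrix (cell count) over all row subsets.
oracle_best_block <- function(obs) {
  m <- nrow(obs)
  best <- 0
  for (S in seq_len(2^m - 1)) {
    rows <- which(bitwAnd(S, 2^(seq_len(m) - 1)) > 0)
    cols <- which(colSums(!obs[rows, , drop = FALSE]) == 0)
    best <- max(best, length(rows) * length(cols))
  }
  best
}

# Exhaustive largest complete square (side length) over all row subsets.
oracle_best_square <- function(obs) {
  m <- nrow(obs)
  best <- 0
  for (S in seq_len(2^m - 1)) {
    rows <- which(bitwAnd(S, 2^(seq_len(m) - 1)) > 0)
    cols <- which(colSums(!obs[rows, , drop = FALSE]) == 0)
    best <- max(best, min(length(rows), length(cols)))
  }
  best
}

# Direct pair enumeration for partition-agreement counts.
oracle_pair_counts <- function(m1, m2) {
  n <- length(m1)
  a <- b <- cc <- d <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- m1[i] == m1[j]
    s2 <- m2[i] == m2[j]
    if (s1 && s2) a <- a + 1L
    else if (s1) b <- b + 1L
    else if (s2) cc <- cc + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d)
}

# A random incidence matrix with an MCAR-masked pattern, for quick fixtures.
random_incidence <- function(m, n, miss = 0.3, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(runif(m * n, 1, 10), m, n)
    A[runif(m * n) < miss] <- NA
    if (all(is.na(A))) A[1, 1] <- 1
    A
  })
}
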