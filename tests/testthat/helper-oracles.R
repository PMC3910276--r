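# Brute-force oracles, independent of the package's sparse-matrix code
# paths: dense adjacency, triple-loop triangle counts, Floyd-Warshall
# distances, direct summation for nearest-neighbour degrees.

denseAdjacency <- function(g) {
  ids <- nodeIds(g)
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  et <- edgeTable(g)
  for (r in seq_len(nrow(et))) {
    A[et$from[r], et$to[r]] <- 1L
    A[et$to[r], et$from[r]] <- 1L
  }
  A
}

bruteClustering <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] == 1L)
    e <- 0L
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] == 1L) e <- e + 1L
      }
    }
    ci[i] <- (2 * e) / (k[i] * (k[i] - 1))
  }
  ci
}

bruteKnn <- function(A) {
  k <- rowSums(A)
  vapply(seq_len(nrow(A)), function(i) {
    if (k[i] == 0) return(NA_real_)
    sum(A[i, ] * k) / k[i]
  }, numeric(1))
}

floydWarshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (m in seq_len(n)) {
    D <- pmin(D, outer(D[, m], D[m, ], `+`))
  }
  D
}

bruteAveragePath <- function(A) {
  D <- floydWarshall(A)
  n <- nrow(A)
  stopifnot(all(is.finite(D)))
  sum(D) / (n * (n - 1))
}

# random simple graph on n nodes via base-R pair sampling (not the package's
# generators), with letters-free ids so lexicographic order is predictable
randomOracleGraph <- function(n, seed) {
  set.seed(seed)
  maxE <- n * (n - 1) / 2
  e <- sample.int(max(1L, round(maxE * 0.3)), 1L)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), e), , drop = FALSE]
  ids <- sprintf("v%03d", seq_len(n))
  interactionGraph(cbind(ids[pick[, 1L]], ids[pick[, 2L]]), nodes = ids)
}

expect_setequal_edges <- function(g1, g2) {
  expect_identical(edgeTable(g1), edgeTable(g2))
}
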