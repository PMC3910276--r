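# Random-graph null models matched in node and edge counts.
#
# All generators return a simple undirected graph with exactly n nodes and
# exactly e edges. WS and BA cannot hit an arbitrary edge count natively, so
# after construction edges are randomly added (uniformly among absent pairs)
# or removed (uniformly among present ones) until the count is exact.

# decode linear indices 1..n(n-1)/2 into pairs (i < j), lexicographic order
pairFromIndex <- function(idx, n) {
  # pairs with first element <= a: a*n - a*(a+1)/2
  a <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  # guard float round-off at block boundaries
  cum <- function(a) a * n - a * (a + 1) / 2
  a <- a - (cum(a - 1) >= idx)
  a <- a + (cum(a) < idx)
  j <- idx - cum(a - 1) + a
  cbind(as.integer(a), as.integer(j))
}

pairIndex <- function(i, j, n) {
  (i - 1) * n - (i - 1) * i / 2 + (j - i)
}

# sample m edges uniformly among pairs NOT in `existing` (index vector)
sampleAbsentPairs <- function(m, n, existing) {
  maxE <- n * (n - 1) / 2
  stopifnot(length(existing) + m <= maxE)
  picked <- numeric(0)
  while (length(picked) < m) {
    need <- m - length(picked)
    cand <- sample(maxE, min(maxE, need * 2 + 10))
    cand <- setdiff(cand, c(existing, picked))
    picked <- c(picked, cand[seq_len(min(need, length(cand)))])
  }
  picked
}

# match edge count exactly by random top-up / removal
matchEdgeCount <- function(idx, e, n) {
  if (length(idx) > e) {
    idx <- idx[sort(sample(length(idx), e))]
  } else if (length(idx) < e) {
    idx <- c(idx, sampleAbsentPairs(e - length(idx), n, idx))
  }
  sort(idx)
}

erdosRenyiIndices <- function(n, e) {
  maxE <- n * (n - 1) / 2
  if (maxE <= .Machine$integer.max) {
    sort(sample.int(maxE, e))
  } else {
    sort(sampleAbsentPairs(e, n, numeric(0)))
  }
}

# ring lattice: node i joined to i +- 1..kappa/2 (mod n); kappa even
ringLatticeIndices <- function(n, kappa) {
  half <- kappa / 2
  i <- rep(seq_len(n), each = half)
  off <- rep(seq_len(half), times = n)
  j <- ((i - 1 + off) %% n) + 1
  a <- pmin(i, j); b <- pmax(i, j)
  unique(pairIndex(a, b, n))
}

wattsStrogatzIndices <- function(n, e, pRewire) {
  kappa <- 2 * floor(e / n)
  if (kappa < 2) kappa <- 2
  if (kappa > n - 1) kappa <- if ((n - 1) %% 2 == 0) n - 1 else n - 2
  idx <- ringLatticeIndices(n, kappa)
  if (pRewire > 0) {
    present <- new.env(hash = TRUE, size = length(idx) * 2L)
    for (v in idx) assign(as.character(v), TRUE, envir = present)
    pairs <- pairFromIndex(idx, n)
    rewire <- runif(length(idx)) < pRewire
    for (r in which(rewire)) {
      u <- pairs[r, 1L]
      # new endpoint: uniform over nodes != u, not already adjacent to u
      for (try in 1:50) {
        w <- sample.int(n, 1L)
        if (w == u) next
        cand <- pairIndex(min(u, w), max(u, w), n)
        if (!exists(as.character(cand), envir = present)) {
          rm(list = as.character(idx[r]), envir = present)
          assign(as.character(cand), TRUE, envir = present)
          idx[r] <- cand
          break
        }
      }
    }
  }
  matchEdgeCount(unique(idx), e, n)
}

barabasiAlbertIndices <- function(n, e) {
  m <- max(1L, round(e / n))
  m0 <- m + 1L
  if (m0 > n) { m <- 1L; m0 <- 2L }
  # seed: complete graph on the first m0 nodes
  seedPairs <- which(upper.tri(matrix(0, m0, m0)), arr.ind = TRUE)
  from <- seedPairs[, 1L]; to <- seedPairs[, 2L]
  # repeated-endpoint list realises preferential attachment
  targets <- c(from, to)
  nEdgesMax <- length(from) + (n - m0) * m
  from <- c(from, integer(nEdgesMax)); to <- c(to, integer(nEdgesMax))
  cnt <- length(seedPairs[, 1L])
  for (v in seq(m0 + 1L, length.out = n - m0)) {
    chosen <- unique(targets[sample.int(length(targets), min(4L * m, length(targets)))])
    while (length(chosen) < m) {
      chosen <- unique(c(chosen,
        targets[sample.int(length(targets), m)]))
    }
    chosen <- chosen[seq_len(m)]
    for (w in chosen) {
      cnt <- cnt + 1L
      from[cnt] <- w; to[cnt] <- v
    }
    targets <- c(targets, chosen, rep.int(v, m))
  }
  from <- from[seq_len(cnt)]; to <- to[seq_len(cnt)]
  idx <- unique(pairIndex(pmin(from, to), pmax(from, to), n))
  matchEdgeCount(idx, e, n)
}

#' Generate a random graph with exact node and edge counts
#'
#' Three classical models, each adjusted to a prescribed edge count so that
#' null networks are matched to an observed graph in both N and E:
#'
#' * `"ER"` (Erdős–Rényi G(n, e)): exactly `e` distinct edges sampled
#'   uniformly without replacement.
#' * `"WS"` (Watts–Strogatz): a ring lattice with even neighbour count
#'   `kappa = 2 * floor(e/n)` (at least 2), each lattice edge rewired with
#'   probability `pRewire`, then random edges added or removed to reach
#'   exactly `e`.
#' * `"BA"` (Barabási–Albert): preferential attachment with
#'   `m = max(1, round(e/n))` edges per incoming node, then random top-up or
#'   removal to exactly `e`.
#'
#' @param model `"ER"`, `"WS"` or `"BA"`.
#' @param n number of nodes (>= 2).
#' @param e number of edges; must satisfy `1 <= e <= n(n-1)/2`.
#' @param pRewire Watts–Strogatz rewiring probability (default 0.1; ignored
#'   by the other models).
#' @param seed integer seed; a fixed seed gives an identical graph.
#' @param labels optional character vector of `n` node labels; default
#'   `"n0001"` style.
#' @return an [InteractionGraph-class] with exactly `n` nodes and `e` edges.
#' @examples
#' g <- randomGraph("ER", n = 4, e = 6, seed = 1)  # forced: K4
#' numEdges(g)
#' @export
randomGraph <- function(model = c("ER", "WS", "BA"), n, e, pRewire = 0.1,
                        seed = 1L, labels = NULL) {
  model <- match.arg(model)
  assertCount(n, "n", min = 2L)
  assertCount(e, "e", min = 1L)
  assertProportion(pRewire, "pRewire")
  if (e > n * (n - 1) / 2)
    stop(sprintf("e = %d exceeds the simple-graph maximum n(n-1)/2 = %g",
                 e, n * (n - 1) / 2), call. = FALSE)
  idx <- withSeed(seed, switch(model,
    ER = erdosRenyiIndices(n, e),
    WS = wattsStrogatzIndices(n, e, pRewire),
    BA = barabasiAlbertIndices(n, e)))
  pairs <- pairFromIndex(idx, n)
  if (is.null(labels)) {
    labels <- sprintf("n%0*d", nchar(as.character(n)), seq_len(n))
  } else stopifnot(length(labels) == n, !anyDuplicated(labels))
  interactionGraph(cbind(labels[pairs[, 1L]], labels[pairs[, 2L]]),
                   nodes = labels)
}

#' Compare a network's C and L with matched random-graph null models
#'
#' For an observed graph (reduced to its giant component), generates
#' replicate ER, WS and BA graphs with the same node and edge counts and
#' reports the clustering coefficient C and average shortest path length L
#' of each model, averaged over replicates, alongside the observed values.
#' L is computed on each replicate's giant component when the replicate is
#' disconnected.
#'
#' @param g observed [InteractionGraph-class]; its giant component is used.
#' @param replicates graphs per model (>= 1).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param pRewire Watts–Strogatz rewiring probability.
#' @param includeLowDegree passed to [clusteringCoefficients()].
#' @param pathLength logical; compute L (the expensive part).
#' @return data.frame with one row per model (`giant`, `ER`, `WS`, `BA`) and
#'   columns `model`, `C`, `L`, `replicates`, `C_sd`, `L_sd`, `p_rewire`.
#' @examples
#' g <- randomGraph("BA", n = 60, e = 120, seed = 7)
#' nullModelTable(g, replicates = 2, seed = 1)
#' @export
nullModelTable <- function(g, replicates = 10L, seed = 1L, pRewire = 0.1,
                           includeLowDegree = TRUE, pathLength = TRUE) {
  stopifnot(is(g, "InteractionGraph"))
  assertCount(replicates, "replicates")
  giant <- giantComponent(g)
  n <- numNodes(giant); e <- numEdges(giant)
  obsC <- clusteringCoefficients(giant,
                                 includeLowDegree = includeLowDegree)$global
  obsL <- if (pathLength && n >= 2L) averageShortestPath(giant) else NA_real_
  models <- c("ER", "WS", "BA")
  seeds <- matrix(deriveSeeds(seed, replicates * length(models)),
                  nrow = replicates)
  rows <- list(data.frame(model = "giant", C = obsC, L = obsL,
                          replicates = 1L, C_sd = NA_real_, L_sd = NA_real_,
                          p_rewire = NA_real_))
  for (mi in seq_along(models)) {
    cs <- numeric(replicates); ls <- numeric(replicates)
    for (r in seq_len(replicates)) {
      gr <- randomGraph(models[mi], n = n, e = e, pRewire = pRewire,
                        seed = seeds[r, mi])
      cs[r] <- clusteringCoefficients(
        gr, includeLowDegree = includeLowDegree)$global
      ls[r] <- if (pathLength) {
        averageShortestPath(giantComponent(gr))
      } else NA_real_
    }
    rows[[mi + 1L]] <- data.frame(
      model = models[mi], C = mean(cs), L = mean(ls),
      replicates = replicates,
      C_sd = if (replicates > 1L) sd(cs) else NA_real_,
      L_sd = if (replicates > 1L) sd(ls) else NA_real_,
      p_rewire = if (models[mi] == "WS") pRewire else NA_real_)
  }
  do.call(rbind, rows)
}
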