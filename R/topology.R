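#' Degree distribution P(k) = N(k)/N
#'
#' Tabulates the empirical degree distribution of a graph: for each observed
#' degree k, the count N(k) of nodes with that degree and the probability
#' P(k) = N(k)/N, where N is the total node count. Degrees that no node
#' attains are omitted.
#'
#' @param g an [InteractionGraph-class] with at least one node.
#' @return a [DegreeDistribution-class].
#' @examples
#' star <- interactionGraph(cbind("hub", paste0("leaf", 1:4)))
#' dd <- degreeDistribution(star)   # P(1) = 0.8, P(4) = 0.2
#' @export
degreeDistribution <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  if (numNodes(g) < 1L) stop("graph has no nodes", call. = FALSE)
  k <- nodeDegrees(g)
  tab <- table(k)
  kk <- as.integer(names(tab))
  cnt <- as.integer(tab)
  new("DegreeDistribution", k = kk, count = cnt,
      p = cnt / numNodes(g), nNodes = numNodes(g))
}

setMethod("show", "DegreeDistribution", function(object) {
  cat(sprintf("DegreeDistribution over %d nodes, %d distinct degrees\n",
              object@nNodes, length(object@k)))
})

#' Coerce a DegreeDistribution to a data.frame
#'
#' @param x a [DegreeDistribution-class].
#' @param ... ignored.
#' @return data.frame with columns `k`, `count`, `p`.
#' @export
as.data.frame.DegreeDistribution <- function(x, ...) {
  data.frame(k = x@k, count = x@count, p = x@p)
}

#' Least-squares power-law fit of a degree distribution
#'
#' Fits P(k) = a * k^-gamma by ordinary least squares of log10 P(k) on
#' log10 k — unweighted and unbinned, using every degree with P(k) > 0.
#' On inputs lying exactly on a power law the parameters are recovered
#' exactly (up to floating-point round-off).
#'
#' @param d a [DegreeDistribution-class], or a data.frame with columns `k`
#'   and `p`.
#' @return a [PowerLawFit-class] with prefactor `a = 10^intercept` and
#'   exponent `gamma = -slope`.
#' @examples
#' k <- 1:20
#' d <- data.frame(k = k, p = 0.5 * k^-1)
#' fitPowerLaw(d)    # a = 0.5, gamma = 1
#' @export
fitPowerLaw <- function(d) {
  if (is(d, "DegreeDistribution")) d <- as.data.frame(d)
  stopifnot(is.data.frame(d), all(c("k", "p") %in% names(d)))
  use <- d$p > 0 & d$k > 0
  if (sum(use) < 2L)
    stop("power-law fit needs at least 2 degrees with P(k) > 0",
         call. = FALSE)
  x <- log10(d$k[use])
  y <- log10(d$p[use])
  fit <- lm(y ~ x)
  cf <- coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  new("PowerLawFit", a = unname(10^cf[1L]), gamma = unname(-cf[2L]),
      fitDomain = as.integer(d$k[use]), rSquared = r2)
}

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: P(k) = %.4g * k^-%.4g  (R^2 = %.3f, %d degrees)\n",
              object@a, object@gamma, object@rSquared,
              length(object@fitDomain)))
})

#' Average nearest-neighbour degree (degree correlation)
#'
#' For each node i with degree k_i >= 1, k_nn,i is the mean degree of its
#' neighbours, (1/k_i) * sum_j a_ij k_j. The per-degree curve k_nn(k) is the
#' arithmetic mean of k_nn,i over nodes of degree k; its decay with k
#' indicates disassortative mixing. Isolated nodes are excluded.
#'
#' @param g an [InteractionGraph-class].
#' @return list with `perNode` (data.frame: node, degree, knn) and `curve`
#'   (data.frame: k, knn).
#' @examples
#' star <- interactionGraph(cbind("hub", paste0("leaf", 1:4)))
#' nearestNeighborDegree(star)$curve   # leaves: 4, hub: 1
#' @export
nearestNeighborDegree <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  A <- adjacencyMatrix(g)
  k <- nodeDegrees(g)
  keep <- k >= 1L
  knn <- as.numeric(A %*% k) / ifelse(k > 0, k, NA_real_)
  perNode <- data.frame(node = g@nodes[keep], degree = unname(k[keep]),
                        knn = knn[keep], stringsAsFactors = FALSE)
  curve <- if (nrow(perNode)) {
    agg <- aggregate(knn ~ degree, data = perNode, FUN = mean)
    data.frame(k = agg$degree, knn = agg$knn)
  } else data.frame(k = integer(0), knn = numeric(0))
  list(perNode = perNode, curve = curve[order(curve$k), , drop = FALSE])
}

#' Clustering coefficients
#'
#' The local clustering coefficient of node i with degree k_i >= 2 is
#' C_i = 2 e_i / (k_i (k_i - 1)), where e_i is the number of edges among the
#' k_i neighbours of i — the probability that two neighbours of i are
#' themselves connected. Nodes with k_i < 2 are assigned C_i = 0 and, by
#' default, included in the network average C (set
#' `includeLowDegree = FALSE` to average over k >= 2 nodes only). The
#' per-degree curve C(k) is the arithmetic mean of C_i over nodes of degree
#' k, for k >= 2.
#'
#' @param g an [InteractionGraph-class].
#' @param includeLowDegree logical; include degree-0/1 nodes (as C_i = 0)
#'   in the network average (default `TRUE`).
#' @return list with `perNode` (data.frame: node, degree, ei, ci), `curve`
#'   (data.frame: k, ck for k >= 2) and `global` (the network C).
#' @examples
#' tri <- interactionGraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' clusteringCoefficients(tri)$global   # 1
#' @export
clusteringCoefficients <- function(g, includeLowDegree = TRUE) {
  stopifnot(is(g, "InteractionGraph"))
  n <- numNodes(g)
  A <- adjacencyMatrix(g)
  k <- unname(nodeDegrees(g))
  # e_i: edges among neighbours of i; sum_j A_ij (A^2)_ij counts each
  # triangle through i twice
  ei <- if (numEdges(g)) as.numeric(rowSums(A * (A %*% A))) / 2 else
    numeric(n)
  ci <- numeric(n)
  hi <- k >= 2L
  ci[hi] <- 2 * ei[hi] / (k[hi] * (k[hi] - 1))
  perNode <- data.frame(node = g@nodes, degree = k, ei = ei, ci = ci,
                        stringsAsFactors = FALSE)
  curveDat <- perNode[hi, , drop = FALSE]
  curve <- if (nrow(curveDat)) {
    agg <- aggregate(ci ~ degree, data = curveDat, FUN = mean)
    data.frame(k = agg$degree, ck = agg$ci)
  } else data.frame(k = integer(0), ck = numeric(0))
  global <- if (includeLowDegree) {
    if (n) mean(ci) else NA_real_
  } else {
    if (any(hi)) mean(ci[hi]) else NA_real_
  }
  list(perNode = perNode, curve = curve[order(curve$k), , drop = FALSE],
       global = global)
}

#' Average shortest path length
#'
#' The shortest path length between two nodes is the number of edges on a
#' shortest path between them; L averages it over all unordered node pairs
#' of a connected component. Computed by breadth-first search from every
#' node (all sources expanded simultaneously through sparse-matrix frontier
#' products).
#'
#' @param g an [InteractionGraph-class].
#' @param component optional character vector restricting the computation to
#'   the induced subgraph on these nodes; default is the whole graph, which
#'   must then be connected.
#' @return the mean shortest-path length L (>= 1 for any connected graph
#'   with >= 2 nodes).
#' @examples
#' path3 <- interactionGraph(cbind(c("a", "b"), c("b", "c")))
#' averageShortestPath(path3)   # (1 + 1 + 2) / 3
#' @export
averageShortestPath <- function(g, component = NULL) {
  stopifnot(is(g, "InteractionGraph"))
  if (!is.null(component)) g <- inducedSubgraph(g, component)
  n <- numNodes(g)
  if (n < 2L)
    stop("average shortest path needs a connected graph with >= 2 nodes",
         call. = FALSE)
  A <- adjacencyMatrix(g)
  total <- 0
  seen <- diag(n) > 0
  frontier <- as.matrix(A) > 0
  d <- 1L
  while (any(frontier)) {
    total <- total + d * sum(frontier)
    seen <- seen | frontier
    frontier <- (as.matrix(frontier %*% A) > 0) & !seen
    d <- d + 1L
  }
  if (!all(seen))
    stop("graph (or the requested component) is disconnected; ",
         "infinite distances are not averaged", call. = FALSE)
  # each unordered pair counted twice in the BFS sweep
  total / (n * (n - 1))
}

#' Full topological characterisation of a network
#'
#' Runs the component census on the full graph, then computes every metric
#' on the giant component: degree distribution with its least-squares
#' power-law fit, nearest-neighbour degree curve, clustering coefficients
#' (network C and C(k) curve with the log-log guideline slope, where
#' C(k) ~ k^-1 signals hierarchical structure), and the average shortest
#' path length L.
#'
#' @param g an [InteractionGraph-class] with at least one node.
#' @param includeLowDegree passed to [clusteringCoefficients()].
#' @param pathLength logical; compute L (all-pairs BFS — quadratic memory in
#'   the giant-component size, so switch off for graphs beyond ~5000 nodes).
#' @return a [TopologySummary-class].
#' @examples
#' tri <- interactionGraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' topologySummary(tri)
#' @export
topologySummary <- function(g, includeLowDegree = TRUE, pathLength = TRUE) {
  stopifnot(is(g, "InteractionGraph"))
  comps <- connectedComponents(g)
  if (!length(comps)) stop("graph has no nodes", call. = FALSE)
  giant <- inducedSubgraph(g, comps[[1L]])
  dd <- degreeDistribution(giant)
  pl <- tryCatch(fitPowerLaw(dd), error = function(e)
    new("PowerLawFit", a = NA_real_, gamma = NA_real_,
        fitDomain = integer(0), rSquared = NA_real_))
  knn <- nearestNeighborDegree(giant)
  cc <- clusteringCoefficients(giant, includeLowDegree = includeLowDegree)
  ckSlope <- {
    use <- cc$curve$ck > 0
    if (sum(use) >= 2L) {
      unname(coef(lm(log10(cc$curve$ck[use]) ~ log10(cc$curve$k[use])))[2L])
    } else NA_real_
  }
  L <- if (pathLength && numNodes(giant) >= 2L) {
    averageShortestPath(giant)
  } else if (pathLength && numNodes(giant) == 1L) NA_real_ else NA_real_
  perNode <- merge(cc$perNode[, c("node", "degree", "ci")],
                   knn$perNode[, c("node", "knn")],
                   by = "node", all.x = TRUE, sort = TRUE)
  new("TopologySummary",
      nComponents = length(comps),
      componentSizes = lengths(comps),
      giantNodes = numNodes(giant), giantEdges = numEdges(giant),
      clustering = cc$global, pathLength = L,
      degreeDist = dd, powerLaw = pl,
      knnCurve = knn$curve, ckCurve = cc$curve, ckSlope = ckSlope,
      perNode = perNode[, c("node", "degree", "knn", "ci")])
}

setMethod("show", "TopologySummary", function(object) {
  cat("TopologySummary\n")
  cat(sprintf("  components: %d (giant: %d nodes, %d edges)\n",
              object@nComponents, object@giantNodes, object@giantEdges))
  cat(sprintf("  clustering coefficient C = %.4g\n", object@clustering))
  if (!is.na(object@pathLength))
    cat(sprintf("  average shortest path  L = %.4g\n", object@pathLength))
  if (!is.na(object@powerLaw@gamma))
    cat(sprintf("  degree distribution fit: P(k) = %.3g * k^-%.3g\n",
                object@powerLaw@a, object@powerLaw@gamma))
  if (!is.na(object@ckSlope))
    cat(sprintf("  C(k) log-log slope: %.3g (hierarchical guideline: -1)\n",
                object@ckSlope))
})

#' Export a TopologySummary as plain files
#'
#' Writes the scalar metrics and fit parameters as JSON and the three curves
#' (degree distribution, k_nn(k), C(k)) as two-column TSVs.
#'
#' @param ts a [TopologySummary-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of the files written, invisibly.
#' @export
writeTopologySummary <- function(ts, dir, prefix = "topology") {
  stopifnot(is(ts, "TopologySummary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fJson <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(
    n_components = ts@nComponents,
    component_sizes = ts@componentSizes,
    giant_nodes = ts@giantNodes,
    giant_edges = ts@giantEdges,
    clustering_coefficient = ts@clustering,
    average_shortest_path = ts@pathLength,
    powerlaw_a = ts@powerLaw@a,
    powerlaw_gamma = ts@powerLaw@gamma,
    powerlaw_r_squared = ts@powerLaw@rSquared,
    ck_loglog_slope = ts@ckSlope
  ), fJson, auto_unbox = TRUE, digits = NA, na = "null")
  fDd <- file.path(dir, paste0(prefix, "_degree_distribution.tsv"))
  writeTsv(as.data.frame(ts@degreeDist)[, c("k", "p")], fDd)
  fKnn <- file.path(dir, paste0(prefix, "_knn_curve.tsv"))
  writeTsv(ts@knnCurve, fKnn)
  fCk <- file.path(dir, paste0(prefix, "_ck_curve.tsv"))
  writeTsv(ts@ckCurve, fCk)
  invisible(c(fJson, fDd, fKnn, fCk))
}
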