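triangle <- interactionGraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
star5 <- interactionGraph(cbind("hub", paste0("leaf", 1:4)))
path3 <- interactionGraph(cbind(c("a", "b"), c("b", "c")))
k4 <- interactionGraph(t(combn(c("a", "b", "c", "d"), 2)))

test_that("degree distribution gives P(k) = N(k)/N and normalises", {
  expect_identical(as.data.frame(degreeDistribution(triangle)),
                   data.frame(k = 2L, count = 3L, p = 1))
  dd <- as.data.frame(degreeDistribution(star5))
  expect_identical(dd$k, c(1L, 4L))
  expect_identical(dd$p, c(0.8, 0.2))
  for (s in 1:10) {
    g <- randomOracleGraph(sample(3:40, 1), seed = s)
    d <- degreeDistribution(g)
    expect_identical(sum(d@count), numNodes(g))
    expect_equal(sum(d@p), 1)
  }
})

test_that("power-law fit recovers exact inputs and degenerate slopes", {
  f <- fitPowerLaw(data.frame(k = 1:20, p = 0.5 * (1:20)^-1))
  expect_equal(f@a, 0.5, tolerance = 1e-12)
  expect_equal(f@gamma, 1, tolerance = 1e-12)
  expect_equal(f@rSquared, 1, tolerance = 1e-12)
  # constant P(k) -> gamma 0
  f0 <- fitPowerLaw(data.frame(k = 1:10, p = rep(0.1, 10)))
  expect_equal(f0@gamma, 0, tolerance = 1e-12)
  expect_error(fitPowerLaw(data.frame(k = 3, p = 1)), "at least 2")
  # zero-probability degrees are excluded from the fit domain
  fz <- fitPowerLaw(data.frame(k = c(1:5, 6), p = c(0.2 * (1:5)^-2, 0)))
  expect_identical(fz@fitDomain, 1:5)
})

test_that("nearest-neighbour degree matches hand examples", {
  knn <- nearestNeighborDegree(star5)
  per <- setNames(knn$perNode$knn, knn$perNode$node)
  expect_equal(unname(per["hub"]), 1)
  expect_equal(unname(per["leaf1"]), 4)
  expect_equal(nearestNeighborDegree(k4)$perNode$knn, rep(3, 4))
  p <- nearestNeighborDegree(path3)$perNode
  expect_equal(setNames(p$knn, p$node), c(a = 2, b = 1, c = 2))
})

test_that("clustering coefficients match hand enumeration", {
  cc <- clusteringCoefficients(triangle)
  expect_equal(cc$perNode$ci, rep(1, 3))
  expect_equal(cc$global, 1)
  expect_equal(clusteringCoefficients(star5)$global, 0)
  # square with one diagonal 1-3
  sq <- interactionGraph(cbind(c("1", "2", "3", "4", "1"),
                               c("2", "3", "4", "1", "3")))
  cs <- clusteringCoefficients(sq)$perNode
  expect_equal(setNames(cs$ci, cs$node),
               c(`1` = 2 / 3, `2` = 1, `3` = 2 / 3, `4` = 1))
  # low-degree nodes: included as 0 by default, excludable
  g <- interactionGraph(cbind(c("a", "b", "c", "c"), c("b", "c", "a", "x")))
  expect_equal(clusteringCoefficients(g)$global, (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(clusteringCoefficients(g, includeLowDegree = FALSE)$global,
               (1 + 1 + 1 / 3) / 3)
})

test_that("average shortest path counts edges and rejects disconnected input", {
  expect_equal(averageShortestPath(path3), 4 / 3)
  expect_equal(averageShortestPath(k4), 1)
  expect_equal(averageShortestPath(star5), 1.6)
  c5 <- interactionGraph(cbind(letters[1:5], letters[c(2:5, 1)]))
  expect_equal(averageShortestPath(c5), 1.5)
  disc <- interactionGraph(cbind(c("a", "c"), c("b", "d")))
  expect_error(averageShortestPath(disc), "disconnected")
  expect_equal(averageShortestPath(disc, component = c("a", "b")), 1)
})

test_that("complete graphs attain the closed-form limits", {
  for (n in c(4, 7, 12)) {
    ids <- sprintf("n%02d", seq_len(n))
    kn <- interactionGraph(t(combn(ids, 2)))
    expect_equal(clusteringCoefficients(kn)$global, 1)
    expect_equal(averageShortestPath(kn), 1)
    expect_equal(nearestNeighborDegree(kn)$perNode$knn, rep(n - 1, n))
  }
})

test_that("metrics agree with igraph on a nontrivial random graph", {
  skip_if_not_installed("igraph")
  g <- randomGraph("BA", n = 120, e = 350, seed = 11)
  ig <- asIgraph(g)
  cc <- clusteringCoefficients(g)
  ci <- setNames(cc$perNode$ci, cc$perNode$node)
  ref <- igraph::transitivity(ig, type = "local", isolates = "zero")
  expect_equal(unname(ci[igraph::V(ig)$name]), unname(ref),
               tolerance = 1e-12)
  comp <- igraph::components(ig)
  giant <- igraph::induced_subgraph(
    ig, comp$membership == which.max(comp$csize))
  expect_equal(averageShortestPath(giantComponent(g)),
               igraph::mean_distance(giant), tolerance = 1e-12)
  knn <- nearestNeighborDegree(g)
  kni <- setNames(knn$perNode$knn, knn$perNode$node)
  igk <- igraph::knn(ig)$knn
  expect_equal(unname(kni[names(igk)]), unname(igk), tolerance = 1e-12)
})

test_that("network clustering coefficient is invariant under relabelling", {
  g <- randomOracleGraph(30, seed = 77)
  base <- clusteringCoefficients(g)$global
  for (s in 1:5) {
    set.seed(100 + s)
    perm <- setNames(sprintf("w%03d", sample(numNodes(g))), nodeIds(g))
    et <- edgeTable(g)
    gp <- interactionGraph(cbind(perm[et$from], perm[et$to]),
                           nodes = unname(perm))
    expect_equal(clusteringCoefficients(gp)$global, base)
  }
})

test_that("topology summary bundles the metrics coherently", {
  ts <- topologySummary(triangle)
  expect_identical(ts@nComponents, 1L)
  expect_equal(ts@clustering, 1)
  expect_equal(ts@pathLength, 1)
  expect_identical(as.data.frame(ts@degreeDist)$p, 1)

  ts2 <- topologySummary(star5)
  expect_equal(ts2@clustering, 0)
  expect_equal(ts2@pathLength, 1.6)
  expect_identical(ts2@giantNodes, 5L)

  # multi-component graph: census on the full graph, metrics on the giant
  g <- interactionGraph(cbind(c("a", "b", "c", "u"), c("b", "c", "a", "v")))
  ts3 <- topologySummary(g)
  expect_identical(ts3@nComponents, 2L)
  expect_identical(ts3@componentSizes, c(3L, 2L))
  expect_identical(ts3@giantNodes, 3L)
  expect_equal(ts3@clustering, 1)
})

test_that("topology summary exports scalars and curves as plain files", {
  g <- randomGraph("BA", n = 80, e = 200, seed = 3)
  ts <- topologySummary(g)
  d <- tempfile()
  files <- writeTopologySummary(ts, d)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(files[1])
  expect_equal(js$clustering_coefficient, ts@clustering)
  expect_equal(js$giant_nodes, ts@giantNodes)
  dd <- read.delim(files[2])
  expect_equal(sum(dd$p), 1)
})
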