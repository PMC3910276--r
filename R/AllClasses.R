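#' InteractionGraph: a simple undirected graph of gene/protein identifiers
#'
#' The central container of the package: nodes are identifiers (unigenes or
#' reference proteins) and edges are unordered identifier pairs. The graph is
#' always *simple* — no self-loops, no duplicate edges — which the validity
#' method enforces. Edges are stored canonically with the lexicographically
#' smaller identifier first.
#'
#' @slot nodes character vector of node identifiers (unique).
#' @slot edges two-column character matrix; each row one undirected edge,
#'   first column lexicographically <= second, no duplicated rows.
#'
#' @seealso [interactionGraph()], [numNodes()], [numEdges()], [nodeDegrees()]
#' @exportClass InteractionGraph
setClass("InteractionGraph",
  representation(nodes = "character", edges = "matrix"),
  prototype(nodes = character(0),
            edges = matrix(character(0), ncol = 2,
                           dimnames = list(NULL, c("from", "to")))))

setValidity("InteractionGraph", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node identifiers must be unique")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be stored with the smaller id first")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "all edge endpoints must be listed in nodes")
  }
  if (length(msg)) msg else TRUE
})

#' DegreeDistribution: N(k) counts and P(k) probabilities
#'
#' Empirical degree distribution of an [InteractionGraph-class]: for each
#' observed degree k, the number of nodes N(k) with that degree and the
#' probability P(k) = N(k)/N. Degrees with zero count are omitted.
#'
#' @slot k integer vector of observed degrees (sorted, unique).
#' @slot count integer vector, N(k).
#' @slot p numeric vector, P(k) = N(k)/N.
#' @slot nNodes total number of nodes N used for normalisation.
#'
#' @seealso [degreeDistribution()], [fitPowerLaw()]
#' @exportClass DegreeDistribution
setClass("DegreeDistribution",
  representation(k = "integer", count = "integer", p = "numeric",
                 nNodes = "integer"))

setValidity("DegreeDistribution", function(object) {
  msg <- character(0)
  if (length(object@k) != length(object@count) ||
      length(object@k) != length(object@p))
    return("k, count and p must have equal length")
  if (is.unsorted(object@k, strictly = TRUE))
    msg <- c(msg, "degrees must be sorted and unique")
  if (sum(object@count) != object@nNodes)
    msg <- c(msg, "counts must sum to the node total")
  if (length(object@p) && abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: least-squares fit of P(k) = a * k^-gamma
#'
#' Result of an ordinary least-squares regression of log10 P(k) on log10 k
#' (unweighted, unbinned, over degrees with P(k) > 0). On inputs lying
#' exactly on a power law the fit reproduces `a` and `gamma` exactly.
#'
#' @slot a positive prefactor, 10^intercept.
#' @slot gamma exponent; the fitted slope is -gamma.
#' @slot fitDomain the degrees used in the fit.
#' @slot rSquared coefficient of determination of the log-log regression.
#'
#' @seealso [fitPowerLaw()]
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(a = "numeric", gamma = "numeric", fitDomain = "integer",
                 rSquared = "numeric"))

#' TopologySummary: the full topological characterisation of a graph
#'
#' Bundles every topology metric the package computes, evaluated on the
#' giant (largest) component: degree distribution with power-law fit,
#' per-degree nearest-neighbour degree curve k_nn(k), per-degree clustering
#' curve C(k) with its log-log guideline slope, network clustering
#' coefficient C, average shortest path length L, and the component census
#' of the full graph.
#'
#' @slot nComponents number of connected components of the full graph.
#' @slot componentSizes integer vector of component sizes, largest first.
#' @slot giantNodes,giantEdges node and edge counts of the giant component.
#' @slot clustering network clustering coefficient C of the giant component.
#' @slot pathLength average shortest path length L of the giant component
#'   (NA when not computed).
#' @slot degreeDist [DegreeDistribution-class] of the giant component.
#' @slot powerLaw [PowerLawFit-class] of the degree distribution.
#' @slot knnCurve data.frame (k, knn): mean nearest-neighbour degree per k.
#' @slot ckCurve data.frame (k, ck): mean clustering coefficient per k >= 2.
#' @slot ckSlope OLS slope of log10 C(k) on log10 k over k with C(k) > 0
#'   (the C(k) ~ k^-1 guideline has slope -1); NA when fewer than 2 points.
#' @slot perNode data.frame (node, degree, knn, ci) for giant-component
#'   nodes.
#'
#' @seealso [topologySummary()]
#' @exportClass TopologySummary
setClass("TopologySummary",
  representation(nComponents = "integer", componentSizes = "integer",
                 giantNodes = "integer", giantEdges = "integer",
                 clustering = "numeric", pathLength = "numeric",
                 degreeDist = "DegreeDistribution", powerLaw = "PowerLawFit",
                 knnCurve = "data.frame", ckCurve = "data.frame",
                 ckSlope = "numeric", perNode = "data.frame"))

#' ScenarioConfig: parameters of a synthetic ortholog-transfer scenario
#'
#' Describes one synthetic study: the reference interactomes (model, size),
#' how many unigenes exist, what fraction of reference proteins have a true
#' ortholog among them, how many reference species are emulated, and the
#' rate at which decoy homology hits (each violating exactly one filter
#' threshold) are injected.
#'
#' @slot nReferenceProteins proteins per reference interactome.
#' @slot nUnigenes number of unigene identifiers available as targets.
#' @slot orthologFraction fraction of reference proteins with a true
#'   ortholog, in \[0, 1\].
#' @slot nSpecies number of reference species.
#' @slot referenceModel one of "ER", "WS", "BA".
#' @slot referenceEdges edges per reference interactome.
#' @slot decoyRate decoy hits per true hit, in \[0, 1\].
#' @slot seed master RNG seed; a fixed seed makes all outputs byte-identical.
#'
#' @seealso [scenarioConfig()], [generateOrthologScenario()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(nReferenceProteins = "integer", nUnigenes = "integer",
                 orthologFraction = "numeric", nSpecies = "integer",
                 referenceModel = "character", referenceEdges = "integer",
                 decoyRate = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (object@nReferenceProteins < 2L)
    msg <- c(msg, "nReferenceProteins must be >= 2")
  if (object@nUnigenes < 1L)
    msg <- c(msg, "nUnigenes must be >= 1")
  if (object@orthologFraction < 0 || object@orthologFraction > 1)
    msg <- c(msg, "orthologFraction must be in [0, 1]")
  if (object@nSpecies < 1L)
    msg <- c(msg, "nSpecies must be >= 1")
  if (!object@referenceModel %in% c("ER", "WS", "BA"))
    msg <- c(msg, "referenceModel must be one of ER, WS, BA")
  n <- as.numeric(object@nReferenceProteins)
  if (object@referenceEdges < 1L ||
      object@referenceEdges > n * (n - 1) / 2)
    msg <- c(msg, "referenceEdges must be feasible for a simple graph")
  if (object@decoyRate < 0 || object@decoyRate > 1)
    msg <- c(msg, "decoyRate must be in [0, 1]")
  nMapped <- floor(object@orthologFraction * n)
  if (nMapped > object@nUnigenes)
    msg <- c(msg,
      "nUnigenes must be >= floor(orthologFraction * nReferenceProteins) for an injective ortholog map")
  if (length(msg)) msg else TRUE
})
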