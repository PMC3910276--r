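#' Construct an InteractionGraph
#'
#' Builds a simple undirected graph from an edge list. Edges are
#' canonicalised (smaller identifier first); self-loops are dropped and
#' duplicate edges collapsed, mirroring how transferred interactions are
#' merged across reference species.
#'
#' @param edges two-column character matrix or data.frame of endpoint
#'   identifiers (may be empty).
#' @param nodes optional character vector of node identifiers; endpoints not
#'   listed are added automatically. Supply this to keep isolated nodes.
#' @return an [InteractionGraph-class].
#' @examples
#' g <- interactionGraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' numNodes(g); numEdges(g)
#' @export
interactionGraph <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("'edges' must be a two-column matrix or data.frame", call. = FALSE)
  storage.mode(edges) <- "character"
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  o <- order(a, b, method = "radix")
  em <- cbind(from = a[o], to = b[o])
  nodes <- sort(unique(c(nodes, c(em))), method = "radix")
  new("InteractionGraph", nodes = nodes, edges = em)
}

#' @rdname InteractionGraph-class
#' @aliases numNodes,InteractionGraph-method
#' @export
setMethod("numNodes", "InteractionGraph", function(x) length(x@nodes))

#' @rdname InteractionGraph-class
#' @aliases numEdges,InteractionGraph-method
#' @export
setMethod("numEdges", "InteractionGraph", function(x) nrow(x@edges))

#' @rdname InteractionGraph-class
#' @aliases nodeIds,InteractionGraph-method
#' @export
setMethod("nodeIds", "InteractionGraph", function(x) x@nodes)

#' @rdname InteractionGraph-class
#' @aliases edgeTable,InteractionGraph-method
#' @export
setMethod("edgeTable", "InteractionGraph", function(x)
  data.frame(from = unname(x@edges[, 1L]), to = unname(x@edges[, 2L]),
             stringsAsFactors = FALSE))

#' @rdname InteractionGraph-class
#' @aliases nodeDegrees,InteractionGraph-method
#' @export
setMethod("nodeDegrees", "InteractionGraph", function(x) {
  d <- setNames(integer(length(x@nodes)), x@nodes)
  if (nrow(x@edges)) {
    t1 <- table(factor(x@edges[, 1L], levels = x@nodes))
    t2 <- table(factor(x@edges[, 2L], levels = x@nodes))
    d[] <- as.integer(t1 + t2)
  }
  d
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph with %d nodes and %d edges\n",
              numNodes(object), numEdges(object)))
  if (numEdges(object)) {
    k <- nodeDegrees(object)
    cat(sprintf("  degree: min %d, mean %.2f, max %d\n",
                min(k), mean(k), max(k)))
  }
})

# sparse symmetric 0/1 adjacency matrix (dgCMatrix), node order = x@nodes
adjacencyMatrix <- function(x) {
  n <- numNodes(x)
  if (nrow(x@edges) == 0L)
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(n, n)))
  i <- match(x@edges[, 1L], x@nodes)
  j <- match(x@edges[, 2L], x@nodes)
  sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
}

#' Connected components of a graph
#'
#' Partitions the nodes into connected components, returned largest first.
#' Ties in node count are broken by edge count (more edges first), then by
#' the lexicographically smallest member identifier, so "the giant
#' component" is always well defined.
#'
#' @param g an [InteractionGraph-class].
#' @return a list of character vectors of node identifiers (each sorted);
#'   empty list for an empty graph.
#' @examples
#' g <- interactionGraph(cbind(c("a", "c"), c("b", "d")))
#' connectedComponents(g)
#' @export
connectedComponents <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  n <- numNodes(g)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  if (nrow(g@edges)) {
    ii <- match(g@edges[, 1L], g@nodes)
    jj <- match(g@edges[, 2L], g@nodes)
    for (r in seq_along(ii)) {
      ri <- find(ii[r]); rj <- find(jj[r])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(g@nodes, root)
  comps <- lapply(comps, sort, method = "radix")
  sizes <- lengths(comps)
  ecount <- vapply(comps, function(cc) {
    if (!nrow(g@edges)) return(0L)
    sum(g@edges[, 1L] %in% cc)
  }, integer(1))
  first <- vapply(comps, `[`, character(1), 1L)
  o <- order(-sizes, -ecount, first, method = "radix")
  unname(comps[o])
}

#' Extract the subgraph induced by a node set
#'
#' @param g an [InteractionGraph-class].
#' @param nodes character vector of node identifiers to keep.
#' @return an [InteractionGraph-class] on `nodes` with all edges among them.
#' @export
inducedSubgraph <- function(g, nodes) {
  stopifnot(is(g, "InteractionGraph"))
  nodes <- intersect(g@nodes, nodes)
  keep <- g@edges[, 1L] %in% nodes & g@edges[, 2L] %in% nodes
  interactionGraph(g@edges[keep, , drop = FALSE], nodes = nodes)
}

#' Giant (largest) component of a graph
#'
#' @param g an [InteractionGraph-class] with at least one node.
#' @return the induced subgraph on the largest component (see
#'   [connectedComponents()] for the tie-break).
#' @export
giantComponent <- function(g) {
  comps <- connectedComponents(g)
  if (!length(comps)) stop("graph has no nodes", call. = FALSE)
  inducedSubgraph(g, comps[[1L]])
}

#' Read / write an edge list as two-column TSV
#'
#' `readEdgeTable()` accepts two id columns plus an optional numeric score
#' column (STRING-like); lines starting with `#` are ignored. A header line
#' is auto-detected: if the first row's third field (when present) is
#' non-numeric, or the file's first two fields repeat as ids nowhere, it is
#' treated as a header.
#'
#' @param path file path.
#' @param header logical; `NA` (default) auto-detects a header line.
#' @param minScore drop edges with score below this (default 0 keeps all;
#'   scoreless tables are never filtered).
#' @return `readEdgeTable`: a data.frame with columns `from`, `to` and
#'   optionally `score`. `writeEdgeTable`: the path, invisibly.
#' @export
readEdgeTable <- function(path, header = NA, minScore = 0) {
  probe <- readTsv(path, header = FALSE, nrows = 1)
  if (is.na(header)) {
    header <- ncol(probe) >= 3 && is.character(probe[[3]]) ||
      all(tolower(unlist(probe[1, 1:2])) %in%
            c("from", "to", "protein_a", "protein_b", "protein1", "protein2",
              "cola", "colb", "node1", "node2"))
  }
  df <- readTsv(path, header = header)
  if (ncol(df) < 2) stop("edge table needs at least two columns",
                         call. = FALSE)
  out <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3 && is.numeric(df[[3]])) {
    out$score <- df[[3]]
    if (minScore > 0) out <- out[out$score >= minScore, , drop = FALSE]
  }
  out
}

#' @rdname readEdgeTable
#' @param g an [InteractionGraph-class].
#' @export
writeEdgeTable <- function(g, path) {
  stopifnot(is(g, "InteractionGraph"))
  writeTsv(edgeTable(g), path)
}

#' Convert to an igraph object
#'
#' Convenience coercion for interoperability; requires the `igraph` package.
#'
#' @param g an [InteractionGraph-class].
#' @return an undirected `igraph` graph with the same nodes and edges.
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the 'igraph' package is required for asIgraph()", call. = FALSE)
  igraph::graph_from_data_frame(edgeTable(g), directed = FALSE,
                                vertices = nodeIds(g))
}
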