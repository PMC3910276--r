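# Homology-hit filtering, best-hit ortholog assignment and interolog
# transfer of reference interactome edges onto unigenes.

blast6Cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Read a BLAST tabular hit file
#'
#' Parses the 12-column tabular dialect (`outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' tolerating the optional `qlen`, `slen` and `qcovs` extension columns and
#' `#`-prefixed comment lines. Query coverage is taken from `qcovs` when
#' present, otherwise computed per hit as `100 * (qend - qstart + 1) / qlen`
#' (the query is the reference protein in a TBLASTN search, so coverage is
#' on the protein).
#'
#' @param path TSV file path.
#' @return data.frame of homology hits with the standard columns plus
#'   `query_coverage` (percent); `qlen`/`slen` retained when present.
#' @export
readBlastTable <- function(path) {
  df <- readTsv(path, header = FALSE)
  if (ncol(df) < 12)
    stop("BLAST tabular input needs at least the 12 standard columns",
         call. = FALSE)
  extras <- c("qlen", "slen", "qcovs")[seq_len(max(0, ncol(df) - 12))]
  names(df) <- c(blast6Cols, extras)[seq_len(ncol(df))]
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  addQueryCoverage(df)
}

# fill query_coverage from qcovs or from alignment span / qlen
addQueryCoverage <- function(df) {
  if (!"query_coverage" %in% names(df)) {
    if ("qcovs" %in% names(df)) {
      df$query_coverage <- as.numeric(df$qcovs)
    } else if ("qlen" %in% names(df)) {
      df$query_coverage <- 100 * (df$qend - df$qstart + 1) / df$qlen
    } else {
      stop("cannot compute query coverage: neither 'qcovs' nor 'qlen' ",
           "is available", call. = FALSE)
    }
  }
  bad <- !is.finite(df$query_coverage)
  if (any(bad))
    stop(sprintf(
      "query coverage undefined for record(s) %s (missing query length?)",
      paste(head(which(bad), 5L), collapse = ", ")), call. = FALSE)
  df
}

#' Filter homology hits by E-value, identity and query coverage
#'
#' Retains hits satisfying all three conditions with *strict* inequalities:
#' `evalue < evalueMax`, `pident > identityMin` and
#' `query_coverage > coverageMin`. Boundary hits (e.g. identity exactly at
#' the threshold) are rejected. Input order is preserved and the operation
#' is idempotent.
#'
#' @param hits data.frame of hits as returned by [readBlastTable()] (needs
#'   `evalue`, `pident` and either `query_coverage` or the columns to derive
#'   it).
#' @param evalueMax E-value ceiling (default `1e-6`).
#' @param identityMin percent-identity floor (default `50`).
#' @param coverageMin query-coverage floor in percent (default `80`).
#' @return the retained rows of `hits`, with `query_coverage` filled in.
#' @export
filterHits <- function(hits, evalueMax = 1e-6, identityMin = 50,
                       coverageMin = 80) {
  stopifnot(is.data.frame(hits),
            all(c("qseqid", "sseqid", "pident", "evalue") %in% names(hits)))
  stopifnot(evalueMax > 0, identityMin >= 0, identityMin <= 100,
            coverageMin >= 0, coverageMin <= 100)
  if (!nrow(hits)) return(addQueryCoverage0(hits))
  hits <- addQueryCoverage(hits)
  keep <- hits$evalue < evalueMax & hits$pident > identityMin &
    hits$query_coverage > coverageMin
  hits[keep, , drop = FALSE]
}

addQueryCoverage0 <- function(hits) {
  if (!"query_coverage" %in% names(hits)) hits$query_coverage <- numeric(0)
  hits
}

#' Assign each reference protein its best-hit unigene
#'
#' On an already-filtered hit table, picks one unigene per reference protein
#' (the BLAST query): lowest E-value, ties broken by highest bitscore, then
#' by lexicographically smallest subject identifier. Deterministic and
#' independent of input row order. Several proteins may map to the same
#' unigene (paralogs collapsed in a de novo assembly).
#'
#' @param filtered data.frame of filtered hits ([filterHits()] output).
#' @param species identifier of the reference species the hits came from.
#' @return list with `species`, `mapping` (named character vector,
#'   reference protein -> unigene) and `provenance` (the winning hit rows).
#' @export
assignOrthologs <- function(filtered, species = "reference") {
  stopifnot(is.data.frame(filtered))
  if (!nrow(filtered)) {
    return(list(species = species,
                mapping = setNames(character(0), character(0)),
                provenance = filtered))
  }
  o <- order(filtered$qseqid, filtered$evalue, -filtered$bitscore,
             filtered$sseqid, method = "radix")
  best <- filtered[o, , drop = FALSE]
  best <- best[!duplicated(best$qseqid), , drop = FALSE]
  list(species = species,
       mapping = setNames(best$sseqid, best$qseqid),
       provenance = best)
}

#' Transfer reference interactome edges onto unigenes
#'
#' The interolog rule: for each reference edge (A, B) of a species whose
#' proteins A and B are both assigned to unigenes u and v, emit the
#' undirected unigene pair \{u, v\}. Pairs collapsing to a single unigene
#' (u = v) are dropped and duplicates — within one species or across
#' species — are merged, so the result is a simple undirected edge set.
#'
#' @param assignments one assignment ([assignOrthologs()] output) or a list
#'   of them, one per reference species.
#' @param referenceEdges a two-column edge data.frame (single species) or a
#'   named list of them matching the assignments' `species`.
#' @return an [InteractionGraph-class] on the inferred unigene edges.
#' @export
transferInteractions <- function(assignments, referenceEdges) {
  if (!is.null(assignments$mapping)) assignments <- list(assignments)
  if (is.data.frame(referenceEdges))
    referenceEdges <- setNames(list(referenceEdges),
                               assignments[[1L]]$species)
  pairs <- lapply(assignments, function(a) {
    edges <- referenceEdges[[a$species]]
    if (is.null(edges))
      stop(sprintf("no reference edge table for species '%s'", a$species),
           call. = FALSE)
    u <- unname(a$mapping[as.character(edges[[1]])])
    v <- unname(a$mapping[as.character(edges[[2]])])
    ok <- !is.na(u) & !is.na(v)
    cbind(u[ok], v[ok])
  })
  interactionGraph(do.call(rbind, pairs))
}

#' Write ortholog assignments as TSV
#'
#' One row per assignment: species, reference protein, unigene, and the
#' winning hit's E-value, identity and query coverage.
#'
#' @param assignments one assignment or a list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  if (!is.null(assignments$mapping)) assignments <- list(assignments)
  rows <- lapply(assignments, function(a) {
    if (!length(a$mapping)) return(NULL)
    data.frame(species = a$species,
               protein = names(a$mapping),
               unigene = unname(a$mapping),
               evalue = a$provenance$evalue,
               identity = a$provenance$pident,
               coverage = a$provenance$query_coverage,
               stringsAsFactors = FALSE)
  })
  writeTsv(do.call(rbind, rows), path)
}
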