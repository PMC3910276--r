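# Synthetic inputs with retained ground truth: reference interactomes,
# ortholog maps, noisy homology hit tables, isoform tables and FASTQ reads.
# Everything is deterministic for a fixed seed.

#' Build a validated scenario configuration
#'
#' @param nReferenceProteins proteins per reference interactome (>= 2).
#' @param nUnigenes available unigene identifiers; must be at least
#'   `floor(orthologFraction * nReferenceProteins)` (the ortholog map is
#'   injective).
#' @param orthologFraction fraction of reference proteins given a true
#'   ortholog unigene, in \[0, 1\].
#' @param nSpecies number of reference species emulated (each gets its own
#'   interactome; the ortholog map is shared, decoys are independent).
#' @param referenceModel random-graph model of the reference interactomes:
#'   `"ER"`, `"WS"` or `"BA"` (default `"BA"`, giving the heavy-tailed
#'   degree distributions typical of curated interactomes).
#' @param referenceEdges edges per reference interactome.
#' @param decoyRate decoy hits injected per true hit, in \[0, 1\]; every
#'   decoy violates exactly one filter threshold, at its boundary value.
#' @param seed master seed; fixed seed implies byte-identical outputs.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nReferenceProteins = 200L, nUnigenes = 300L,
                           orthologFraction = 0.7, nSpecies = 2L,
                           referenceModel = c("BA", "ER", "WS"),
                           referenceEdges = 600L, decoyRate = 0.2,
                           seed = 1L) {
  new("ScenarioConfig",
      nReferenceProteins = assertCount(nReferenceProteins,
                                       "nReferenceProteins", 2L),
      nUnigenes = assertCount(nUnigenes, "nUnigenes"),
      orthologFraction = assertProportion(orthologFraction,
                                          "orthologFraction"),
      nSpecies = assertCount(nSpecies, "nSpecies"),
      referenceModel = match.arg(referenceModel),
      referenceEdges = assertCount(referenceEdges, "referenceEdges"),
      decoyRate = assertProportion(decoyRate, "decoyRate"),
      seed = assertCount(seed, "seed", 0L))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %d species x %s(%d proteins, %d edges); %d unigenes,\n",
    object@nSpecies, object@referenceModel, object@nReferenceProteins,
    object@referenceEdges, object@nUnigenes))
  cat(sprintf("  ortholog fraction %.2f, decoy rate %.2f, seed %d\n",
              object@orthologFraction, object@decoyRate, object@seed))
})

#' Generate a reference interactome
#'
#' A labelled random graph standing in for one reference species' curated
#' protein-protein interaction network.
#'
#' @param model `"ER"`, `"WS"` or `"BA"`.
#' @param n number of proteins.
#' @param e number of interactions; `e <= n(n-1)/2`.
#' @param seed integer seed (deterministic output).
#' @param species label used in the protein identifiers.
#' @return list with `graph` (an [InteractionGraph-class]), `edges`
#'   (two-column data.frame with a `score` column) and `proteins`
#'   (character vector of protein identifiers).
#' @export
generateReferenceInteractome <- function(model = c("BA", "ER", "WS"), n, e,
                                         seed = 1L, species = "sp1") {
  model <- match.arg(model)
  labels <- sprintf("%s_P%0*d", species, nchar(as.character(n)), seq_len(n))
  g <- randomGraph(model, n = n, e = e, seed = seed, labels = labels)
  et <- edgeTable(g)
  et$score <- withSeed(seed + 1L, round(runif(nrow(et), 0.4, 0.999), 3))
  list(graph = g, edges = et, proteins = labels)
}

# one passing hit per mapped protein: clears all three thresholds
truePassingHits <- function(proteins, unigenes, qlens) {
  n <- length(proteins)
  if (n == 0L) {
    empty <- data.frame(qseqid = character(0), sseqid = character(0),
                        pident = numeric(0), length = integer(0),
                        mismatch = integer(0), gapopen = integer(0),
                        qstart = integer(0), qend = integer(0),
                        sstart = integer(0), send = integer(0),
                        evalue = numeric(0), bitscore = numeric(0),
                        qlen = integer(0), stringsAsFactors = FALSE)
    return(empty)
  }
  alen <- pmax(1L, as.integer(round(qlens * runif(n, 0.85, 1.0))))
  qstart <- pmax(1L, as.integer(ceiling(runif(n, 0, qlens - alen + 1))))
  data.frame(
    qseqid = proteins, sseqid = unigenes,
    pident = round(runif(n, 55, 98), 2),
    length = alen, mismatch = as.integer(round(alen * 0.05)),
    gapopen = 0L,
    qstart = qstart, qend = qstart + alen - 1L,
    sstart = 1L, send = alen * 3L,
    evalue = 10^runif(n, -60, -7),
    bitscore = round(runif(n, 120, 800), 1),
    qlen = qlens, stringsAsFactors = FALSE)
}

# decoys violate exactly one filter each, at the boundary value
decoyHits <- function(proteins, unigenes, qlens, kind) {
  h <- truePassingHits(proteins, unigenes, qlens)
  if (kind == "evalue") {
    h$evalue <- 1e-5              # fails evalue < 1e-6
  } else if (kind == "identity") {
    h$pident <- 50.0              # fails pident > 50
  } else {                        # coverage: exactly 80% of the query
    # round the query length to a multiple of 5 so 80% is representable
    ql <- pmax(5L, as.integer(5 * round(qlens / 5)))
    span <- as.integer(ql * 0.80)
    h$qlen <- ql
    h$qstart <- 1L
    h$qend <- span
    h$length <- span
  }
  h$decoy_kind <- kind
  h
}

#' Generate a complete ortholog-transfer scenario with ground truth
#'
#' Produces, per reference species: a reference interactome, a shared
#' injective ortholog map covering `orthologFraction` of its proteins, and a
#' TBLASTN-style hit table that contains one filter-passing hit for every
#' true ortholog pair plus decoy hits — each violating exactly one of the
#' three thresholds at its boundary value (E-value 1e-5, identity 50.0,
#' coverage 80.0), to pin strict-inequality semantics. The ground-truth edge
#' set is the image of the reference edges under the ortholog map
#' (self-pairs removed, duplicates collapsed), so
#' `filterHits` -> `assignOrthologs` -> `transferInteractions` on the hit
#' tables must recover it exactly.
#'
#' @param config a [ScenarioConfig-class] (see [scenarioConfig()]).
#' @return list with:
#' * `config`: the input configuration;
#' * `orthologMap`: named character vector, reference protein (bare id,
#'   without species prefix) -> unigene;
#' * `expectedEdges`: the ground-truth [InteractionGraph-class] on unigenes;
#' * `species`: per-species list of `name`, `interactome` (edge data.frame
#'   with score), `proteins`, `hits` (the noisy hit table; decoys carry a
#'   `decoy_kind` label, true hits `"none"`).
#' @export
generateOrthologScenario <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  n <- config@nReferenceProteins
  seeds <- deriveSeeds(config@seed, 2L + 3L * config@nSpecies)
  unigeneIds <- sprintf("UG%05d", seq_len(config@nUnigenes))
  nMapped <- floor(config@orthologFraction * n)
  bareIds <- sprintf("P%0*d", nchar(as.character(n)), seq_len(n))
  orthologMap <- withSeed(seeds[1L], {
    mapped <- sort(sample(bareIds, nMapped))
    setNames(sample(unigeneIds, nMapped), mapped)
  })
  qlens <- withSeed(seeds[2L],
                    setNames(as.integer(round(runif(n, 150, 900))), bareIds))
  speciesOut <- vector("list", config@nSpecies)
  allPairs <- NULL
  for (s in seq_len(config@nSpecies)) {
    spName <- sprintf("sp%d", s)
    ref <- generateReferenceInteractome(config@referenceModel, n = n,
                                        e = config@referenceEdges,
                                        seed = seeds[2L + s],
                                        species = spName)
    # ground-truth edges: reference edges whose both endpoints are mapped
    bare <- function(x) sub(paste0("^", spName, "_"), "", x)
    u <- unname(orthologMap[bare(ref$edges$from)])
    v <- unname(orthologMap[bare(ref$edges$to)])
    ok <- !is.na(u) & !is.na(v)
    allPairs <- rbind(allPairs, cbind(u[ok], v[ok]))
    hits <- withSeed(seeds[2L + config@nSpecies + s], {
      mappedBare <- names(orthologMap)
      if (is.null(mappedBare)) mappedBare <- character(0)
      # paste0() drops zero-length arguments, so guard the empty map
      prefixed <- if (length(mappedBare)) {
        paste0(spName, "_", mappedBare)
      } else character(0)
      truths <- truePassingHits(prefixed, unname(orthologMap),
                                unname(qlens[mappedBare]))
      truths$decoy_kind <- rep("none", nrow(truths))
      nDecoy <- round(config@decoyRate * nrow(truths))
      if (nDecoy > 0) {
        kinds <- rep(c("evalue", "identity", "coverage"),
                     length.out = nDecoy)
        dprot <- sample(bareIds, nDecoy, replace = TRUE)
        dugs <- sample(unigeneIds, nDecoy, replace = TRUE)
        decoys <- do.call(rbind, lapply(unique(kinds), function(kk) {
          sel <- kinds == kk
          decoyHits(paste0(spName, "_", dprot[sel]), dugs[sel],
                    unname(qlens[dprot[sel]]), kk)
        }))
        rbind(truths, decoys)
      } else truths
    })
    rownames(hits) <- NULL
    speciesOut[[s]] <- list(name = spName, interactome = ref$edges,
                            proteins = ref$proteins, hits = hits)
  }
  expected <- interactionGraph(
    if (is.null(allPairs)) matrix(character(0), ncol = 2) else allPairs)
  list(config = config, orthologMap = orthologMap,
       expectedEdges = expected, species = speciesOut)
}

#' Run the inference chain on a scenario's hit tables
#'
#' Convenience wrapper: filter every species' hit table, assign best-hit
#' orthologs, and transfer the reference edges. On a decoy-free scenario the
#' result equals `scenario$expectedEdges` exactly; boundary decoys change
#' nothing because all three filters are strict.
#'
#' @param scenario output of [generateOrthologScenario()].
#' @param evalueMax,identityMin,coverageMin filter thresholds (see
#'   [filterHits()]).
#' @return an [InteractionGraph-class] of inferred unigene interactions.
#' @export
inferScenarioNetwork <- function(scenario, evalueMax = 1e-6,
                                 identityMin = 50, coverageMin = 80) {
  assignments <- lapply(scenario$species, function(sp) {
    assignOrthologs(filterHits(sp$hits, evalueMax, identityMin, coverageMin),
                    species = sp$name)
  })
  refEdges <- setNames(lapply(scenario$species, `[[`, "interactome"),
                       vapply(scenario$species, `[[`, character(1), "name"))
  transferInteractions(assignments, refEdges)
}

#' Generate an RSEM-style isoform quantification table
#'
#' Per gene, 1 to `maxIsoforms` transcript isoforms with positive integer
#' lengths, non-negative expected counts, and isoform percentages that sum
#' to 100 within each gene.
#'
#' @param nGenes number of genes.
#' @param maxIsoforms maximum isoforms per gene.
#' @param seed integer seed (deterministic output).
#' @return data.frame with columns `transcript_id`, `gene_id`, `length`,
#'   `expected_count`, `isoform_percent`.
#' @export
generateIsoformTable <- function(nGenes, maxIsoforms = 4L, seed = 1L) {
  assertCount(nGenes, "nGenes")
  assertCount(maxIsoforms, "maxIsoforms")
  withSeed(seed, {
    rows <- lapply(seq_len(nGenes), function(gI) {
      k <- sample.int(maxIsoforms, 1L)
      w <- runif(k)
      pct <- 100 * w / sum(w)
      data.frame(
        transcript_id = sprintf("g%04d_t%d", gI, seq_len(k)),
        gene_id = sprintf("g%04d", gI),
        length = as.integer(round(runif(k, 200, 3000))),
        expected_count = round(runif(k, 0, 5000), 2),
        isoform_percent = pct,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

randomDnaString <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate synthetic FASTQ reads with planted defects
#'
#' A configurable fraction of reads is given more than 5% N bases (so they
#' fail the unknown-base rule) and another fraction is given the read-1
#' adapter `AGATCGGAAGAGCACACGTC` (a 12-20 nt prefix of it) at the 3' end.
#' Quality strings are a constant Phred 40 ('I'). Provenance labels record
#' which defect each read carries, for testing.
#'
#' @param nReads number of reads.
#' @param readLen read length in nt.
#' @param nRate fraction of reads made to fail the 5% N rule.
#' @param adapterRate fraction of reads given a 3' adapter.
#' @param seed integer seed (byte-identical FASTQ for a fixed seed).
#' @param adapter adapter sequence planted at the 3' end.
#' @return list with `reads` (a `QualityScaledDNAStringSet`) and
#'   `provenance` (data.frame: read_id, fails_n_rule, has_adapter,
#'   adapter_overlap).
#' @export
generateFastqReads <- function(nReads, readLen = 100L, nRate = 0,
                               adapterRate = 0, seed = 1L,
                               adapter = "AGATCGGAAGAGCACACGTC") {
  assertCount(nReads, "nReads")
  assertCount(readLen, "readLen", min = 20L)
  assertProportion(nRate, "nRate")
  assertProportion(adapterRate, "adapterRate")
  withSeed(seed, {
    ids <- sprintf("read%06d", seq_len(nReads))
    seqs <- randomDnaString(nReads, readLen)
    nN <- round(nRate * nReads)
    nAd <- round(adapterRate * nReads)
    defect <- sample(c(rep("N", nN), rep("adapter", nAd),
                       rep("none", max(0L, nReads - nN - nAd))))[
                         seq_len(nReads)]
    overlap <- integer(nReads)
    for (i in which(defect == "N")) {
      # strictly more than 5% N bases
      howMany <- floor(0.05 * readLen) + 1L
      pos <- sample.int(readLen, howMany)
      ss <- strsplit(seqs[i], "")[[1L]]
      ss[pos] <- "N"
      seqs[i] <- paste(ss, collapse = "")
    }
    for (i in which(defect == "adapter")) {
      o <- sample(12:min(20L, nchar(adapter)), 1L)
      overlap[i] <- o
      seqs[i] <- paste0(substr(seqs[i], 1L, readLen - o),
                        substr(adapter, 1L, o))
    }
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(rep(strrep("I", readLen), nReads)))
    list(reads = reads,
         provenance = data.frame(read_id = ids,
                                 fails_n_rule = defect == "N",
                                 has_adapter = defect == "adapter",
                                 adapter_overlap = overlap,
                                 stringsAsFactors = FALSE))
  })
}

#' Generate random unigene sequences
#'
#' @param n number of sequences.
#' @param minLength,maxLength length range (bp).
#' @param seed integer seed.
#' @return a named `DNAStringSet` (names `UG00001`, ...).
#' @export
generateUnigeneSequences <- function(n, minLength = 250L, maxLength = 2500L,
                                     seed = 1L) {
  assertCount(n, "n")
  withSeed(seed, {
    lens <- as.integer(round(runif(n, minLength, maxLength)))
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    Biostrings::DNAStringSet(setNames(seqs, sprintf("UG%05d", seq_len(n))))
  })
}

#' Write a scenario's inputs as plain files
#'
#' Materialises every input the pipeline consumes: per-species hit tables
#' (BLAST outfmt-6 columns plus `qlen`) and edge tables (`from`, `to`,
#' `score`), and a JSON ground-truth sidecar (ortholog map + expected
#' edges).
#'
#' @param scenario output of [generateOrthologScenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in scenario$species) {
    fh <- file.path(dir, sprintf("hits_%s.tsv", sp$name))
    hitCols <- c(blast6Cols, "qlen")
    writeBlast <- sp$hits[, hitCols]
    write.table(writeBlast, fh, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    fe <- file.path(dir, sprintf("edges_%s.tsv", sp$name))
    writeTsv(sp$interactome, fe)
    files <- c(files, setNames(c(fh, fe),
                               paste0(c("hits_", "edges_"), sp$name)))
  }
  fg <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    ortholog_map = as.list(scenario$orthologMap),
    expected_edges = edgeTable(scenario$expectedEdges)
  ), fg, auto_unbox = TRUE, digits = NA)
  files <- c(files, ground_truth = fg)
  invisible(files)
}
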