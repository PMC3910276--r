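Package: interolog
Title: Homology-Transfer Protein Interaction Networks from De Novo
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a protein-protein interaction network for a non-model
    organism by homology transfer (interolog mapping): unigene selection and
    longest-ORF rules for de novo assembled transcripts, filtering of TBLASTN
    hit tables against reference interactomes by E-value, identity and query
    coverage, best-hit ortholog assignment, and transfer of reference
    interactome edges onto unigenes. Characterises the resulting network's
    topology (degree distribution with least-squares power-law fit,
    nearest-neighbour degree, clustering coefficients, average shortest path
    length, component census) and compares it with Erdos-Renyi,
    Watts-Strogatz and Barabasi-Albert random-graph null models matched in
    node and edge counts. Ships a synthetic-data generator that emulates
    every input with ground truth retained, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
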