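---
title: "Homology-transfer interaction networks: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-transfer interaction networks: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interolog)
```

## The problem

For a species with no sequenced genome, protein–protein interactions cannot
be looked up: they have to be *transferred*. Given a de novo assembled
transcriptome, the interolog-mapping approach searches the proteins of
reference species with curated interactomes (STRING-like edge tables)
against the unigenes, keeps only confident homologies, and then projects
every reference interaction (A, B) onto the pair of unigenes that A and B
map to. The resulting network is then characterised topologically — degree
distribution, degree correlation, clustering, path lengths — and compared
with random-graph null models matched in size.

This vignette explains each stage's model and assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the procedure was genuinely open.

## Transcript-facing rules

**Read cleaning.** Two rules are mandated and implemented exactly:

* a 3′ adapter contamination — an exact match of a prefix (≥ 8 nt) of an
  adapter such as the Illumina read-1 adapter `AGATCGGAAGAGCACACGTC` at the
  read's 3′ end — is trimmed off;
* reads whose fraction of unknown (N) bases is *strictly greater* than 5%
  (`maxUnknownFraction = 0.05`) are dropped, evaluated after trimming. The
  strict inequality means a 100 nt read with exactly 5 N bases is kept.

"Low-quality read" filtering is often part of such protocols but no
particular threshold is canonical; `cleanReads()` therefore exposes an
optional mean-Phred cutoff (`minMeanQuality`) that is **off by default**, so
the mandatory behaviour is exactly the two stated rules and nothing
invented.

**Unigene selection.** De novo assemblers emit several isoforms per gene
cluster. One representative (the *unigene*) is chosen per gene as the
transcript maximising `length × isoform_percent` — a compromise between
completeness and abundance support. Ties go to the longer transcript, then
the lexicographically smaller identifier, making the selection
deterministic.

**TPM.** Expression is reported as transcripts per million:
TPM_i = (c_i/l_i) / Σ_j (c_j/l_j) × 10⁶ with c the estimated count and l
the transcript length. An all-zero count table yields all-zero TPM rather
than an error.

**Longest ORF.** Without a protein database at hand, the coding sequence of
a unigene is approximated by its longest open reading frame over all six
frames: ATG to the first in-frame stop, stop codon included in the reported
1-based forward-strand coordinates. Ties prefer the forward strand, then the
smallest start. If a sequence contains no complete ORF, the longest open
ATG-to-frame-end stretch is reported and flagged (`has_stop = FALSE`).
Database-guided ORF correction is deliberately out of scope: it depends on
external database versions.

**Assembly statistics.** `assemblyStats()` reports N50 by the standard
cumulative-half definition (scanning lengths in descending order until half
the total assembled bases is reached) plus mean and total length. A brute
force prefix-scan oracle checks it over a thousand random length lists in
the test suite.

**Length pre-filter.** Unigenes must be strictly longer than 300 bp before
homology mapping (`filterUnigeneLength()`, configurable).

## Homology filtering and transfer

A TBLASTN-style hit (reference protein query vs unigene subject) survives
`filterHits()` only if **all three** hold, each a *strict* inequality:

* E-value < 1e−6,
* percent identity > 50,
* query coverage > 80% of the reference protein.

Coverage is taken from a `qcovs` column when the hit table has one,
otherwise computed per hit as 100 × (qend − qstart + 1)/qlen. Multiple hits
of one protein to different regions of a unigene are *not* merged before the
coverage test — filtering is per alignment record.

`assignOrthologs()` then keeps one unigene per reference protein: lowest
E-value, then highest bitscore, then smallest subject identifier. The map is
many-to-one on purpose — in a de novo assembly, paralogous reference
proteins frequently collapse onto one unigene, and nothing in the procedure
justifies forcing injectivity (a one-to-one reciprocal-best-hit scheme is a
different method and is out of scope). STRING-like confidence scores are
read but not filtered by default (`minScore = 0`), since no score cutoff is
part of the procedure.

`transferInteractions()` projects each species' reference edges through its
assignment, drops pairs that collapse onto a single unigene, and merges
duplicates within and across species into one simple undirected edge set —
the `InteractionGraph` class enforces simplicity as a validity invariant.

## Topology

For a graph with N nodes, adjacency a_ij and degrees k_i:

* **Degree distribution** P(k) = N(k)/N over observed degrees.
* **Power-law fit**: ordinary least squares of log₁₀ P(k) on log₁₀ k —
  unweighted, unbinned, over all degrees with P(k) > 0; the fit returns
  a = 10^intercept and γ = −slope. On exact power-law input the parameters
  are recovered to floating-point accuracy. *Caveat*: on heavy-tailed
  empirical distributions this raw-OLS protocol is biased shallow, because
  the tail contributes many degrees observed exactly once (a flat floor at
  P = 1/N). On preferential-attachment graphs with a theoretical exponent 3
  (N = 10⁴, E = 3 × 10⁴) the protocol lands at γ ≈ 2.00 ± 0.03 (12
  replicates). Log-binning, CCDF regression or maximum-likelihood would
  reduce the bias but are different estimators and are deliberately not
  substituted.
* **Degree correlation**: k_nn,i = (1/k_i) Σ_j a_ij k_j, and the per-degree
  curve k_nn(k) as the arithmetic mean over nodes of degree k. A decaying
  curve indicates disassortative mixing.
* **Clustering**: C_i = 2e_i/(k_i(k_i − 1)) with e_i the edges among i's
  neighbours. Nodes with k_i < 2 are assigned C_i = 0 and **included** in
  the network average by default. The choice matters: in sparse transferred
  networks most nodes have degree 1, so including them lowers C several
  fold. The convention is exposed (`includeLowDegree = FALSE` excludes
  them), and the per-degree curve C(k) only ever uses k ≥ 2 nodes. The
  C(k) ~ k^−1 hierarchy guideline is reported as the OLS slope of
  log₁₀ C(k) on log₁₀ k over positive C(k).
* **Path length**: L is the mean number of **edges** on shortest paths over
  all unordered pairs of a connected component. Describing path length by
  "intermediate nodes traversed" (i.e. edges − 1) appears in the
  literature, but adjacent nodes would then have distance 0 and typical
  L values near 5 for networks of this size are only consistent with the
  edge-count convention, which is what `averageShortestPath()` computes —
  by simultaneous breadth-first search from all sources via sparse-matrix
  frontier products. Memory is quadratic in component size; beyond ~5000
  nodes pass `pathLength = FALSE` to `topologySummary()`.

All metrics are validated against brute-force oracles (triple-loop triangle
counts, Floyd–Warshall distances, direct k_nn summation) with exact equality
on 200 random graphs, and cross-checked against igraph.

## Null models

`randomGraph()` produces Erdős–Rényi, Watts–Strogatz and Barabási–Albert
graphs with **exactly** the observed node and edge counts, because the
comparison requires nulls matched in both N and E:

* ER: e distinct edges sampled uniformly without replacement (G(n, e));
* WS: ring lattice with even neighbour count κ = 2⌊e/n⌋ (≥ 2), each lattice
  edge rewired with probability `pRewire` (default 0.1 — a standard
  small-world operating point; the value is configurable and echoed in
  outputs because no canonical value exists), then random edge
  top-up/removal to exactly e;
* BA: preferential attachment with m = max(1, round(e/n)) edges per new
  node over a complete seed of m + 1 nodes, then top-up/removal to e.

The top-up/removal step is the price of exact-E matching: WS and BA cannot
hit an arbitrary edge count natively. When e = nκ/2 and `pRewire = 0` the
WS graph is the exact ring lattice, whose clustering has the closed form
3(κ − 2)/(4(κ − 1)) — a test anchor. The ER ensemble's expected clustering
is p = 2E/(N(N − 1)), checked to Monte-Carlo accuracy at N = 1887,
E = 7634. `nullModelTable()` reports C and L per model, averaged over
replicates with their dispersion; disconnected replicates contribute the L
of their giant component.

## The synthetic-data generator

`generateOrthologScenario()` creates the complete study: per species a
reference interactome (BA by default, for the heavy-tailed degree
distributions of curated interactomes), a shared injective ortholog map
covering a configurable fraction of reference proteins, and a hit table
containing one threshold-clearing hit per true ortholog plus decoys. Decoys
are generated *per filter at its boundary value* — E-value exactly 1e−5,
identity exactly 50.0, coverage exactly 80.0 — each violating exactly one
rule, which pins the strict-inequality semantics: a correct implementation
produces identical networks with decoy rate 0 or 1. The ground-truth edge
set is the image of the reference edges under the map (self-pairs dropped,
duplicates merged), so exact recovery is a set-equality oracle, not an
approximation. FASTQ reads are generated with planted defects (> 5% N, or a
12–20 nt 3′ adapter prefix) and constant 'I' (Phred 40) qualities, with
provenance labels retained.

Deliberately **not** emulated: realistic sequence evolution, read error
profiles and quality-score distributions, the actual proteomes of any
reference species, and non-injective ortholog maps (many-to-one cases are
exercised directly at the transfer stage instead). Passing tests therefore
demonstrate the correctness of the rules and the determinism of the chain —
not that homology transfer gives biologically accurate networks on real
data, where assembly artefacts, annotation errors and STRING's own false
positives dominate.

## Determinism and problem sizes

Every stochastic component takes an explicit seed; generators restore the
caller's RNG state, and per-replicate seeds are derived from one master
seed, so scenario files, pipeline outputs and null-model tables are
byte-identical across runs. The shipped validation exercises: 200
oracle-checked random graphs (≤ 50 nodes), recovery scenarios with up to
~400 reference proteins × 3 species, ER ensembles at N = 1887 / E = 7634
(the scale of a typical transferred giant component), and a single
N = 10⁴ preferential-attachment graph for the fit-protocol calibration —
sizes chosen so the whole suite runs in well under a minute on one core
while still covering every rule at a realistic scale.

## Known limitations

* The raw-OLS power-law exponent is a descriptive statistic, not a
  consistent estimator of the true exponent (see above).
* Best-hit assignment ignores hit-region structure; chimeric unigenes can
  inherit interactions from two fused genes.
* L's dense all-pairs computation limits exact path lengths to components
  of a few thousand nodes.
* The network clustering coefficient depends on the degree-1 convention;
  both conventions are computable, and comparisons across studies should
  state which was used.
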