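test_that("reference interactome generation is sized, labelled and deterministic", {
  ref <- generateReferenceInteractome("ER", n = 4, e = 6, seed = 123)
  expect_identical(unname(nodeDegrees(ref$graph)), rep(3L, 4))  # K4 forced
  ba <- generateReferenceInteractome("BA", n = 1887, e = 7634, seed = 1)
  expect_identical(sum(nodeDegrees(ba$graph)), 15268L)
  expect_identical(length(ba$proteins), 1887L)
  r1 <- generateReferenceInteractome("ER", n = 100, e = 300, seed = 7)
  r2 <- generateReferenceInteractome("ER", n = 100, e = 300, seed = 7)
  expect_identical(r1$edges, r2$edges)
})

test_that("scenario configs validate their parameter space", {
  expect_error(scenarioConfig(orthologFraction = 1.2), "orthologFraction")
  expect_error(scenarioConfig(nReferenceProteins = 10, referenceEdges = 100),
               "feasible")
  expect_error(scenarioConfig(nReferenceProteins = 100, nUnigenes = 10,
                              orthologFraction = 1), "injective")
})

test_that("decoy-free scenarios are recovered exactly by the inference chain", {
  for (s in 1:3) {
    cfg <- scenarioConfig(nReferenceProteins = 60, nUnigenes = 90,
                          orthologFraction = 0.75, nSpecies = 2,
                          referenceModel = "BA", referenceEdges = 150,
                          decoyRate = 0, seed = s)
    sc <- generateOrthologScenario(cfg)
    expect_setequal_edges(inferScenarioNetwork(sc), sc$expectedEdges)
  }
})

test_that("every decoy violates exactly one threshold, at its boundary", {
  sc <- generateOrthologScenario(
    scenarioConfig(nReferenceProteins = 80, nUnigenes = 120,
                   orthologFraction = 0.9, nSpecies = 2,
                   referenceEdges = 200, decoyRate = 1, seed = 4))
  for (sp in sc$species) {
    d <- sp$hits[sp$hits$decoy_kind != "none", , drop = FALSE]
    expect_gt(nrow(d), 0)
    cov <- 100 * (d$qend - d$qstart + 1) / d$qlen
    failE <- !(d$evalue < 1e-6)
    failI <- !(d$pident > 50)
    failC <- !(cov > 80)
    expect_true(all(failE + failI + failC == 1L))
    expect_true(all(d$evalue[failE] == 1e-5))
    expect_true(all(d$pident[failI] == 50))
    expect_true(all(abs(cov[failC] - 80) < 1e-12))
    # true hits clear every threshold
    t <- sp$hits[sp$hits$decoy_kind == "none", , drop = FALSE]
    tcov <- 100 * (t$qend - t$qstart + 1) / t$qlen
    expect_true(all(t$evalue < 1e-6 & t$pident > 50 & tcov > 80))
  }
})

test_that("ortholog fraction bounds behave as stated", {
  sc0 <- generateOrthologScenario(
    scenarioConfig(nReferenceProteins = 30, nUnigenes = 40,
                   orthologFraction = 0, nSpecies = 1,
                   referenceEdges = 50, decoyRate = 0, seed = 1))
  expect_length(sc0$orthologMap, 0L)
  expect_identical(numEdges(sc0$expectedEdges), 0L)
  # full injective map relabels the reference graph edge-for-edge
  sc1 <- generateOrthologScenario(
    scenarioConfig(nReferenceProteins = 30, nUnigenes = 40,
                   orthologFraction = 1, nSpecies = 1,
                   referenceEdges = 50, decoyRate = 0, seed = 2))
  expect_identical(numEdges(sc1$expectedEdges), 50L)
  # every unigene in the expected edges is in the map's image
  expect_true(all(nodeIds(sc1$expectedEdges) %in% sc1$orthologMap))
})

test_that("scenario outputs are byte-identical for a fixed seed", {
  cfg <- scenarioConfig(nReferenceProteins = 40, nUnigenes = 60,
                        orthologFraction = 0.6, nSpecies = 2,
                        referenceEdges = 80, decoyRate = 0.5, seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- writeScenario(generateOrthologScenario(cfg), d1)
  f2 <- writeScenario(generateOrthologScenario(cfg), d2)
  expect_identical(names(f1), names(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("isoform tables have per-gene percentages summing to 100", {
  tab <- generateIsoformTable(25, maxIsoforms = 5, seed = 8)
  sums <- tapply(tab$isoform_percent, tab$gene_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_true(all(tab$length >= 1 & tab$length == trunc(tab$length)))
  one <- generateIsoformTable(1, maxIsoforms = 1, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_equal(one$isoform_percent, 100)
  expect_identical(generateIsoformTable(10, 4, seed = 2),
                   generateIsoformTable(10, 4, seed = 2))
})

test_that("generated FASTQ honours rates, adapters and determinism", {
  clean <- generateFastqReads(30, readLen = 100, nRate = 0,
                              adapterRate = 0, seed = 5)
  expect_false(any(clean$provenance$fails_n_rule))
  out <- cleanReads(clean$reads)
  expect_identical(out$report$kept, 30L)

  sim <- generateFastqReads(50, readLen = 100, nRate = 0.3,
                            adapterRate = 0.2, seed = 6)
  nCounts <- as.numeric(Biostrings::letterFrequency(sim$reads, "N"))
  expect_true(all(nCounts[sim$provenance$fails_n_rule] / 100 > 0.05))
  ads <- sim$provenance$has_adapter
  expect_true(all(vapply(seq_len(sum(ads)), function(i) {
    o <- sim$provenance$adapter_overlap[ads][i]
    substr(as.character(sim$reads[ads][i]), 101 - o, 100) ==
      substr("AGATCGGAAGAGCACACGTC", 1, o)
  }, logical(1))))

  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeQualityScaledXStringSet(
    generateFastqReads(20, seed = 9)$reads, f1)
  Biostrings::writeQualityScaledXStringSet(
    generateFastqReads(20, seed = 9)$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
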