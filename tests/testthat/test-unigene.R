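test_that("read cleaning applies the strict 5% unknown-base rule", {
  mkReads <- function(seqs) {
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, paste0("r", seq_along(seqs)))),
      Biostrings::PhredQuality(vapply(seqs, function(s)
        strrep("I", nchar(s)), character(1), USE.NAMES = FALSE)))
  }
  base <- strrep("ACGT", 25)  # 100 nt
  with5N <- paste0(strrep("N", 5), substr(base, 6, 100))
  with6N <- paste0(strrep("N", 6), substr(base, 7, 100))
  out <- cleanReads(mkReads(c(base, with5N, with6N)))
  expect_identical(out$report$kept, 2L)       # 5/100 is not > 5%
  expect_identical(out$report$dropped_n, 1L)  # 6/100 is
  expect_identical(names(out$kept), c("r1", "r2"))

  # 12 nt of the read-1 adapter at the 3' end is trimmed before the N test
  adapter12 <- substr("AGATCGGAAGAGCACACGTC", 1, 12)
  contaminated <- paste0(substr(base, 1, 88), adapter12)
  out2 <- cleanReads(mkReads(contaminated))
  expect_identical(out2$report$trimmed, 1L)
  expect_identical(Biostrings::width(out2$kept), 88L)
  expect_identical(as.character(out2$kept[[1]]), substr(base, 1, 88))
  # shorter than the minimum 8 nt overlap: untouched
  contaminated7 <- paste0(substr(base, 1, 93),
                          substr("AGATCGGAAGAGCACACGTC", 1, 7))
  expect_identical(cleanReads(mkReads(contaminated7))$report$trimmed, 0L)
})

test_that("malformed FASTQ input is rejected with the record index", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGT", "BROKEN", "IIII"), f)
  expect_error(cleanReads(f), "record at index 2")
  f2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), f2)  # quality length mismatch
  expect_error(cleanReads(f2), "record at index 1")
})

test_that("cleaning a file of generated reads matches the planted provenance", {
  sim <- generateFastqReads(120, readLen = 100, nRate = 0.25,
                            adapterRate = 0.25, seed = 42)
  f <- tempfile(fileext = ".fastq")
  Biostrings::writeQualityScaledXStringSet(sim$reads, f)
  out <- cleanReads(f)
  expect_identical(out$report$dropped_n, sum(sim$provenance$fails_n_rule))
  expect_identical(out$report$trimmed, sum(sim$provenance$has_adapter))
  expect_identical(sort(names(out$kept)),
                   sort(sim$provenance$read_id[!sim$provenance$fails_n_rule]))
})

test_that("unigene selection maximises length x isoform percent with tie-breaks", {
  tab <- data.frame(
    transcript_id = c("t1", "t2", "s1", "a", "b"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    length = c(1000, 500, 700, 800, 400),
    isoform_percent = c(30, 70, 100, 50, 100))
  sel <- selectUnigenes(tab)
  expect_identical(sel, c(g1 = "t2",  # 35000 > 30000
                          g2 = "s1",  # single isoform
                          g3 = "a"))  # both score 40000; longer wins
  # score and length both tied: lexicographically smaller transcript id
  tab2 <- data.frame(transcript_id = c("z", "y"), gene_id = "g",
                     length = c(400, 400), isoform_percent = c(50, 50))
  expect_identical(unname(selectUnigenes(tab2)), "y")
  expect_length(selectUnigenes(tab), length(unique(tab$gene_id)))
})

test_that("TPM follows the length-normalised formula and sums to one million", {
  tab <- data.frame(transcript_id = c("a", "b"), length = c(500, 500),
                    expected_count = c(7, 7))
  expect_equal(unname(computeTpm(tab)), c(5e5, 5e5))
  tab2 <- data.frame(transcript_id = c("a", "b"), length = c(100, 900),
                     expected_count = c(10, 0))
  expect_equal(unname(computeTpm(tab2)), c(1e6, 0))
  # hand evaluation: rates 1/100, 1/100, 2/200 are all equal
  tab3 <- data.frame(transcript_id = c("a", "b", "c"),
                     length = c(100, 100, 200), expected_count = c(1, 1, 2))
  expect_equal(unname(computeTpm(tab3)), rep(1e6 / 3, 3))
  # all-zero counts: all-zero TPM, no division error
  tab4 <- data.frame(transcript_id = "a", length = 100, expected_count = 0)
  expect_identical(unname(computeTpm(tab4)), 0)
  for (s in 1:10) {
    iso <- generateIsoformTable(20, maxIsoforms = 5, seed = s)
    expect_equal(sum(computeTpm(iso)), 1e6, tolerance = 1e-9)
  }
})

test_that("assembly statistics match the cumulative-half definition", {
  st <- assemblyStats(c(2, 3, 4, 5, 6))
  expect_identical(st$n50, 5)   # 6 + 5 = 11 >= 10
  expect_identical(st$mean_length, 4)
  expect_identical(st$total_nt, 20)
  expect_identical(assemblyStats(10)$n50, 10)
  expect_identical(assemblyStats(rep(77, 9))$n50, 77)
  expect_error(assemblyStats(numeric(0)), "non-empty")
  expect_error(assemblyStats(c(5, 0)), "positive")
  # brute-force oracle: scan all prefixes of the descending lengths
  bruteN50 <- function(lens) {
    s <- sort(lens, decreasing = TRUE)
    tot <- sum(s)
    for (i in seq_along(s)) if (sum(s[1:i]) >= tot / 2) return(s[i])
  }
  set.seed(99)
  for (r in 1:1000) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_identical(assemblyStats(lens)$n50, bruteN50(lens))
  }
})

test_that("unigene length filter is strict at the 300 bp boundary", {
  lens <- setNames(c(299, 300, 301, 1200), paste0("u", 1:4))
  expect_identical(names(filterUnigeneLength(lens)), c("u3", "u4"))
  seqs <- generateUnigeneSequences(5, minLength = 100, maxLength = 400,
                                   seed = 3)
  kept <- filterUnigeneLength(seqs, 300)
  expect_true(all(Biostrings::width(kept) > 300))
})
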