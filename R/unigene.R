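# Transcript-facing rules: read cleaning, unigene selection, TPM, assembly
# statistics.

# locate the first structurally malformed 4-line FASTQ record, if any
validateFastqFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  nRec <- ceiling(length(lines) / 4)
  for (r in seq_len(nRec)) {
    block <- lines[(4 * (r - 1) + 1):min(4 * r, length(lines))]
    ok <- length(block) == 4L && startsWith(block[1L], "@") &&
      startsWith(block[3L], "+") && nchar(block[2L]) == nchar(block[4L]) &&
      nchar(block[2L]) > 0L
    if (!ok)
      stop(sprintf("malformed FASTQ record at index %d in '%s'", r, path),
           call. = FALSE)
  }
  invisible(TRUE)
}

# longest adapter prefix (>= minOverlap) matching the read's 3' end;
# returns trimmed-length per read (0 = untouched)
adapterTrimLengths <- function(seqs, adapter, minOverlap = 8L) {
  w <- Biostrings::width(seqs)
  trim <- integer(length(seqs))
  maxO <- min(nchar(adapter), max(w))
  chars <- as.character(seqs)
  for (o in seq(from = maxO, to = minOverlap)) {
    prefix <- substr(adapter, 1L, o)
    idx <- which(trim == 0L & w >= o)
    if (!length(idx)) next
    hit <- substr(chars[idx], w[idx] - o + 1L, w[idx]) == prefix
    trim[idx[hit]] <- o
  }
  trim
}

#' Clean short reads: trim 3' adapters, drop N-rich reads
#'
#' Applies the two mandated read-cleaning rules: (1) a 3' adapter
#' contamination — an exact match of an adapter *prefix* of at least
#' `minOverlap` nt at the read's 3' end — is trimmed off; (2) reads whose
#' fraction of unknown (N) bases, evaluated *after* trimming, is strictly
#' greater than `maxUnknownFraction` are dropped. Reads trimmed to nothing
#' are also dropped. An optional mean-quality threshold is available but off
#' by default (`minMeanQuality = NULL`), as no particular quality rule is
#' mandated.
#'
#' @param reads a `QualityScaledDNAStringSet`, or the path of a FASTQ file.
#' @param adapters character vector of adapter sequences to trim (default:
#'   the Illumina paired-end read-1 and read-2 adapters).
#' @param maxUnknownFraction maximum tolerated N fraction (default 0.05;
#'   strictly greater is dropped, so exactly 5% N is kept).
#' @param minOverlap minimum adapter-prefix overlap in nt (default 8).
#' @param minMeanQuality optional minimum mean Phred quality; `NULL`
#'   (default) disables the check.
#' @return list with `kept` (a `QualityScaledDNAStringSet`) and `report`
#'   (counts: input, kept, dropped_n, dropped_empty, dropped_quality,
#'   trimmed).
#' @examples
#' reads <- generateFastqReads(20, readLen = 50, nRate = 0.2,
#'                             adapterRate = 0.3, seed = 1)
#' cleanReads(reads$reads)$report
#' @export
cleanReads <- function(reads,
                       adapters = c("AGATCGGAAGAGCACACGTC",
                                    "AGATCGGAAGAGCGTCGTGT"),
                       maxUnknownFraction = 0.05, minOverlap = 8L,
                       minMeanQuality = NULL) {
  assertProportion(maxUnknownFraction, "maxUnknownFraction")
  if (is.character(reads) && length(reads) == 1L) {
    validateFastqFile(reads)
    reads <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(reads),
      warning = function(w) {
        # Biostrings warns that FASTQ metadata columns are dropped; the
        # qualities themselves are kept, so this is noise here
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  n0 <- length(reads)
  trim <- integer(n0)
  for (ad in adapters) {
    t2 <- adapterTrimLengths(reads, ad, minOverlap)
    trim <- pmax(trim, t2)
  }
  w <- Biostrings::width(reads)
  newEnd <- w - trim
  nonEmpty <- newEnd > 0L
  trimmed <- Biostrings::subseq(reads[nonEmpty], start = 1L,
                                end = newEnd[nonEmpty])
  nFrac <- as.numeric(
    Biostrings::letterFrequency(trimmed, "N")) / Biostrings::width(trimmed)
  passN <- nFrac <= maxUnknownFraction
  droppedQ <- 0L
  keep <- passN
  if (!is.null(minMeanQuality)) {
    q <- Biostrings::quality(trimmed)
    mq <- vapply(as(q, "IntegerList"), mean, numeric(1))
    passQ <- mq >= minMeanQuality
    droppedQ <- sum(passN & !passQ)
    keep <- passN & passQ
  }
  kept <- trimmed[keep]
  list(kept = kept,
       report = list(input = n0,
                     kept = length(kept),
                     dropped_n = sum(!passN),
                     dropped_empty = sum(!nonEmpty),
                     dropped_quality = droppedQ,
                     trimmed = sum(trim > 0L & nonEmpty)))
}

#' Select one representative transcript (unigene) per gene
#'
#' Scores every isoform by `length * isoform_percent` and returns, per gene,
#' the top-scoring transcript. Ties are broken by greater length, then by
#' lexicographically smallest transcript identifier.
#'
#' @param records data.frame with columns `transcript_id`, `gene_id`,
#'   `length` and `isoform_percent` (an RSEM-style `IsoPct` column is
#'   accepted under either name).
#' @return named character vector: gene_id -> chosen transcript_id.
#' @examples
#' tab <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
#'                   length = c(1000, 500), isoform_percent = c(30, 70))
#' selectUnigenes(tab)   # t2: 500 * 70 > 1000 * 30
#' @export
selectUnigenes <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!"isoform_percent" %in% names(records) && "IsoPct" %in% names(records))
    records$isoform_percent <- records$IsoPct
  stopifnot(all(c("transcript_id", "gene_id", "length",
                  "isoform_percent") %in% names(records)))
  stopifnot(all(records$isoform_percent >= 0),
            all(records$isoform_percent <= 100),
            all(records$length >= 1))
  score <- records$length * records$isoform_percent
  o <- order(records$gene_id, -score, -records$length,
             records$transcript_id, method = "radix")
  best <- records[o, , drop = FALSE]
  best <- best[!duplicated(best$gene_id), , drop = FALSE]
  setNames(as.character(best$transcript_id), as.character(best$gene_id))
}

#' Transcripts-per-million from counts and lengths
#'
#' TPM_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6. The values sum to one
#' million whenever any count is positive; an all-zero table yields all-zero
#' TPM rather than a division error.
#'
#' @param records data.frame with columns `transcript_id`, `length` and
#'   `expected_count`.
#' @return named numeric vector of TPM values, one per transcript.
#' @examples
#' tab <- data.frame(transcript_id = c("a", "b", "c"),
#'                   length = c(100, 100, 200),
#'                   expected_count = c(1, 1, 2))
#' computeTpm(tab)   # 250000, 250000, 500000
#' @export
computeTpm <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("transcript_id", "length", "expected_count") %in%
                  names(records)))
  stopifnot(all(records$length > 0), all(records$expected_count >= 0))
  rate <- records$expected_count / records$length
  tot <- sum(rate)
  tpm <- if (tot > 0) rate / tot * 1e6 else rep(0, length(rate))
  setNames(tpm, as.character(records$transcript_id))
}

#' Assembly summary statistics (N50, mean length, totals)
#'
#' N50 is the length of the sequence at which, scanning the lengths in
#' descending order, the cumulative sum first reaches at least half of the
#' total assembled bases.
#'
#' @param lengths vector of positive sequence lengths (bp).
#' @return list with `n_sequences`, `mean_length`, `n50`, `total_nt`.
#' @examples
#' assemblyStats(c(2, 3, 4, 5, 6))   # N50 = 5, mean = 4
#' @export
assemblyStats <- function(lengths) {
  if (!length(lengths) || !is.numeric(lengths) || any(lengths <= 0) ||
      any(!is.finite(lengths)))
    stop("'lengths' must be a non-empty vector of positive lengths",
         call. = FALSE)
  total <- sum(lengths)
  srt <- sort(lengths, decreasing = TRUE)
  n50 <- srt[which(cumsum(srt) >= total / 2)[1L]]
  list(n_sequences = length(lengths),
       mean_length = total / length(lengths),
       n50 = n50,
       total_nt = total)
}

#' Length pre-filter for unigenes ahead of homology mapping
#'
#' Keeps sequences strictly longer than `minLength` (default 300 bp, so a
#' 300 bp unigene is excluded).
#'
#' @param seqs a `DNAStringSet` or named numeric vector of lengths.
#' @param minLength exclusive lower length bound (default 300).
#' @return the retained subset, same type as the input.
#' @export
filterUnigeneLength <- function(seqs, minLength = 300) {
  w <- if (is(seqs, "XStringSet")) Biostrings::width(seqs) else seqs
  seqs[w > minLength]
}
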