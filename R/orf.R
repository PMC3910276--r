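# Six-frame longest-ORF scan for coding-sequence selection.

stopCodons <- c("TAA", "TAG", "TGA")

# all ATG..stop ORFs in one strand's sequence; returns start/end (1-based on
# that strand, stop codon included) and a flag for open (stop-less) ORFs
orfsOneStrand <- function(s) {
  L <- nchar(s)
  out <- list()
  if (L < 3L) return(out)
  for (frame in 0:2) {
    starts <- seq(frame + 1L, L - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2L)
    isStart <- codons == "ATG"
    isStop <- codons %in% stopCodons
    open <- NA_integer_  # position index of the pending ATG
    for (ci in seq_along(codons)) {
      if (is.na(open) && isStart[ci]) open <- ci
      if (!is.na(open) && isStop[ci]) {
        out[[length(out) + 1L]] <- list(start = starts[open],
                                        end = starts[ci] + 2L,
                                        frame = frame, stopped = TRUE)
        open <- NA_integer_
      }
    }
    if (!is.na(open)) {
      out[[length(out) + 1L]] <- list(start = starts[open],
                                      end = starts[length(starts)] + 2L,
                                      frame = frame, stopped = FALSE)
    }
  }
  out
}

emptyOrfCall <- function(id) {
  list(unigene_id = id, found = FALSE, strand = NA_character_,
       frame = NA_integer_, start = NA_integer_, end = NA_integer_,
       protein = "", has_stop = NA)
}

#' Find the longest open reading frame in a nucleotide sequence
#'
#' Scans all six frames (both strands). An ORF runs from an ATG to the first
#' in-frame stop codon, stop included in the reported coordinates. The
#' longest ORF wins; ties are broken in favour of the forward strand, then
#' the smallest forward-strand start position. When no ATG-to-stop ORF
#' exists anywhere, the longest *open* stretch from an ATG to the end of its
#' frame is returned instead (`has_stop = FALSE`); if there is no ATG at
#' all, the call is flagged not found.
#'
#' Coordinates are 1-based inclusive on the *forward* strand, also for minus
#' strand calls. The reported protein excludes the stop.
#'
#' @param sequence a single nucleotide string (or `DNAString`) over
#'   A, C, G, T, N.
#' @param id identifier to carry in the call (default `""`).
#' @return a list (one ORF call): `unigene_id`, `found`, `strand` (`"+"` or
#'   `"-"`), `frame` (0/1/2 on the calling strand), `start`, `end`,
#'   `protein`, `has_stop`.
#' @examples
#' findLongestOrf("ATGAAATAG")   # start 1, end 9, protein "MK"
#' @export
findLongestOrf <- function(sequence, id = "") {
  s <- toupper(as.character(sequence))
  if (!nzchar(s)) return(emptyOrfCall(id))
  if (grepl("[^ACGTN]", s))
    stop("sequence must be over the alphabet {A, C, G, T, N}",
         call. = FALSE)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cands <- list()
  addCands <- function(orfs, strand) {
    for (o in orfs) {
      # map minus-strand coordinates back to the forward strand
      if (strand == "+") {
        fs <- o$start; fe <- o$end
      } else {
        fs <- L - o$end + 1L; fe <- L - o$start + 1L
      }
      cands[[length(cands) + 1L]] <<- list(
        strand = strand, frame = o$frame, fwdStart = fs, fwdEnd = fe,
        srcStart = o$start, srcEnd = o$end, len = o$end - o$start + 1L,
        stopped = o$stopped)
    }
  }
  addCands(orfsOneStrand(s), "+")
  addCands(orfsOneStrand(rc), "-")
  if (!length(cands)) return(emptyOrfCall(id))
  stopped <- vapply(cands, `[[`, logical(1), "stopped")
  pool <- if (any(stopped)) cands[stopped] else cands
  len <- vapply(pool, `[[`, integer(1), "len")
  plus <- vapply(pool, `[[`, character(1), "strand") == "+"
  fs <- vapply(pool, `[[`, integer(1), "fwdStart")
  best <- pool[[order(-len, !plus, fs)[1L]]]
  src <- if (best$strand == "+") s else rc
  orfNt <- substr(src, best$srcStart, best$srcEnd)
  if (best$stopped) orfNt <- substr(orfNt, 1L, nchar(orfNt) - 3L)
  protein <- if (nzchar(orfNt)) {
    as.character(Biostrings::translate(Biostrings::DNAString(orfNt),
                                       if.fuzzy.codon = "solve"))
  } else ""
  list(unigene_id = id, found = TRUE, strand = best$strand,
       frame = best$frame, start = best$fwdStart, end = best$fwdEnd,
       protein = protein, has_stop = best$stopped)
}

#' Longest ORF for every sequence in a set
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @return data.frame with one row per sequence: `unigene_id`, `found`,
#'   `strand`, `frame`, `start`, `end`, `orf_length`, `protein`, `has_stop`.
#' @export
findLongestOrfs <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  chars <- as.character(seqs)
  calls <- lapply(seq_along(chars), function(i)
    findLongestOrf(chars[i], id = ids[i]))
  data.frame(
    unigene_id = vapply(calls, `[[`, character(1), "unigene_id"),
    found = vapply(calls, `[[`, logical(1), "found"),
    strand = vapply(calls, `[[`, character(1), "strand"),
    frame = vapply(calls, `[[`, integer(1), "frame"),
    start = vapply(calls, `[[`, integer(1), "start"),
    end = vapply(calls, `[[`, integer(1), "end"),
    orf_length = vapply(calls, function(x)
      if (x$found) x$end - x$start + 1L else NA_integer_, integer(1)),
    protein = vapply(calls, `[[`, character(1), "protein"),
    has_stop = vapply(calls, `[[`, logical(1), "has_stop"),
    stringsAsFactors = FALSE)
}
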