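#' Read a transcriptome assembly from FASTA
#'
#' Sequences are uppercased on ingest. Record ids are taken as the first
#' whitespace-delimited token of each header line.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return A named character vector of nucleotide sequences over
#'   `{A,C,G,T,N}` (other IUPAC codes are preserved but never occur inside a
#'   reported ORF's start/stop codon).
#' @export
read_transcripts <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript ids in ", path)
  if (any(nchar(seqs) < 1L)) stop("empty sequence in ", path)
  seqs
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(s) {
  chartr(
    "ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB",
    vapply(s, function(x)
      paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""),
      character(1L), USE.NAMES = FALSE)
  )
}

#' Locate the longest complete open reading frame in a transcript
#'
#' Scans all three frames on both strands for ATG-initiated,
#' stop-terminated reading frames with no internal in-frame stop, and
#' returns the longest. Only complete ORFs (start and stop both present)
#' are considered; partial ORFs truncated at contig ends are ignored,
#' since an unambiguous frame is required for codon-position G+C.
#'
#' @param seq A single nucleotide string (uppercase; `N` is allowed outside
#'   start/stop codons).
#' @return A list with elements `start` (0-based inclusive), `end` (0-based
#'   exclusive), `strand` (`"+"` or `"-"`), `length_nt` (multiple of 3,
#'   including the stop codon) and `codon_count`; coordinates are on the
#'   reported strand (i.e. on the reverse complement for `strand == "-"`).
#'   `NULL` if no complete ORF of at least 6 nt exists. Ties are broken by
#'   strand (`+` before `-`), then by smaller start.
#' @examples
#' find_longest_orf("ATGAAATAG")
#' @export
find_longest_orf <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty nucleotide string")
  seq <- toupper(seq)
  cand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 2L) next
      at <- seq.int(frame + 1L, by = 3L, length.out = ncod)
      codons <- substring(s, at, at + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% .STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      # index of first in-frame stop strictly after each ATG
      j <- findInterval(atg, stp) + 1L
      keep <- j <= length(stp)
      if (!any(keep)) next
      atg <- atg[keep]
      span <- stp[j[keep]] - atg + 1L
      best <- which.max(span) # earliest ATG wins ties within a frame
      cand[[length(cand) + 1L]] <- list(
        start = at[atg[best]] - 1L,
        length_nt = 3L * span[best],
        strand = strand
      )
    }
  }
  if (!length(cand)) return(NULL)
  len <- vapply(cand, `[[`, integer(1L), "length_nt")
  minus <- vapply(cand, `[[`, character(1L), "strand") == "-"
  st <- vapply(cand, `[[`, integer(1L), "start")
  pick <- order(-len, minus, st)[1L]
  b <- cand[[pick]]
  list(start = b$start, end = b$start + b$length_nt, strand = b$strand,
       length_nt = b$length_nt, codon_count = b$length_nt %/% 3L)
}

#' Extract an ORF's nucleotide sequence on its reported strand
#'
#' @param seq Transcript sequence.
#' @param orf An ORF record from [find_longest_orf()].
#' @keywords internal
orf_sequence <- function(seq, orf) {
  s <- if (orf$strand == "+") toupper(seq) else revcomp(toupper(seq))
  substr(s, orf$start + 1L, orf$end)
}

#' G+C fraction at each codon position
#'
#' Counts every codon of the string it is given. Codons with an ambiguous
#' base (anything outside `A,C,G,T`) at position *k* are excluded from
#' position *k*'s denominator.
#'
#' @param orf_seq An in-frame nucleotide string whose length is a multiple
#'   of 3.
#' @return A list with `gc1`, `gc2`, `gc3`, `gc_overall` (fractions in
#'   \[0,1\]) and `n_codons_counted`.
#' @examples
#' gc_by_codon_position("ATGGGCTAA") # gc1 = 1/3, gc2 = 1/3, gc3 = 2/3
#' @export
gc_by_codon_position <- function(orf_seq) {
  if (!is.character(orf_seq) || length(orf_seq) != 1L || is.na(orf_seq))
    stop("'orf_seq' must be a single string")
  n <- nchar(orf_seq)
  if (n < 3L || n %% 3L != 0L)
    stop("ORF length must be a positive multiple of 3, got ", n)
  b <- matrix(strsplit(toupper(orf_seq), "", fixed = TRUE)[[1L]], nrow = 3L)
  frac <- function(x) {
    valid <- x %in% c("A", "C", "G", "T")
    sum(x %in% c("G", "C")) / sum(valid)
  }
  list(gc1 = frac(b[1L, ]), gc2 = frac(b[2L, ]), gc3 = frac(b[3L, ]),
       gc_overall = frac(as.vector(b)), n_codons_counted = ncol(b))
}

#' Pooled G+C percentage of a set of transcripts
#'
#' A single pooled percentage over all bases of all sequences (not a mean of
#' per-transcript percentages); ambiguous bases are excluded from numerator
#' and denominator.
#'
#' @param seqs Nonempty character vector of nucleotide sequences.
#' @return Percentage in \[0, 100\].
#' @examples
#' gc_percent_of_set(c("AATT", "GGCC")) # 50
#' @export
gc_percent_of_set <- function(seqs) {
  if (length(seqs) == 0L) stop("'seqs' must be a nonempty set of sequences")
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(seqs)), letters = c("A", "C", "G", "T")))
  100 * sum(counts[c("G", "C")]) / sum(counts)
}

#' Longest-ORF feature table for a transcript set
#'
#' Runs [find_longest_orf()] on every transcript and attaches codon-position
#' G+C fractions of the ORF. By default the (compositionally constrained)
#' stop codon is excluded from the G+C counts, while `length_nt` always
#' includes it.
#'
#' @param transcripts Named character vector of sequences (names are ids).
#' @param count_stop_codon Include the terminal stop codon in the G+C
#'   counts? Default `FALSE`.
#' @return A data.frame with one row per transcript that has a complete ORF:
#'   `transcript_id, start, end, strand, length_nt, codon_count, gc1, gc2,
#'   gc3, gc_overall`.
#' @export
orf_feature_table <- function(transcripts, count_stop_codon = FALSE) {
  stopifnot(is.character(transcripts), !is.null(names(transcripts)))
  rows <- lapply(names(transcripts), function(id) {
    orf <- find_longest_orf(transcripts[[id]])
    if (is.null(orf)) return(NULL)
    os <- orf_sequence(transcripts[[id]], orf)
    if (!count_stop_codon) os <- substr(os, 1L, nchar(os) - 3L)
    gc <- gc_by_codon_position(os)
    data.frame(transcript_id = id, start = orf$start, end = orf$end,
               strand = orf$strand, length_nt = orf$length_nt,
               codon_count = orf$codon_count,
               gc1 = gc$gc1, gc2 = gc$gc2, gc3 = gc$gc3,
               gc_overall = gc$gc_overall, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      length_nt = integer(), codon_count = integer(),
                      gc1 = numeric(), gc2 = numeric(), gc3 = numeric(),
                      gc_overall = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
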