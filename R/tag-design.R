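#' k-mer counts over a sequence collection
#'
#' Overlapping k-mer counts across all records, after uppercasing; windows
#' containing a non-ACGT character (N and friends) are skipped.
#'
#' @param sequences a `DNAStringSet`, character vector, or FASTA path
#' @param k word length (1..12)
#' @param includeZeros also return the k-mers absent from the input
#' @return named integer vector of counts
#' @examples
#' kmerCounts("ACGACG", 3)   # ACG 2, CGA 1, GAC 1
#' @export
kmerCounts <- function(sequences, k, includeZeros = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (k > 12L) stop("k larger than 12 is not supported")
  x <- .asDNAStringSet(sequences)
  if (!length(x) || all(width(x) < k))
    return(setNames(integer(0), character(0)))
  counts <- oligonucleotideFrequency(x, width = k, simplify.as = "collapsed")
  mode(counts) <- "integer"
  if (includeZeros) counts else counts[counts > 0L]
}

.asDNAStringSet <- function(sequences) {
  if (is(sequences, "DNAStringSet")) sequences
  else if (is.character(sequences) && length(sequences) == 1L &&
           file.exists(sequences)) readDNAStringSet(sequences)
  else DNAStringSet(.normSeq(sequences))
}

#' Count occurrences of a motif in a sequence collection
#'
#' All exact occurrences, overlapping ones included, summed over records.
#'
#' @param sequences a `DNAStringSet`, character vector, or FASTA path
#' @param motif nucleotide string
#' @return total occurrence count
#' @examples
#' motifOccurrence("CGATCGATCG", "CGATCG")  # 2 (overlap allowed)
#' @export
motifOccurrence <- function(sequences, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  x <- .asDNAStringSet(sequences)
  motif <- DNAString(.normSeq(motif))
  sum(vapply(seq_along(x), function(i)
    length(matchPattern(motif, x[[i]])), integer(1)))
}

#' Rank candidate flanking trinucleotides by assembled-tag rarity
#'
#' For each of the 64 trinucleotides t the candidate tag t + coreSite + t is
#' assembled and its occurrences in the supplied transcriptome counted
#' (overlaps allowed); candidates are returned rarest first, ties broken
#' lexicographically. Counting is single-strand by default (a transcriptome
#' is already stranded); `bothStrands` adds reverse-complement occurrences
#' for genome input. The flank's own occurrence count is reported alongside.
#'
#' @param sequences transcriptome as `DNAStringSet`, character vector or
#'   FASTA path
#' @param coreSite 6-nt core recognition site (default the PvuI site)
#' @param bothStrands also count occurrences on the reverse complement
#' @return data.frame: `flank`, `tag` (the assembled 12-mer), `count`,
#'   `flank_count`, ascending by `count`
#' @export
rankFlankCandidates <- function(sequences, coreSite = "CGATCG",
                                bothStrands = FALSE) {
  coreSite <- .normSeq(coreSite)
  if (nchar(coreSite) != 6L) stop("coreSite must be 6 nt long")
  x <- .asDNAStringSet(sequences)
  if (bothStrands) x <- c(x, reverseComplement(x))
  bases <- c("A", "C", "G", "T")
  flanks <- sort(apply(expand.grid(bases, bases, bases), 1, paste,
                       collapse = ""))
  tags <- paste0(flanks, coreSite, flanks)
  counts <- vapply(tags, function(t) motifOccurrence(x, t), integer(1))
  k3 <- kmerCounts(x, 3L, includeZeros = TRUE)
  out <- data.frame(flank = flanks, tag = tags, count = unname(counts),
                    flank_count = unname(as.integer(k3[flanks])))
  out[order(out$count, out$flank), , drop = FALSE]
}
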