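# Independent oracles and small fixture builders used across the suite.

# Full dynamic-programming Levenshtein distance (base R), independent of the
# package's banded implementation.
levOracle <- function(a, b) {
  as.integer(utils::adist(a, b))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force overlapping motif count by position-by-position comparison.
motifCountOracle <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(seq, i, i + m - 1L) == motif, logical(1)))
}

# All strings one edit away from `s` over the DNA alphabet.
singleEditNeighbours <- function(s) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  subs <- unlist(lapply(seq_len(n), function(i)
    vapply(setdiff(bases, ch[i]), function(b) {
      x <- ch; x[i] <- b; paste(x, collapse = "")
    }, "")))
  ins <- unlist(lapply(0:n, function(i)
    vapply(bases, function(b)
      paste0(substr(s, 1, i), b, substr(s, i + 1, n)), "")))
  dels <- vapply(seq_len(n), function(i)
    paste0(substr(s, 1, i - 1), substr(s, i + 1, n)), "")
  list(substitutions = subs, insertions = ins, deletions = dels)
}

writeFastq <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

writeSam <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(lines, path)
  path
}

samLine <- function(qname, flag, rname, pos1, cigar, nm = NULL) {
  paste(c(qname, flag, rname, pos1, 60, cigar, "*", 0, 0, "*", "*",
          if (!is.null(nm)) paste0("NM:i:", nm)), collapse = "\t")
}

# Minimal gene-model object matching readGeneModels() output: single-exon
# genes unless exon ranges are given explicitly.
makeGenes <- function(chr, start0, end0, strand, ids, exons = NULL) {
  g <- GenomicRanges::GRanges(chr, IRanges::IRanges(start0 + 1L, end0),
                              strand = strand)
  S4Vectors::mcols(g)$gene_id <- ids
  S4Vectors::mcols(g)$exons <- if (is.null(exons))
    GenomicRanges::GRangesList(lapply(seq_along(g), function(i)
      GenomicRanges::granges(g[i])))
  else exons
  names(g) <- ids
  g
}
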