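#' Read gene models from BED or GFF3
#'
#' BED input (BED6 or BED12) uses the `name` column as the gene id and block
#' structure, when present, as exons; a BED6 gene is treated as single-exon.
#' GFF3 input takes `type == "gene"` features as genic intervals and groups
#' `type == "exon"` features to genes via their `Parent` (or `gene_id`)
#' attribute.
#'
#' @param path annotation file (`.bed`, `.gff`/`.gff3`)
#' @param format override the extension-based format guess ("bed" or "gff3")
#' @return `GRanges` of genic intervals with `gene_id` metadata and an
#'   `exons` metadata column holding a `GRangesList`
#' @export
readGeneModels <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    g <- rtracklayer::import(path, format = "BED")
    if (is.null(g$name) || anyNA(g$name))
      stop("BED gene models need a name column (gene id)")
    exons <- if (!is.null(g$blocks)) {
      GenomicRanges::GRangesList(lapply(seq_along(g), function(i) {
        b <- g$blocks[[i]]
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(g)[i],
                               IRanges::shift(b, BiocGenerics::start(g)[i] - 1L),
                               strand = GenomicRanges::strand(g)[i])
      }))
    } else {
      GenomicRanges::GRangesList(lapply(seq_along(g), function(i)
        GenomicRanges::granges(g[i])))
    }
    out <- GenomicRanges::granges(g)
    S4Vectors::mcols(out)$gene_id <- g$name
  } else {
    g <- rtracklayer::import(path, format = "gff3")
    genes <- g[g$type == "gene"]
    gid <- if (!is.null(genes$ID)) genes$ID else genes$gene_id
    ex <- g[g$type == "exon"]
    parent <- if (length(ex) && !is.null(ex$Parent))
      as.character(unlist(ex$Parent)) else ex$gene_id
    exons <- GenomicRanges::GRangesList(lapply(seq_along(genes), function(i) {
      e <- ex[parent == gid[i]]
      if (length(e)) GenomicRanges::granges(e) else GenomicRanges::granges(genes[i])
    }))
    out <- GenomicRanges::granges(genes)
    S4Vectors::mcols(out)$gene_id <- gid
  }
  S4Vectors::mcols(out)$exons <- exons
  names(out) <- out$gene_id
  out
}

# SAM is tab-separated text; the spec of this tool admits header-less files,
# so lines are split directly and CIGAR arithmetic is delegated to
# GenomicAlignments.
#' Read alignment records from a SAM file
#'
#' Requires QNAME, FLAG, RNAME, POS and CIGAR; unmapped records (FLAG 0x4 or
#' RNAME `*`) are dropped. Identity is `1 - NM / aligned_length` from the NM
#' auxiliary tag; records without NM get `NA` identity (they fail filtering
#' with reason `identity-unavailable` rather than being guessed). The
#' fragment orientation is recovered from a `|fw` / `|rv` suffix on the
#' query name, as written by [processDataset()]; mate 2 is recognised from
#' FLAG 0x80.
#'
#' @param path SAM file (header optional)
#' @return list: `records` (a `DataFrame` with `read_id`, `orientation`,
#'   `mate`, `rname`, `start`, `aligned_length`, `reverse_flag`, `identity`)
#'   and `blocks` (a `GRangesList` of aligned reference blocks per record)
#' @export
readSamAlignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(list(records = .emptySamRecords(),
                blocks = GenomicRanges::GRangesList()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record at line(s): ",
         paste(head(which(nf < 11L), 5), collapse = ", "))
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*" & cigar != "*"
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]; nm <- nm[mapped]

  ori <- rep("unknown", length(qname))
  ori[grepl("\\|fw$", qname)] <- "fw"
  ori[grepl("\\|rv$", qname)] <- "rv"
  readId <- sub("\\|(fw|rv)$", "", qname)
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L,
                 ifelse(bitwAnd(flag, 64L) > 0L, 1L, 0L))

  blockRanges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"), reduce.ranges = TRUE)
  alignedLen <- sum(IRanges::width(blockRanges))
  blocks <- GenomicRanges::GRangesList(mapply(function(r, ch)
    GenomicRanges::GRanges(ch, r), blockRanges, rname, SIMPLIFY = FALSE))
  records <- DataFrame(
    read_id = readId, orientation = ori, mate = mate, rname = rname,
    start = pos - 1L, aligned_length = alignedLen,
    reverse_flag = bitwAnd(flag, 16L) > 0L,
    identity = ifelse(is.na(nm), NA_real_, 1 - nm / alignedLen))
  list(records = records, blocks = blocks)
}

.emptySamRecords <- function() DataFrame(
  read_id = character(), orientation = character(), mate = integer(),
  rname = character(), start = integer(), aligned_length = integer(),
  reverse_flag = logical(), identity = numeric())

#' Coverage / identity filter for alignment records
#'
#' An alignment passes when it covers at least `minCoverage` reference bases
#' and its identity is at least `minIdentity` (both bounds inclusive).
#' Records with unavailable identity fail with reason
#' `"identity-unavailable"`.
#'
#' @param alignedLength aligned reference bases per record
#' @param identity per-record identity fraction (`NA` when unavailable)
#' @param minCoverage minimum aligned length, nt
#' @param minIdentity minimum identity fraction
#' @return `DataFrame` with logical `pass` and character `reason`
#'   (`"ok"`, `"coverage"`, `"identity"`, `"identity-unavailable"`)
#' @export
filterAlignment <- function(alignedLength, identity, minCoverage = 70L,
                            minIdentity = 0.95) {
  reason <- rep("ok", length(alignedLength))
  reason[!is.na(identity) & identity < minIdentity] <- "identity"
  reason[is.na(identity)] <- "identity-unavailable"
  reason[alignedLength < minCoverage] <- "coverage"
  DataFrame(pass = reason == "ok", reason = reason)
}

#' Assign alignments to genes by genic overlap
#'
#' The overlap of an alignment with a gene is the summed intersection of its
#' aligned blocks with the gene's genic interval. Genes reaching
#' `minOverlap` qualify: exactly one qualifying gene assigns the read, more
#' than one discards it as ambiguous, none leaves it intergenic.
#'
#' @param blocks `GRangesList` of aligned blocks, one element per alignment
#' @param genes gene models from [readGeneModels()]
#' @param minOverlap minimum genic overlap, nt
#' @return character vector per alignment: a gene id, `NA` (intergenic) or
#'   `"ambiguous"`
#' @export
assignGene <- function(blocks, genes, minOverlap = 50L) {
  n <- length(blocks)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  flat <- unlist(blocks, use.names = FALSE)
  grp <- rep(seq_len(n), lengths(blocks))
  ov <- GenomicRanges::findOverlaps(flat, genes)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      flat[S4Vectors::queryHits(ov)], genes[S4Vectors::subjectHits(ov)]))
    key <- paste(grp[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
    tot <- rowsum(w, key)
    parts <- strsplit(rownames(tot), " ")
    ai <- as.integer(vapply(parts, `[[`, "", 1L))
    gi <- as.integer(vapply(parts, `[[`, "", 2L))
    qual <- tot[, 1] >= minOverlap
    nq <- tabulate(ai[qual], nbins = n)
    out[nq > 1L] <- "ambiguous"
    one <- which(nq == 1L)
    hitGene <- gi[qual]
    names(hitGene) <- ai[qual]
    out[one] <- genes$gene_id[hitGene[as.character(one)]]
  }
  out
}

#' Transcript strand from tag orientation and alignment strand
#'
#' An fw-tagged fragment aligned to the forward genomic strand derives from
#' a `+` transcript; reverse alignment flips it, and an rv tag inverts both
#' (fw/forward -> `+`, fw/reverse -> `-`, rv/forward -> `-`,
#' rv/reverse -> `+`). Unknown or ambiguous orientations give `"*"`
#' (unknown). Vectorised.
#'
#' @param orientation `"fw"`, `"rv"`, `"unknown"` or `"ambiguous"`
#' @param reverseFlag logical; alignment on the reverse genomic strand
#' @return character vector over `"+"`, `"-"`, `"*"`
#' @export
callTranscriptStrand <- function(orientation, reverseFlag) {
  n <- max(length(orientation), length(reverseFlag))
  orientation <- rep_len(orientation, n)
  reverseFlag <- rep_len(reverseFlag, n)
  out <- rep("*", n)
  fw <- orientation == "fw"
  rv <- orientation == "rv"
  out[fw & !reverseFlag] <- "+"
  out[fw & reverseFlag] <- "-"
  out[rv & !reverseFlag] <- "-"
  out[rv & reverseFlag] <- "+"
  out
}

#' Per-gene sense / antisense tabulation
#'
#' For gene-assigned, strand-known calls, a call is antisense when its
#' transcript strand is opposite to the gene's annotated strand. Antisense
#' calls are localised as exonic when at least one aligned base intersects
#' an exon of the assigned gene, else intronic. The global antisense
#' fraction is antisense / strand-known genic calls (`NA` with a warning if
#' there are none).
#'
#' @param calls `DataFrame` with `gene_id`, `transcript_strand` and the row
#'   index `block_idx` into `blocks`
#' @param blocks `GRangesList` of aligned blocks (indexed by `block_idx`)
#' @param genes gene models from [readGeneModels()]
#' @return list: `perGene` (data.frame `gene_id`, `strand`, `sense`,
#'   `antisense`, `antisense_exonic`, `antisense_intronic`) and
#'   `antisenseFraction`
#' @export
countAntisense <- function(calls, blocks, genes) {
  genic <- !is.na(calls$gene_id) & calls$gene_id != "ambiguous"
  known <- genic & calls$transcript_strand %in% c("+", "-")
  gstrand <- setNames(as.character(GenomicRanges::strand(genes)),
                      genes$gene_id)
  rel <- rep("unknown", nrow(calls))
  rel[known] <- ifelse(
    calls$transcript_strand[known] == gstrand[calls$gene_id[known]],
    "sense", "antisense")

  exonic <- rep(NA, nrow(calls))
  for (i in which(known)) {
    ex <- genes$exons[[match(calls$gene_id[i], genes$gene_id)]]
    exonic[i] <- length(GenomicRanges::findOverlaps(
      blocks[[calls$block_idx[i]]], ex, ignore.strand = TRUE)) > 0L
  }

  gid <- sort(unique(calls$gene_id[genic]))
  perGene <- data.frame(
    gene_id = gid,
    strand = unname(gstrand[gid]),
    sense = vapply(gid, function(g)
      sum(rel == "sense" & calls$gene_id == g, na.rm = TRUE), integer(1)),
    antisense = vapply(gid, function(g)
      sum(rel == "antisense" & calls$gene_id == g, na.rm = TRUE), integer(1)),
    antisense_exonic = vapply(gid, function(g)
      sum(rel == "antisense" & calls$gene_id == g & exonic, na.rm = TRUE),
      integer(1)),
    row.names = NULL)
  perGene$antisense_intronic <- perGene$antisense - perGene$antisense_exonic
  frac <- if (sum(known) == 0L) {
    warning("no strand-known genic calls; antisense fraction undefined")
    NA_real_
  } else sum(rel == "antisense") / sum(known)
  list(perGene = perGene, antisenseFraction = frac,
       relation = rel, exonic = exonic)
}

#' Reads per kilobase of gene model per million mapped reads
#'
#' `count / (geneLength/1e3 * librarySize/1e6)`.
#'
#' @param count reads assigned to the gene
#' @param geneLength gene model length, nt (> 0)
#' @param librarySize total mapped reads in the library (> 0)
#' @return numeric expression value(s)
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, geneLength, librarySize) {
  if (any(geneLength <= 0) || any(librarySize <= 0))
    stop("geneLength and librarySize must be positive")
  count / (geneLength / 1e3 * librarySize / 1e6)
}

#' Full strand-assignment pipeline for a SAM file
#'
#' Reads alignments, applies the coverage/identity filter, assigns genes by
#' genic overlap, calls transcript strand from the tag orientation carried
#' in the read identifier, and tabulates sense/antisense reads per gene with
#' RPKM values (library size = gene-assigned read count).
#'
#' @param sam SAM file path
#' @param genes gene models ([readGeneModels()]) or annotation file path
#' @param minCoverage,minIdentity,minOverlap filtering thresholds
#' @param complementMate2 complement the tag orientation of mate-2 records
#'   before calling the strand
#' @return list: `calls` (per-alignment `DataFrame` with filtering, gene,
#'   strand, relation and localization), `perGene` (per-gene table with
#'   `rpkm`), `antisenseFraction`
#' @export
assignStrand <- function(sam, genes, minCoverage = 70L, minIdentity = 0.95,
                         minOverlap = 50L, complementMate2 = TRUE) {
  if (is.character(genes)) genes <- readGeneModels(genes)
  aln <- readSamAlignments(sam)
  rec <- aln$records
  flt <- filterAlignment(rec$aligned_length, rec$identity,
                         minCoverage, minIdentity)
  rec$pass <- flt$pass
  rec$fail_reason <- flt$reason
  keep <- which(rec$pass)
  gene <- rep(NA_character_, nrow(rec))
  gene[keep] <- assignGene(aln$blocks[keep], genes, minOverlap)
  ori <- rec$orientation
  if (complementMate2) {
    flip <- rec$mate == 2L & ori %in% c("fw", "rv")
    ori[flip] <- ifelse(ori[flip] == "fw", "rv", "fw")
  }
  strand <- callTranscriptStrand(ori, rec$reverse_flag)
  strand[!rec$pass] <- "*"
  calls <- DataFrame(rec, gene_id = gene, transcript_strand = strand,
                     block_idx = seq_len(nrow(rec)))
  cs <- countAntisense(calls, aln$blocks, genes)
  calls$relation <- cs$relation
  calls$localization <- ifelse(is.na(cs$exonic), NA_character_,
                               ifelse(cs$exonic, "exonic", "intronic"))
  perGene <- cs$perGene
  libSize <- sum(!is.na(gene) & gene != "ambiguous")
  glen <- IRanges::width(genes)[match(perGene$gene_id, genes$gene_id)]
  perGene$rpkm <- if (nrow(perGene) && libSize > 0)
    rpkm(perGene$sense + perGene$antisense, glen, libSize) else numeric(0)
  list(calls = calls, perGene = perGene,
       antisenseFraction = cs$antisenseFraction)
}
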