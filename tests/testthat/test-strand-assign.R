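test_that("coverage and identity thresholds are inclusive bounds", {
  f <- filterAlignment(c(69L, 120L, 70L, 200L), c(0.99, 0.94, 0.95, NA))
  expect_identical(f$pass, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(f$reason,
                   c("coverage", "identity", "ok", "identity-unavailable"))
})

test_that("gene assignment uses summed block overlap with genic intervals", {
  genes <- makeGenes("chr1", c(0L, 500L), c(200L, 800L), c("+", "-"),
                     c("geneA", "geneB"))
  gr <- function(s, e) GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1L, e)))
  # 100-nt block overlapping geneA by 49 -> intergenic
  expect_identical(assignGene(gr(151L, 251L), genes), NA_character_)
  expect_identical(assignGene(gr(120L, 220L), genes), "geneA")
  # split blocks 60 nt in each gene -> ambiguous
  both <- GenomicRanges::GRangesList(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101L, 601L), c(160L, 660L))))
  expect_identical(assignGene(both, genes), "ambiguous")
  # raising the overlap threshold is monotone
  expect_identical(assignGene(gr(120L, 220L), genes, minOverlap = 90L),
                   NA_character_)
})

test_that("transcript strand is the XOR of tag orientation and FLAG strand", {
  expect_identical(callTranscriptStrand("fw", FALSE), "+")
  expect_identical(callTranscriptStrand("fw", TRUE), "-")
  expect_identical(callTranscriptStrand("rv", FALSE), "-")
  expect_identical(callTranscriptStrand("rv", TRUE), "+")
  expect_identical(callTranscriptStrand("unknown", TRUE), "*")
  expect_identical(callTranscriptStrand("ambiguous", FALSE), "*")
  # flipping either input flips a known call; flipping both restores it
  for (o in c("fw", "rv")) for (rev in c(TRUE, FALSE)) {
    base <- callTranscriptStrand(o, rev)
    flipO <- callTranscriptStrand(ifelse(o == "fw", "rv", "fw"), rev)
    flipR <- callTranscriptStrand(o, !rev)
    expect_true(base != flipO && base != flipR)
    expect_identical(
      callTranscriptStrand(ifelse(o == "fw", "rv", "fw"), !rev), base)
  }
})

test_that("antisense tabulation and localization follow the gene annotation", {
  exons <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1L, 801L),
                                                    c(300L, 1000L))))
  genes <- makeGenes("chr1", 0L, 1000L, "+", "geneA", exons = exons)
  n <- 100
  blocks <- GenomicRanges::GRangesList(c(
    lapply(seq_len(99), function(i)
      GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 200L))),
    list(GenomicRanges::GRanges("chr1", IRanges::IRanges(401L, 500L)))))
  calls <- S4Vectors::DataFrame(
    gene_id = rep("geneA", n),
    transcript_strand = c(rep("+", 99), "-"),
    block_idx = seq_len(n))
  cs <- countAntisense(calls, blocks, genes)
  expect_equal(cs$antisenseFraction, 0.01)
  expect_identical(cs$perGene$sense, 99L)
  expect_identical(cs$perGene$antisense, 1L)
  # the antisense call sits in 401..500, outside both exons -> intronic
  expect_identical(cs$perGene$antisense_intronic, 1L)
  expect_identical(cs$perGene$antisense_exonic, 0L)

  exonicCall <- S4Vectors::DataFrame(gene_id = "geneA",
                                     transcript_strand = "-",
                                     block_idx = 1L)
  cs2 <- countAntisense(exonicCall, blocks, genes)
  expect_identical(cs2$perGene$antisense_exonic, 1L)

  noneKnown <- S4Vectors::DataFrame(gene_id = "geneA",
                                    transcript_strand = "*",
                                    block_idx = 1L)
  expect_warning(cs3 <- countAntisense(noneKnown, blocks, genes),
                 "undefined")
  expect_true(is.na(cs3$antisenseFraction))
})

test_that("rpkm is the depth- and length-normalised expression value", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1234, 5e6), 0)
  expect_equal(rpkm(25, 2500, 5e6), 2)
  expect_error(rpkm(1, 0, 1e6), "positive")
  expect_error(rpkm(1, 1000, 0), "positive")
})

test_that("SAM records parse with blocks, identity and orientation suffix", {
  sam <- writeSam(c(
    "@SQ\tSN:chr1\tLN:10000",
    samLine("r1/frag1|fw", 0L, "chr1", 101L, "100M", nm = 2L),
    samLine("r2/frag1|rv", 16L, "chr1", 201L, "40M20N60M", nm = 0L),
    samLine("r3/frag2", 0L, "chr1", 301L, "80M"),
    samLine("unmapped", 4L, "*", 0L, "*")))
  aln <- readSamAlignments(sam)
  rec <- aln$records
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$read_id, c("r1/frag1", "r2/frag1", "r3/frag2"))
  expect_identical(rec$orientation, c("fw", "rv", "unknown"))
  expect_identical(rec$reverse_flag, c(FALSE, TRUE, FALSE))
  expect_identical(rec$aligned_length, c(100L, 100L, 80L))
  expect_equal(rec$identity, c(0.98, 1, NA))
  # the spliced record has two reference blocks around the N gap
  expect_identical(BiocGenerics::start(aln$blocks[[2]]), c(201L, 261L))
  expect_identical(BiocGenerics::end(aln$blocks[[2]]), c(240L, 320L))
  # header-less input parses identically
  aln2 <- readSamAlignments(writeSam(
    samLine("r1/frag1|fw", 0L, "chr1", 101L, "100M", nm = 2L)))
  expect_identical(aln2$records$aligned_length, 100L)
  expect_error(readSamAlignments(writeSam("r1\t0\tchr1")), "malformed SAM")
})

test_that("gene models load from BED and GFF3", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\tgeneA\t0\t+",
               "chr1\t2000\t3000\tgeneB\t0\t-"), bed)
  g <- readGeneModels(bed)
  expect_identical(g$gene_id, c("geneA", "geneB"))
  expect_identical(as.character(GenomicRanges::strand(g)), c("+", "-"))
  expect_identical(BiocGenerics::start(g), c(1L, 2001L))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 1, 1000, ".", "+", ".",
                     "ID=geneA", sep = "\t"),
               paste("chr1", "src", "exon", 1, 300, ".", "+", ".",
                     "Parent=geneA", sep = "\t"),
               paste("chr1", "src", "exon", 801, 1000, ".", "+", ".",
                     "Parent=geneA", sep = "\t")), gff)
  g2 <- readGeneModels(gff)
  expect_identical(g2$gene_id, "geneA")
  expect_identical(length(g2$exons[[1]]), 2L)
})

test_that("error-free tagged fragments are recovered as sense end to end", {
  set.seed(77)
  genes <- makeGenes("chr1", c(0L, 5000L), c(2000L, 8000L), c("+", "-"),
                     c("geneA", "geneB"))
  n <- 200
  gidx <- sample(1:2, n, replace = TRUE)
  gstrand <- c("+", "-")[gidx]
  # a sense transcript fragment: on a + gene, fw tag aligns forward or rv
  # tag aligns reverse; on a - gene the two combinations flip
  ori <- sample(c("fw", "rv"), n, replace = TRUE)
  revFlag <- ifelse(gstrand == "+", ori == "rv", ori == "fw")
  starts <- ifelse(gidx == 1L, 101L, 5101L) + sample(0:500, n, TRUE)
  lines <- vapply(seq_len(n), function(i)
    samLine(sprintf("f%03d|%s", i, ori[i]),
            ifelse(revFlag[i], 16L, 0L), "chr1", starts[i], "100M", nm = 1L),
    "")
  res <- assignStrand(writeSam(lines), genes)
  calls <- res$calls
  expect_true(all(calls$pass))
  expect_identical(unname(calls$gene_id), c("geneA", "geneB")[gidx])
  expect_true(all(calls$relation == "sense"))
  expect_identical(sum(res$perGene$sense), as.integer(n))
  expect_identical(sum(res$perGene$antisense), 0L)
  # per-gene conservation: sense + antisense <= assigned strand-known calls
  for (g in res$perGene$gene_id) {
    tot <- sum(calls$gene_id == g & calls$transcript_strand %in% c("+", "-"),
               na.rm = TRUE)
    row <- res$perGene[res$perGene$gene_id == g, ]
    expect_lte(row$sense + row$antisense, tot)
  }
  expect_equal(res$antisenseFraction, 0)
})

test_that("mate-2 orientation is complemented before the strand call", {
  genes <- makeGenes("chr1", 0L, 2000L, "+", "geneA")
  # FLAG 128 marks mate 2; fw on mate 2 behaves like rv
  sam <- writeSam(samLine("p1/frag1|fw", 128L + 16L, "chr1", 101L, "100M",
                          nm = 0L))
  res <- assignStrand(sam, genes)
  expect_identical(unname(res$calls$transcript_strand), "+")
  res2 <- assignStrand(sam, genes, complementMate2 = FALSE)
  expect_identical(unname(res2$calls$transcript_strand), "-")
})
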