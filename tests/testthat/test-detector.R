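spec <- tagSpec()
RV <- canonicalTag(spec)                       # TCGCGATCGTCG
FW <- tagVariants(spec)$sequence[2]            # CGACGATCGCGA
FW35 <- tagVariants(spec)$sequence[4]

test_that("the greedy scan reports planted tags at their exact windows", {
  h <- scanRead(paste0(strrep("A", 20), RV, strrep("C", 20)), spec)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 20L)
  expect_identical(h$end, 32L)
  expect_identical(h$variant, "RV53")
  expect_identical(h$n_variations, 0L)

  h2 <- scanRead(paste0(RV, strrep("G", 40), FW, strrep("T", 30)), spec)
  expect_identical(h2$variant, c("RV53", "FW53"))
  expect_identical(h2$start, c(0L, 52L))
  # hits non-overlapping and sorted
  expect_true(all(h2$start[-1] >= h2$end[-nrow(h2)]))

  expect_identical(nrow(scanRead("ACGT", spec)), 0L)
})

test_that("read classification follows the 3'->5' chimera rule", {
  expect_identical(classifyRead(NULL),
                   list(status = "untagged", n_tags = 0L))
  h1 <- scanRead(paste0(strrep("A", 20), RV, strrep("C", 20)), spec)
  expect_identical(classifyRead(h1), list(status = "tagged", n_tags = 1L))
  hc <- scanRead(paste0(strrep("A", 20), RV, strrep("C", 20), FW35,
                        strrep("G", 20)), spec)
  expect_identical(classifyRead(hc)$status, "chimeric")
  expect_identical(classifyRead(hc)$n_tags, 2L)
})

test_that("splitting honours the length cutoff and slices qualities", {
  r <- paste0(strrep("A", 50), RV, strrep("C", 50))
  q <- paste0(strrep("H", 50), strrep("#", 12), strrep("J", 50))
  h <- scanRead(r, spec)
  fr <- splitRead(r, q, h, minLen = 40)
  expect_identical(nrow(fr), 2L)
  expect_identical(fr$sequence, c(strrep("A", 50), strrep("C", 50)))
  expect_identical(fr$qualities, c(strrep("H", 50), strrep("J", 50)))
  expect_identical(fr$end - fr$start, c(50L, 50L))

  r2 <- paste0(strrep("A", 30), RV, strrep("C", 50))
  fr2 <- splitRead(r2, NULL, scanRead(r2, spec), minLen = 40)
  expect_identical(fr2$sequence, strrep("C", 50))

  expect_identical(nrow(splitRead(strrep("A", 39), NULL, NULL, 40)), 0L)
  expect_identical(nrow(splitRead(strrep("A", 40), NULL, NULL, 40)), 1L)
  expect_error(splitRead("ACGT", NULL, NULL, 0), "minLen")
})

test_that("fragment orientation comes from the 5' flank, then the 3' flank", {
  # rv-tag then fw-tag: middle fragment sees disagreeing flanks
  r <- paste0(strrep("A", 45), RV, strrep("C", 45), FW, strrep("G", 45))
  fr <- splitRead(r, NULL, scanRead(r, spec), minLen = 10)
  expect_identical(fr$orientation, c("rv", "ambiguous", "fw"))

  # two rv tags agree: all tagged fragments rv, leading fragment too (3' flank)
  r2 <- paste0(strrep("A", 45), RV, strrep("C", 45), RV, strrep("G", 45))
  fr2 <- splitRead(r2, NULL, scanRead(r2, spec), minLen = 10)
  expect_identical(fr2$orientation, c("rv", "rv", "rv"))

  expect_identical(splitRead(strrep("A", 50), NULL, NULL, 40)$orientation,
                   "unknown")
})

test_that("a toy FASTQ runs end to end with consistent counters", {
  ids <- c("r1", "r2", "r3")
  seqs <- c(strrep("A", 45),
            paste0(strrep("G", 45), RV, strrep("C", 45)),
            strrep("T", 20))
  fq <- writeFastq(ids, seqs, strrep("I", nchar(seqs)))
  out <- tempfile(fileext = ".fastq")
  rpt <- tempfile()
  det <- processDataset(fq, spec, minLen = 40, fastqOut = out,
                        reportDir = rpt)
  cnt <- detectionCounters(det)
  expect_identical(cnt$reads_in, 3L)
  expect_identical(cnt$reads_tagged, 1L)
  expect_identical(cnt$reads_chimeric, 0L)
  expect_identical(cnt$total_tags, 1L)
  expect_identical(readClassifications(det)$status,
                   c("untagged", "tagged", "untagged"))

  written <- Biostrings::readDNAStringSet(out, format = "fastq")
  expect_identical(length(written), 3L)  # r1 whole, r2 two fragments
  expect_identical(names(written),
                   c("r1/frag1", "r2/frag1|rv", "r2/frag2|rv"))
  tp <- read.delim(file.path(rpt, "tagspositions.txt"))
  expect_identical(nrow(tp), 1L)
  expect_identical(tp$start, 45L)
  expect_identical(tp$variant, "RV53")

  # counters partition and histogram conservation
  st <- readClassifications(det)$status
  expect_identical(cnt$reads_in,
                   sum(st == "untagged") + sum(st == "tagged") +
                   sum(st == "chimeric"))
  expect_identical(sum(cnt$tag_count_histogram), cnt$total_tags)
})

test_that("empty and malformed FASTQ inputs are handled", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  det <- processDataset(empty, spec)
  expect_identical(detectionCounters(det)$reads_in, 0L)
  expect_identical(nrow(detectionHits(det)), 0L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated record
  expect_error(processDataset(bad, spec), "malformed FASTQ")

  p64 <- writeFastq("r1", strrep("A", 50), strrep("h", 50))
  expect_error(processDataset(p64, spec), "Phred\\+64|Phred\\+33")
})

test_that("chimeric fragments are excluded from output unless kept", {
  r <- paste0(strrep("A", 45), FW35, strrep("C", 45))
  fq <- writeFastq("chim", r, strrep("I", nchar(r)))
  out1 <- tempfile(fileext = ".fastq")
  det <- processDataset(fq, spec, minLen = 40, fastqOut = out1)
  expect_identical(readClassifications(det)$status, "chimeric")
  expect_identical(length(Biostrings::readDNAStringSet(out1,
                                                       format = "fastq")), 0L)
  out2 <- tempfile(fileext = ".fastq")
  processDataset(fq, spec, minLen = 40, fastqOut = out2, keepChimeric = TRUE)
  expect_identical(length(Biostrings::readDNAStringSet(out2,
                                                       format = "fastq")), 2L)
})

test_that("splitting is conservative: re-inserting tag windows round-trips", {
  set.seed(9)
  sim <- simulateCleanReads(simProfile(
    composition = c("0" = 20, "1" = 60, "2" = 60, "3" = 60), seed = 9), spec)
  det <- processDataset(simReads(sim), spec, minLen = 40)
  seqs <- as.character(simReads(sim))
  hits <- detectionHits(det)
  frs <- fragmentTable(det)
  for (rid in names(seqs)) {
    h <- hits[hits$read_id == rid, , drop = FALSE]
    f <- frs[frs$read_id == rid, , drop = FALSE]
    pieces <- rbind(
      data.frame(start = h$start, end = h$end),
      data.frame(start = f$start, end = f$end))
    pieces <- pieces[order(pieces$start), , drop = FALSE]
    rebuilt <- paste(substring(seqs[[rid]], pieces$start + 1, pieces$end),
                     collapse = "")
    expect_identical(rebuilt, seqs[[rid]])
  }
})

test_that("filters are monotone and runs deterministic", {
  set.seed(5)
  sim <- corrupt454(simulateCleanReads(simProfile(
    composition = c("1" = 40, "2" = 40, "3" = 40), seed = 5), spec))
  reads <- simReads(sim)

  d40 <- processDataset(reads, spec, minLen = 40)
  d80 <- processDataset(reads, spec, minLen = 80)
  expect_lte(sum(fragmentTable(d80)$passed), sum(fragmentTable(d40)$passed))

  spec0 <- tagSpec(maxVariations = 0)
  d0 <- processDataset(reads, spec0, minLen = 40)
  expect_lte(nrow(detectionHits(d0)), nrow(detectionHits(d40)))

  again <- processDataset(reads, spec, minLen = 40)
  expect_identical(as.data.frame(detectionHits(again)),
                   as.data.frame(detectionHits(d40)))
  expect_identical(as.data.frame(fragmentTable(again)),
                   as.data.frame(fragmentTable(d40)))
})

test_that("positional-median trimming cuts at the first failing position", {
  mk <- function(qs) {
    q <- intToUtf8(qs + 33L)
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(strrep("A", length(qs)), "r")),
      Biostrings::PhredQuality(Biostrings::BStringSet(setNames(q, "r"))))
  }
  ok <- medianQsTrim(mk(rep(30L, 50)), threshold = 25)
  expect_true(is.na(ok$cutPosition))
  expect_identical(Biostrings::width(ok$reads), 50L)

  tr <- medianQsTrim(mk(c(30L, 30L, 10L)), threshold = 25)
  expect_identical(tr$cutPosition, 2L)
  expect_identical(Biostrings::width(tr$reads), 2L)

  # positional medians 30 for 0..179 then 20: cut at 180 across many reads
  n <- 11
  qsets <- lapply(seq_len(n), function(i) c(rep(30L, 180), rep(20L, 60)))
  qs <- vapply(qsets, function(q) intToUtf8(q + 33L), "")
  ids <- paste0("r", seq_len(n))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(rep(strrep("A", 240), n), ids)),
    Biostrings::PhredQuality(Biostrings::BStringSet(setNames(qs, ids))))
  tr2 <- medianQsTrim(reads, threshold = 25)
  expect_identical(tr2$cutPosition, 180L)
  expect_true(all(Biostrings::width(tr2$reads) == 180L))
})
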