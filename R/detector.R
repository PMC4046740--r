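#' Scan one read for tags
#'
#' Greedy 5'->3' scan: at every offset each window length is tried against
#' all four tag variants; on a hit the scan records it and resumes at the
#' hit's end, so reported hits are non-overlapping and sorted by start.
#' Reads shorter than the smallest window return an empty table.
#'
#' @param read nucleotide string (the read sequence)
#' @param spec a [TagSpec]
#' @param readId identifier recorded in the hit table
#' @return `DataFrame` with one row per hit: `read_id`, `tag_index`, `start`,
#'   `end` (0-based half-open), `variant`, `direction`, `strand_class`,
#'   `n_variations`, `window_length`
#' @examples
#' spec <- tagSpec()
#' scanRead(paste0(strrep("A", 20), canonicalTag(spec), strrep("C", 20)), spec)
#' @export
scanRead <- function(read, spec = tagSpec(), readId = "read") {
  if (!nzchar(read)) stop("read sequence must be non-empty")
  read <- .normSeq(read)
  m <- scan_read_cpp(read, spec@variants$sequence, spec@windowLengths,
                     spec@maxVariations)
  h <- .hitFrame(m, spec)
  if (nrow(h) == 0L)
    return(DataFrame(read_id = character(), tag_index = integer(), h))
  DataFrame(read_id = readId, tag_index = seq_len(nrow(h)), h)
}

#' Classify a read from its tag hits
#'
#' A read with at least one inversely directed (3'->5') tag is a chimeric
#' artefact of multiple-displacement amplification; otherwise it is tagged
#' if it carries any tag, and untagged if it carries none.
#'
#' @param hits hit table for one read (as returned by [scanRead()])
#' @return list with `status` (`"untagged"`, `"tagged"` or `"chimeric"`) and
#'   `n_tags`
#' @export
classifyRead <- function(hits) {
  n <- if (is.null(hits)) 0L else nrow(hits)
  status <- if (n == 0L) "untagged"
            else if (any(hits$direction == "3to5")) "chimeric"
            else "tagged"
  list(status = status, n_tags = n)
}

# Orientation of each inter-tag segment from its flanking tags: the left
# (5') flank is authoritative when only one flank exists; two flanks that
# disagree mark the fragment ambiguous; no flanks -> unknown.
.fragOrientation <- function(leftClass, rightClass) {
  mapply(function(l, r) {
    if (is.na(l) && is.na(r)) "unknown"
    else if (is.na(r)) l
    else if (is.na(l)) r
    else if (l == r) l
    else "ambiguous"
  }, leftClass, rightClass, USE.NAMES = FALSE)
}

#' Split a read at its tag windows and orient the fragments
#'
#' Cuts the read at every hit window; inter-tag segments at least `minLen`
#' long become fragments with qualities sliced in register. A fragment takes
#' its fw/rv orientation from its 5'-flanking tag, falling back to the
#' 3'-flanking tag; disagreeing flanks give `"ambiguous"` and an untagged
#' read passes whole with orientation `"unknown"`.
#'
#' @param read nucleotide string
#' @param qualities quality string (same length as `read`) or `NULL`
#' @param hits sorted, non-overlapping hit table from [scanRead()]
#' @param minLen minimum fragment length retained (>= 1)
#' @return `DataFrame`: `sub_index`, `start`, `end`, `sequence`, `qualities`,
#'   `orientation`; rows only for fragments of length >= `minLen`
#' @export
splitRead <- function(read, qualities = NULL, hits = NULL, minLen = 40L) {
  minLen <- as.integer(minLen)
  if (is.na(minLen) || minLen < 1L) stop("minLen must be a positive integer")
  if (!is.null(qualities) && nchar(qualities) != nchar(read))
    stop("sequence and quality strings differ in length")
  f <- .fragmentRanges(nchar(read), hits)
  keep <- which(f$length >= minLen)
  if (!length(keep)) {
    return(DataFrame(sub_index = integer(), start = integer(),
                     end = integer(), sequence = character(),
                     qualities = character(), orientation = character()))
  }
  DataFrame(
    sub_index = seq_along(keep),
    start = f$start[keep], end = f$end[keep],
    sequence = substring(read, f$start[keep] + 1L, f$end[keep]),
    qualities = if (is.null(qualities)) NA_character_ else
      substring(qualities, f$start[keep] + 1L, f$end[keep]),
    orientation = f$orientation[keep]
  )
}

# All inter-tag segments (possibly empty) of a read of length `len`,
# 0-based half-open, with flank-derived orientations.
.fragmentRanges <- function(len, hits) {
  n <- if (is.null(hits)) 0L else nrow(hits)
  if (n == 0L) {
    return(list(start = 0L, end = len, length = len, orientation = "unknown"))
  }
  start <- c(0L, unname(hits$end))
  end <- c(unname(hits$start), len)
  left <- c(NA_character_, hits$strand_class)
  right <- c(hits$strand_class, NA_character_)
  list(start = start, end = end, length = end - start,
       orientation = .fragOrientation(left, right))
}

.checkPhred33 <- function(qualChars) {
  codes <- utf8ToInt(paste(qualChars, collapse = ""))
  if (length(codes) && (min(codes) < 33L || max(codes) > 80L))
    stop("quality strings are not Phred+33 (codes outside 33..80); ",
         "Phred+64 input is not supported")
}

.readFastq <- function(path) {
  if (file.exists(path) && file.size(path) == 0L)
    return(QualityScaledDNAStringSet(DNAStringSet(),
                                     PhredQuality(character(0))))
  reads <- tryCatch({
    r <- suppressWarnings(
      readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
    # force quality materialisation so truncated records fail here, with a
    # message naming the file, not deep inside downstream code
    if (!identical(unname(nchar(as.character(quality(r)))),
                   unname(nchar(as.character(r)))))
      stop("sequence and quality lengths differ")
    r
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  # keep only the first whitespace-delimited token of each identifier
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Process a FASTQ read set: scan, classify, split, filter
#'
#' Streams every read through the tag scan, classifies it, cuts it at tag
#' windows, and keeps fragments at least `minLen` nt long. Fragments of
#' chimeric reads are flagged and excluded from the cleaned output unless
#' `keepChimeric` is set. Output identifiers are `<read_id>/frag<k>` with a
#' `|fw` / `|rv` suffix carrying the inferred orientation where known.
#'
#' @param fastqIn path to a Phred+33 FASTQ file, or a
#'   `QualityScaledDNAStringSet`
#' @param spec a [TagSpec]
#' @param minLen minimum fragment length written to the cleaned output
#' @param fastqOut optional path for the cleaned FASTQ
#' @param reportDir optional directory receiving `tagspositions.txt` (one row
#'   per tag hit) and `summary.tsv` (the run's summary counters)
#' @param keepChimeric keep fragments of chimeric reads in the output
#' @return a [TagDetection] object
#' @export
processDataset <- function(fastqIn, spec = tagSpec(), minLen = 40L,
                           fastqOut = NULL, reportDir = NULL,
                           keepChimeric = FALSE) {
  minLen <- as.integer(minLen)
  if (is.na(minLen) || minLen < 1L) stop("minLen must be a positive integer")
  reads <- if (is(fastqIn, "QualityScaledDNAStringSet")) fastqIn
           else .readFastq(fastqIn)
  seqs <- as.character(reads)
  quals <- as.character(quality(reads))
  .checkPhred33(quals)
  ids <- names(reads)
  if (is.null(ids) && length(reads))
    stop("reads must carry identifiers")
  if (anyDuplicated(ids))
    warning("duplicate read identifiers in input")

  vseq <- spec@variants$sequence
  n <- length(reads)
  if (n == 0L) {
    hits <- .emptyHits()
    fragments <- .emptyFrags()
    fragments$passed <- logical(0)
    fragments$frag_id <- character(0)
    readTab <- DataFrame(read_id = character(), length = integer(),
                         status = character(), n_tags = integer())
    det <- new("TagDetection", reads = readTab, hits = hits,
               fragments = fragments,
               counters = .detectionCounters(readTab, hits, fragments),
               params = list(minLen = minLen, keepChimeric = keepChimeric,
                             canonical = spec@canonical,
                             maxVariations = spec@maxVariations))
    if (!is.null(fastqOut)) .writeFragments(det, character(), character(),
                                            fastqOut)
    if (!is.null(reportDir)) {
      dir.create(reportDir, recursive = TRUE, showWarnings = FALSE)
      writeTagPositions(det, file.path(reportDir, "tagspositions.txt"))
      utils::write.table(datasetSummary(det),
                         file.path(reportDir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(det)
  }
  seqsN <- .normSeq(seqs)
  lens <- nchar(seqsN)
  ms <- vector("list", n)
  for (i in seq_len(n))
    ms[[i]] <- scan_read_cpp(seqsN[i], vseq, spec@windowLengths,
                             spec@maxVariations)
  nh <- vapply(ms, nrow, integer(1))
  big <- do.call(rbind, ms)
  v <- spec@variants
  col <- function(name) as.vector(big[, name])
  hits <- DataFrame(
    read_id = rep(ids, nh), tag_index = sequence(nh),
    start = col("start"), end = col("end"),
    variant = v$label[col("variant")],
    direction = v$direction[col("variant")],
    strand_class = v$strand_class[col("variant")],
    n_variations = col("n_variations"),
    window_length = col("window_length"))
  if (!nrow(hits)) hits <- .emptyHits()
  nTags <- nh
  chim <- vapply(ms, function(m) any(m[, "variant"] >= 3L), logical(1))
  status <- ifelse(nh == 0L, "untagged", ifelse(chim, "chimeric", "tagged"))

  # fragments: the k+1 inter-tag segments of each read (empty ones dropped)
  fs <- fe <- vector("list", n)
  for (i in seq_len(n)) {
    m <- ms[[i]]
    fs[[i]] <- c(0L, as.vector(m[, "end"]))
    fe[[i]] <- c(as.vector(m[, "start"]), lens[i])
  }
  fragAll <- DataFrame(
    read_id = rep(ids, nh + 1L), sub_index = sequence(nh + 1L),
    start = unlist(fs), end = unlist(fe))
  fragAll$length <- fragAll$end - fragAll$start
  leftCls <- rightCls <- rep(NA_character_, nrow(fragAll))
  isFirst <- fragAll$sub_index == 1L
  isLast <- fragAll$sub_index == rep(nh + 1L, nh + 1L)
  leftCls[!isFirst] <- hits$strand_class[
    match(paste(fragAll$read_id, fragAll$sub_index - 1L),
          paste(hits$read_id, hits$tag_index))[!isFirst]]
  rightCls[!isLast] <- hits$strand_class[
    match(paste(fragAll$read_id, fragAll$sub_index),
          paste(hits$read_id, hits$tag_index))[!isLast]]
  fragAll$orientation <- .fragOrientation(leftCls, rightCls)
  fragAll$chimeric <- rep(status == "chimeric", nh + 1L)
  fragments <- fragAll[fragAll$length > 0L, , drop = FALSE]
  if (!nrow(fragments)) fragments <- .emptyFrags()
  # renumber surviving fragments within each read
  fragments$sub_index <- sequence(as.integer(table(
    factor(fragments$read_id, levels = unique(fragments$read_id)))))
  fragments$passed <- fragments$length >= minLen
  suffix <- ifelse(fragments$orientation %in% c("fw", "rv"),
                   paste0("|", fragments$orientation), "")
  fragments$frag_id <- paste0(fragments$read_id, "/frag", fragments$sub_index,
                              suffix)

  readTab <- DataFrame(read_id = ids, length = nchar(seqs),
                       status = status, n_tags = nTags)
  counters <- .detectionCounters(readTab, hits, fragments)
  det <- new("TagDetection", reads = readTab, hits = hits,
             fragments = fragments, counters = counters,
             params = list(minLen = minLen, keepChimeric = keepChimeric,
                           canonical = spec@canonical,
                           maxVariations = spec@maxVariations))
  validObject(det)

  if (!is.null(fastqOut))
    .writeFragments(det, seqs, quals, fastqOut)
  if (!is.null(reportDir)) {
    dir.create(reportDir, recursive = TRUE, showWarnings = FALSE)
    writeTagPositions(det, file.path(reportDir, "tagspositions.txt"))
    utils::write.table(datasetSummary(det),
                       file.path(reportDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  det
}

.emptyHits <- function() DataFrame(
  read_id = character(), tag_index = integer(), start = integer(),
  end = integer(), variant = character(), direction = character(),
  strand_class = character(), n_variations = integer(),
  window_length = integer())

.emptyFrags <- function() DataFrame(
  read_id = character(), sub_index = integer(), start = integer(),
  end = integer(), length = integer(), orientation = character(),
  chimeric = logical())

.detectionCounters <- function(readTab, hits, fragments) {
  hist <- table(factor(readTab$n_tags[readTab$n_tags > 0L],
                       levels = seq_len(max(1L, readTab$n_tags))))
  list(
    reads_in = nrow(readTab),
    mean_read_length = if (nrow(readTab)) mean(readTab$length) else 0,
    reads_tagged = sum(readTab$status != "untagged" & readTab$n_tags > 0L),
    reads_chimeric = sum(readTab$status == "chimeric"),
    total_tags = nrow(hits),
    tag_count_histogram = as.integer(hist) * as.integer(names(hist)),
    reads_by_tag_count = setNames(as.integer(hist), names(hist)),
    per_variant = setNames(
      as.integer(table(factor(hits$variant, levels = .VARIANT_LABELS))),
      .VARIANT_LABELS),
    fragments_ge40 = sum(fragments$length >= 40L),
    fragments_ge100 = sum(fragments$length >= 100L)
  )
}

.writeFragments <- function(det, seqs, quals, fastqOut) {
  fr <- det@fragments
  keep <- fr$passed & (det@params$keepChimeric | !fr$chimeric)
  fr <- fr[keep, , drop = FALSE]
  idx <- match(fr$read_id, det@reads$read_id)
  out <- DNAStringSet(substring(.normSeq(seqs[idx]), fr$start + 1L, fr$end))
  q <- BStringSet(substring(quals[idx], fr$start + 1L, fr$end))
  names(out) <- fr$frag_id
  writeXStringSet(out, fastqOut, format = "fastq", qualities = q)
  invisible(fastqOut)
}

#' Write the tag-positions report
#'
#' One TSV row per detected tag: `read_id`, `tag_index`, `start`, `end`
#' (0-based half-open), `variant`, `direction`, `n_variations`.
#'
#' @param det a [TagDetection]
#' @param path output file path
#' @export
writeTagPositions <- function(det, path) {
  h <- as.data.frame(det@hits)
  utils::write.table(
    h[, c("read_id", "tag_index", "start", "end", "variant", "direction",
          "n_variations")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim a read set at the first low-quality position
#'
#' Computes, for every position, the median Phred quality across all reads
#' covering it, scanning 5'->3'; the cut position is the first whose
#' positional median falls below `threshold`, and every read is truncated
#' there. If no positional median falls below the threshold the reads are
#' returned unchanged.
#'
#' @param reads a `QualityScaledDNAStringSet` (Phred+33) or FASTQ path
#' @param threshold minimum acceptable positional median quality
#' @return list with `reads` (trimmed set) and `cutPosition` (0-based, or
#'   `NA` when no trimming occurred)
#' @export
medianQsTrim <- function(reads, threshold = 25) {
  if (is.character(reads)) reads <- .readFastq(reads)
  if (!length(reads)) stop("dataset must be non-empty")
  if (threshold < 0) stop("threshold must be >= 0")
  qchars <- as.character(quality(reads))
  .checkPhred33(qchars)
  w <- width(reads)
  maxw <- max(w)
  qm <- matrix(NA_integer_, nrow = length(reads), ncol = maxw)
  for (i in seq_along(reads)) {
    qm[i, seq_len(w[i])] <- utf8ToInt(qchars[i]) - 33L
  }
  med <- apply(qm, 2, median, na.rm = TRUE)
  below <- which(med < threshold)
  if (!length(below))
    return(list(reads = reads, cutPosition = NA_integer_))
  cut <- below[1] - 1L  # 0-based position of the first failing median
  newEnd <- pmin(w, cut)
  kept <- newEnd > 0L
  trimmed <- subseq(reads[kept], start = 1L, end = newEnd[kept])
  list(reads = trimmed, cutPosition = cut)
}
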