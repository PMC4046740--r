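#' Build a tag specification
#'
#' Assembles the canonical tag as `flank + coreSite + flank` and derives the
#' scanned window lengths (canonical length +/- `maxVariations`) and the four
#' orientation variants. The defaults give the 12-nt tag `TCGCGATCGTCG`
#' (trinucleotide TCG on both sides of the PvuI site CGATCG) scanned over
#' 11-13 nt windows with at most one variation.
#'
#' @param flank nucleotide string placed on both sides of the core site
#' @param coreSite central recognition site (its own reverse complement for
#'   the default PvuI site)
#' @param maxVariations maximum edit distance (deletion, insertion or
#'   mismatch) tolerated when matching
#' @return a [TagSpec] object
#' @examples
#' tagSpec()
#' tagSpec("A", "CC", maxVariations = 0)
#' @export
tagSpec <- function(flank = "TCG", coreSite = "CGATCG", maxVariations = 1L) {
  if (!is.character(flank) || !is.character(coreSite) ||
      !nzchar(flank) || !nzchar(coreSite))
    stop("invalid tag specification: flank and coreSite must be non-empty strings")
  flank <- .normSeq(flank)
  coreSite <- .normSeq(coreSite)
  if (grepl("[^ACGT]", flank) || grepl("[^ACGT]", coreSite))
    stop("invalid alphabet: flank and coreSite may contain only A/C/G/T (or U)")
  maxVariations <- as.integer(maxVariations)
  if (is.na(maxVariations) || maxVariations < 0L)
    stop("invalid tag specification: maxVariations must be a non-negative integer")
  canonical <- paste0(flank, coreSite, flank)
  L <- nchar(canonical)
  # preference order for tie-breaking: full length first, then shorter, longer
  windows <- as.integer(L + c(0L, if (maxVariations > 0L)
    as.vector(rbind(-seq_len(maxVariations), seq_len(maxVariations)))))
  rv53 <- canonical
  fw53 <- .revcomp(canonical)
  variants <- DataFrame(
    label = .VARIANT_LABELS,
    sequence = unname(c(rv53, fw53, .strrev(rv53), .strrev(fw53))),
    direction = unname(.VARIANT_DIRECTION[.VARIANT_LABELS]),
    strand_class = unname(.VARIANT_CLASS[.VARIANT_LABELS])
  )
  new("TagSpec", flank = flank, coreSite = coreSite, canonical = canonical,
      maxVariations = maxVariations, windowLengths = windows,
      variants = variants)
}

#' @describeIn tagSpec the four orientation variants of a `TagSpec` as a
#'   `DataFrame` (`label`, `sequence`, `direction`, `strand_class`)
#' @param spec a [TagSpec]
#' @export
tagVariants <- function(spec) spec@variants

#' @describeIn tagSpec the assembled canonical tag sequence
#' @export
canonicalTag <- function(spec) spec@canonical

#' @describeIn tagSpec the scanned window lengths (sorted)
#' @export
windowLengths <- function(spec) sort(spec@windowLengths)

#' @describeIn tagSpec the matching tolerance
#' @export
maxVariations <- function(spec) spec@maxVariations

#' Bounded Levenshtein distance
#'
#' Edit distance (unit-cost deletions, insertions, mismatches) between two
#' nucleotide strings, computed only up to `limit`: pairs farther apart than
#' the limit return `NA`. Characters outside A/C/G/T (N and other ambiguity
#' codes) count as mismatches against every character, themselves included.
#' Vectorised over pairs.
#'
#' @param a,b character vectors of equal length (non-empty strings)
#' @param limit non-negative cap on the distance
#' @return integer vector; `NA` where the distance exceeds `limit`
#' @examples
#' boundedEditDistance("TCGCGATCGTCG", "TCGCGTTCGTCG", 1)  # 1
#' boundedEditDistance("TCGCGATCGTCG", "CGACGATCGCGA", 1)  # NA (exceeds)
#' @export
boundedEditDistance <- function(a, b, limit) {
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("strings must be non-empty")
  limit <- as.integer(limit)
  if (is.na(limit) || limit < 0L) stop("limit must be >= 0")
  bounded_edit_distance_cpp(.normSeq(a), .normSeq(b), limit)
}

.hitFrame <- function(m, spec, readId = NULL) {
  v <- spec@variants
  col <- function(name) as.vector(m[, name])
  d <- DataFrame(
    start = col("start"), end = col("end"),
    variant = v$label[col("variant")],
    direction = v$direction[col("variant")],
    strand_class = v$strand_class[col("variant")],
    n_variations = col("n_variations"),
    window_length = col("window_length")
  )
  rownames(d) <- NULL
  if (!is.null(readId) && nrow(d))
    d <- DataFrame(read_id = readId, tag_index = seq_len(nrow(d)), d)
  d
}

#' Match tag variants at one read offset
#'
#' Evaluates every window length at `pos` against all four tag variants and
#' returns the best hit: lowest number of variations, ties broken by window
#' length (canonical length, then one shorter, then one longer) and then by
#' variant order RV53, FW53, RV35, FW35.
#'
#' @param read nucleotide string
#' @param pos 0-based offset; must satisfy
#'   `0 <= pos <= nchar(read) - min(windowLengths(spec))`
#' @param spec a [TagSpec]
#' @return a one-row `DataFrame` (`start`, `end`, `variant`, `direction`,
#'   `strand_class`, `n_variations`, `window_length`) or `NULL` if every
#'   window exceeds the tolerance
#' @export
matchWindow <- function(read, pos, spec = tagSpec()) {
  read <- .normSeq(read)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L || pos > nchar(read) - min(spec@windowLengths))
    stop("pos out of range: need 0 <= pos <= nchar(read) - min window length")
  m <- match_window_cpp(read, pos, spec@variants$sequence,
                        spec@windowLengths, spec@maxVariations)
  if (nrow(m) == 0L) return(NULL)
  .hitFrame(m, spec)
}
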