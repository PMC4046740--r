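#' TagSpec: the tag sequence and its matching tolerances
#'
#' A `TagSpec` bundles the canonical tag (flank + core site + flank, by
#' default `TCG` + `CGATCG` + `TCG` = `TCGCGATCGTCG`), the four orientation
#' variants derived from it, the maximum number of tolerated variations
#' (deletion, insertion or mismatch) and the window lengths scanned
#' (canonical length +/- the tolerance, 11-13 nt by default).
#'
#' The four variants are: `RV53` (the canonical tag as synthesised 5'->3' on
#' first-strand cDNA), `FW53` (its reverse complement, arising on the second
#' cDNA strand), and their character reversals `RV35`/`FW35`, which represent
#' tags read against the direction of synthesis and are diagnostic of
#' chimeric reads produced during multiple-displacement amplification.
#'
#' @slot flank trinucleotide (or other) flank on each side of the core site
#' @slot coreSite the central recognition site (default the PvuI site CGATCG)
#' @slot canonical the assembled tag, `flank + coreSite + flank`
#' @slot maxVariations maximum edit distance tolerated in a match
#' @slot windowLengths integer vector of scanned window lengths, in
#'   tie-breaking preference order (canonical length first)
#' @slot variants `DataFrame` with columns `label`, `sequence`, `direction`
#'   (`5to3`/`3to5`) and `strand_class` (`fw`/`rv`)
#' @aliases TagSpec
#' @exportClass TagSpec
setClass("TagSpec", representation(
  flank = "character",
  coreSite = "character",
  canonical = "character",
  maxVariations = "integer",
  windowLengths = "integer",
  variants = "DataFrame"
))

setValidity("TagSpec", function(object) {
  msg <- character()
  if (nchar(object@flank) < 1 || nchar(object@coreSite) < 1)
    msg <- c(msg, "flank and core site must be non-empty")
  if (grepl("[^ACGT]", object@flank) || grepl("[^ACGT]", object@coreSite))
    msg <- c(msg, "flank and core site must contain only A/C/G/T")
  if (!identical(object@canonical,
                 paste0(object@flank, object@coreSite, object@flank)))
    msg <- c(msg, "canonical must equal flank + coreSite + flank")
  if (object@maxVariations < 0L)
    msg <- c(msg, "maxVariations must be >= 0")
  L <- nchar(object@canonical)
  want <- seq(L - object@maxVariations, L + object@maxVariations)
  if (!setequal(object@windowLengths, want))
    msg <- c(msg, "windowLengths must span canonical length +/- maxVariations")
  if (nrow(object@variants) != 4L)
    msg <- c(msg, "there must be exactly four orientation variants")
  # a tag equal to its own reverse complement carries no strand information;
  # reversal coincidences (palindromic-by-reversal toy tags) are tolerated
  v <- object@variants
  if (nrow(v) == 4L &&
      v$sequence[v$label == "RV53"] == v$sequence[v$label == "FW53"])
    msg <- c(msg, "canonical tag must differ from its reverse complement")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TagSpec", function(object) {
  cat("TagSpec:", object@canonical,
      sprintf("(%s + %s + %s)\n", object@flank, object@coreSite, object@flank))
  cat("  tolerance:", object@maxVariations, "variation(s); windows:",
      paste(sort(object@windowLengths), collapse = ","), "nt\n")
  v <- object@variants
  cat(sprintf("  %s: %s (%s, %s)\n", v$label, v$sequence, v$direction,
              v$strand_class), sep = "")
})

#' TagDetection: results of scanning a read set for tags
#'
#' Container for the per-read tag hits, per-read classifications
#' (untagged / tagged / chimeric), the fragments obtained by cutting each
#' read at its tag windows, and summary counters.
#'
#' Coordinates are 0-based half-open throughout. Fragments record their
#' flanking tags and the strand orientation inferred from them; the `passed`
#' column marks fragments meeting the active length cutoff.
#'
#' @slot reads `DataFrame`: `read_id`, `length`, `status`, `n_tags`
#' @slot hits `DataFrame`: `read_id`, `tag_index`, `start`, `end`, `variant`,
#'   `direction`, `strand_class`, `n_variations`, `window_length`
#' @slot fragments `DataFrame`: `read_id`, `sub_index`, `frag_id`, `start`,
#'   `end`, `length`, `orientation`, `chimeric`, `passed`
#' @slot counters list of summary counters (see [detectionCounters()])
#' @slot params list of parameters the run used
#' @aliases TagDetection
#' @exportClass TagDetection
setClass("TagDetection", representation(
  reads = "DataFrame",
  hits = "DataFrame",
  fragments = "DataFrame",
  counters = "list",
  params = "list"
))

setValidity("TagDetection", function(object) {
  msg <- character()
  cnt <- object@counters
  st <- object@reads$status
  if (cnt$reads_in != nrow(object@reads))
    msg <- c(msg, "reads_in counter disagrees with per-read records")
  if (cnt$reads_in != sum(st == "untagged") + sum(st == "tagged") +
      sum(st == "chimeric"))
    msg <- c(msg, "classification counts must partition the input reads")
  if (cnt$total_tags != nrow(object@hits))
    msg <- c(msg, "total_tags counter disagrees with the hit table")
  if (sum(cnt$tag_count_histogram) != nrow(object@hits))
    msg <- c(msg, "tag-count histogram does not sum to the number of hits")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TagDetection", function(object) {
  cnt <- object@counters
  cat("TagDetection:", cnt$reads_in, "reads;",
      cnt$reads_tagged, "with >= 1 tag;", cnt$reads_chimeric, "chimeric\n")
  cat("  tags found:", cnt$total_tags,
      "| fragments >=40 nt:", cnt$fragments_ge40,
      "| >=100 nt:", cnt$fragments_ge100, "\n")
  cat("  fragments passing min length", object@params$minLen, "nt:",
      sum(object@fragments$passed), "\n")
})

#' TagSimulation: simulated tagged reads with planted ground truth
#'
#' Reads produced by the concatenamer simulator together with the exact
#' positions, variants and strand classes of every planted tag and the
#' orientation of every cDNA segment.
#'
#' @slot reads `QualityScaledDNAStringSet` of simulated reads
#' @slot truth `DataFrame`: `read_id`, `tag_index`, `start`, `end`,
#'   `variant`, `strand_class` (0-based half-open coordinates)
#' @slot segments `DataFrame`: `read_id`, `seg_index`, `orientation`
#' @slot profile the simulation profile used (a list)
#' @aliases TagSimulation
#' @exportClass TagSimulation
setClass("TagSimulation", representation(
  reads = "QualityScaledDNAStringSet",
  truth = "DataFrame",
  segments = "DataFrame",
  profile = "list"
))

setValidity("TagSimulation", function(object) {
  msg <- character()
  tr <- object@truth
  # after corruption the truth keeps uncorrupted-read coordinates, which
  # indels can push past the new read end; skip the containment check then
  if (nrow(tr) && !isTRUE(object@profile$corrupted)) {
    len <- setNames(width(object@reads), names(object@reads))
    if (any(tr$start < 0L) || any(tr$end > len[tr$read_id]))
      msg <- c(msg, "planted tags must lie within their read")
    bad <- vapply(split(tr, tr$read_id), function(d) {
      o <- order(d$start)
      any(d$start[o][-1] < d$end[o][-nrow(d)])
    }, logical(1))
    if (any(bad)) msg <- c(msg, "planted tags must be disjoint within a read")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TagSimulation", function(object) {
  cat("TagSimulation:", length(object@reads), "reads,",
      nrow(object@truth), "planted tags",
      sprintf("(mean length %.0f nt)\n", mean(width(object@reads))))
})

#' @describeIn TagDetection the per-hit table (one row per detected tag)
#' @param x a `TagDetection` (or `TagSimulation` for its accessors)
#' @export
detectionHits <- function(x) x@hits

#' @describeIn TagDetection per-read classifications
#' @export
readClassifications <- function(x) x@reads

#' @describeIn TagDetection the fragment table
#' @export
fragmentTable <- function(x) x@fragments

#' @describeIn TagDetection the summary counters (reads in, reads with >= 1
#'   tag, chimeric reads, fragment counts at the 40 and 100 nt thresholds,
#'   tag-count histogram, per-variant counts)
#' @export
detectionCounters <- function(x) x@counters

#' @describeIn TagSimulation the simulated reads
#' @export
simReads <- function(x) x@reads

#' @describeIn TagSimulation the planted-tag ground truth
#' @export
simTruth <- function(x) x@truth

#' @describeIn TagSimulation per-segment orientations
#' @export
segmentOrientations <- function(x) x@segments
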