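#' Matching policy for scoring detected tags against planted tags
#'
#' @param positionSlack maximum start-coordinate difference (nt) for a
#'   detected hit to match a planted tag; absorbs the drift upstream indels
#'   cause because truth coordinates refer to the uncorrupted read
#' @param requireVariantMatch when `TRUE`, a hit only matches a planted tag
#'   of the same variant (recall then folds in orientation)
#' @return a list with class `"matchingPolicy"`
#' @export
matchingPolicy <- function(positionSlack = 2L, requireVariantMatch = FALSE) {
  positionSlack <- as.integer(positionSlack)
  if (is.na(positionSlack) || positionSlack < 0L)
    stop("positionSlack must be >= 0")
  structure(list(positionSlack = positionSlack,
                 requireVariantMatch = requireVariantMatch),
            class = "matchingPolicy")
}

# One-to-one greedy matching, planted-major: planted tags in start order
# each take the nearest unused hit on the same read within the slack.
.matchTags <- function(truth, hits, policy) {
  if (anyDuplicated(paste(truth$read_id, truth$tag_index)))
    stop("duplicate read_id/tag_index pairs in truth")
  tRow <- hRow <- integer(nrow(truth))
  npair <- 0L
  hStart <- hits$start
  hVar <- hits$variant
  hitsByRead <- split(seq_len(nrow(hits)), hits$read_id)
  truthByRead <- split(seq_len(nrow(truth)), truth$read_id)
  for (rid in names(truthByRead)) {
    hi <- hitsByRead[[rid]]
    if (is.null(hi)) next
    ti <- truthByRead[[rid]]
    ti <- ti[order(truth$start[ti])]
    used <- logical(length(hi))
    for (t in ti) {
      d <- abs(hStart[hi] - truth$start[t])
      ok <- !used & d <= policy$positionSlack
      if (policy$requireVariantMatch)
        ok <- ok & hVar[hi] == truth$variant[t]
      if (!any(ok)) next
      j <- which(ok)[which.min(d[ok])]
      used[j] <- TRUE
      npair <- npair + 1L
      tRow[npair] <- t
      hRow[npair] <- hi[j]
    }
  }
  data.frame(truth_row = tRow[seq_len(npair)], hit_row = hRow[seq_len(npair)])
}

#' Tag recall against planted ground truth
#'
#' Greedy one-to-one matching of detected hits to planted tags on the same
#' read within the policy's positional slack. Recall is matched / planted;
#' detected hits left unmatched are counted as false positives (including
#' hits on reads absent from the truth, e.g. spontaneous tag occurrences in
#' random sequence).
#'
#' @param truth planted-tag table ([simTruth()] of a [TagSimulation])
#' @param hits detected-hit table ([detectionHits()] of a [TagDetection])
#' @param policy a [matchingPolicy()]
#' @return list: `recall`, `matched`, `planted`, `detected`,
#'   `false_positives` (recall is 1 for empty truth with no hits)
#' @export
tagRecall <- function(truth, hits, policy = matchingPolicy()) {
  m <- .matchTags(truth, hits, policy)
  planted <- nrow(truth)
  list(recall = if (planted == 0L && nrow(hits) == 0L) 1
       else if (planted == 0L) NA_real_
       else nrow(m) / planted,
       matched = nrow(m), planted = planted, detected = nrow(hits),
       false_positives = nrow(hits) - nrow(m))
}

#' Count-based tag retrieval rate
#'
#' The per-read count metric: on each read, `min(planted, detected)` tags
#' count as retrieved, and the rate is retrieved / planted. This mirrors a
#' tags-per-read bookkeeping of detector output against the simulated
#' composition and is insensitive to the coordinate drift that indels cause
#' (truth coordinates refer to the uncorrupted read), which positional
#' matching under a small slack is not.
#'
#' @inheritParams tagRecall
#' @return list: `rate`, `retrieved`, `planted`
#' @export
tagRetrievalRate <- function(truth, hits) {
  planted <- nrow(truth)
  if (planted == 0L)
    return(list(rate = if (nrow(hits) == 0L) 1 else NA_real_,
                retrieved = 0L, planted = 0L))
  expK <- table(truth$read_id)
  obsK <- table(hits$read_id)[names(expK)]
  obsK[is.na(obsK)] <- 0L
  retrieved <- sum(pmin(as.integer(expK), as.integer(obsK)))
  list(rate = retrieved / planted, retrieved = retrieved, planted = planted)
}

#' Orientation accuracy among matched tags
#'
#' Fraction of matched planted/detected pairs whose detected fw/rv strand
#' class equals the planted strand class. Returns `NA` with a warning when
#' no pairs matched.
#'
#' @inheritParams tagRecall
#' @return a single fraction in `[0, 1]`, or `NA`
#' @export
orientationAccuracy <- function(truth, hits, policy = matchingPolicy()) {
  m <- .matchTags(truth, hits, policy)
  if (!nrow(m)) {
    warning("no matched tag pairs; orientation accuracy undefined")
    return(NA_real_)
  }
  mean(hits$strand_class[m$hit_row] == truth$strand_class[m$truth_row])
}

#' Expected versus observed tags-per-read table
#'
#' Histograms of reads by number of tags carried, from the ground truth
#' (expected) and from the detected hits (observed), with the total planted
#' and detected tag counts.
#'
#' @inheritParams tagRecall
#' @param maxK largest tags-per-read column tabulated
#' @return data.frame with rows `expected` and `observed`; columns
#'   `tags_1` .. `tags_<maxK>` and `total_tags`
#' @export
tagCountTable <- function(truth, hits, maxK = NULL) {
  expK <- table(truth$read_id)
  obsK <- table(hits$read_id)
  if (is.null(maxK))
    maxK <- max(1L, expK, obsK)
  lev <- seq_len(maxK)
  expH <- as.integer(table(factor(as.integer(expK), levels = lev)))
  obsH <- as.integer(table(factor(as.integer(obsK), levels = lev)))
  out <- data.frame(rbind(expected = expH, observed = obsH))
  names(out) <- paste0("tags_", lev)
  out$total_tags <- c(nrow(truth), nrow(hits))
  out
}

#' One summary row for a detection run
#'
#' Mirrors the per-sample yield summary: reads in, average read length,
#' reads with at least one tag, fragments at least 40 and 100 nt after tag
#' elimination, and chimeric reads.
#'
#' @param det a [TagDetection]
#' @return one-row data.frame
#' @export
datasetSummary <- function(det) {
  cnt <- detectionCounters(det)
  data.frame(
    n_reads = cnt$reads_in,
    mean_read_length = cnt$mean_read_length,
    n_reads_tagged = cnt$reads_tagged,
    n_fragments_ge40 = cnt$fragments_ge40,
    n_fragments_ge100 = cnt$fragments_ge100,
    n_chimeric = cnt$reads_chimeric
  )
}

#' Run the simulation-based accuracy evaluation
#'
#' Generates the default tagged-read set, corrupts it with the 454-like
#' error model, runs the detector at single-variation tolerance, and scores
#' recall and orientation accuracy against the planted truth.
#'
#' @param profile a [simProfile()]; its `seed` controls the whole run
#' @param spec a [TagSpec]
#' @param policy a [matchingPolicy()]
#' @param corrupt corruption function ([corrupt454()] or [corruptIllumina()]);
#'   `NULL` evaluates the clean reads
#' @return list: `recall` (fraction), `orientation_accuracy` (fraction),
#'   `planted`, `matched`, `false_positives`, `table` (the expected/observed
#'   tags-per-read table), `detection` (the [TagDetection])
#' @export
evaluateDetector <- function(profile = simProfile(), spec = tagSpec(),
                             policy = matchingPolicy(),
                             corrupt = corrupt454) {
  sim <- simulateCleanReads(profile, spec)
  if (!is.null(corrupt)) sim <- corrupt(sim)
  det <- processDataset(simReads(sim), spec = spec, minLen = 40L)
  truth <- simTruth(sim)
  hits <- detectionHits(det)
  rec <- tagRecall(truth, hits, policy)
  list(recall = rec$recall,
       retrieval = tagRetrievalRate(truth, hits)$rate,
       orientation_accuracy = orientationAccuracy(truth, hits, policy),
       planted = rec$planted, matched = rec$matched,
       false_positives = rec$false_positives,
       table = tagCountTable(truth, hits),
       detection = det)
}
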