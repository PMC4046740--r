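#' Simulation profile for concatenamer-derived tagged reads
#'
#' The default profile mirrors the simulated evaluation set: 1,002 reads of
#' mean length 350 nt whose tags-per-read composition is 5/100/726/166/5
#' reads carrying 1-5 tags (3,072 planted tags in total), corrupted with a
#' 454-like error model (per-base error rate 1%, 60% of errors single-base
#' indels, indels three-fold enriched inside homopolymer runs).
#'
#' @param composition named integer vector: `composition[k]` reads carry `k`
#'   tags (names are `k`; a `"0"` entry gives untagged reads)
#' @param meanReadLength mean simulated read length, nt
#' @param lengthSpread standard deviation of the read length, nt
#' @param errorRate per-base error probability
#' @param indelFraction proportion of errors that are single-base indels
#' @param homopolymerBias multiplier on the indel proportion inside
#'   homopolymer runs (renormalised so the read-wide proportion is kept)
#' @param seed integer seed making a simulation reproducible
#' @return a list with class `"simProfile"`
#' @export
simProfile <- function(composition = c("1" = 5L, "2" = 100L, "3" = 726L,
                                       "4" = 166L, "5" = 5L),
                       meanReadLength = 350L, lengthSpread = 40L,
                       errorRate = 0.01, indelFraction = 0.6,
                       homopolymerBias = 3, seed = 1L) {
  k <- as.integer(names(composition))
  if (anyNA(k) || any(k < 0L) || any(k > 10L))
    stop("composition names must be tag counts in 0..10")
  if (any(composition < 0L)) stop("composition counts must be >= 0")
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  if (indelFraction < 0 || indelFraction > 1)
    stop("indelFraction must be in [0, 1]")
  structure(list(composition = composition,
                 meanReadLength = as.integer(meanReadLength),
                 lengthSpread = as.integer(lengthSpread),
                 errorRate = errorRate, indelFraction = indelFraction,
                 homopolymerBias = homopolymerBias,
                 seed = as.integer(seed)),
            class = "simProfile")
}

.randBases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate error-free tagged reads with ground truth
#'
#' Each read is built as k+1 random-nucleotide cDNA segments separated by k
#' planted tag instances. A tag is the canonical (RV53) or
#' reverse-complement (FW53) variant with equal probability, and carries the
#' orientation of the segment it primes (the segment to its right); the
#' leading segment receives an independent orientation that no tag records.
#' Segment lengths partition the read length uniformly at random. All
#' planting is logged in the returned ground truth; a fixed seed reproduces
#' the simulation exactly.
#'
#' @param profile a [simProfile()]
#' @param spec a [TagSpec] supplying the planted variant sequences
#' @return a [TagSimulation] object (clean reads, constant quality 40)
#' @export
simulateCleanReads <- function(profile = simProfile(), spec = tagSpec()) {
  set.seed(profile$seed)
  ks <- rep(as.integer(names(profile$composition)), profile$composition)
  n <- length(ks)
  tagLen <- nchar(spec@canonical)
  rv <- spec@canonical
  fw <- .revcomp(spec@canonical)

  seqs <- character(n)
  ids <- sprintf("sim_%05d", seq_len(n))
  tStart <- tOri <- segOriL <- vector("list", n)
  for (i in seq_len(n)) {
    k <- ks[i]
    minLen <- tagLen * k + k + 1L
    L <- max(minLen,
             as.integer(round(rnorm(1, profile$meanReadLength,
                                    profile$lengthSpread))))
    rest <- L - tagLen * k
    # uniform composition of the non-tag length into k+1 segments
    breaks <- sort(sample.int(rest + 1L, k, replace = TRUE) - 1L)
    segLens <- diff(c(0L, breaks, rest))
    segOri <- sample(c("fw", "rv"), k + 1L, replace = TRUE)
    tagOri <- segOri[-1L]  # tag j primes segment j+1
    segs <- vapply(segLens, .randBases, "")
    tags <- ifelse(tagOri == "fw", fw, rv)
    pieces <- character(2L * k + 1L)
    pieces[seq(1L, 2L * k + 1L, by = 2L)] <- segs
    if (k > 0L) pieces[seq(2L, 2L * k, by = 2L)] <- tags
    seqs[i] <- paste(pieces, collapse = "")
    if (k > 0L) {
      tStart[[i]] <- segLens[1L] +
        c(0L, cumsum(tagLen + segLens[seq_len(k - 1L) + 1L]))
      tOri[[i]] <- tagOri
    }
    segOriL[[i]] <- segOri
  }
  nt <- lengths(tOri)
  starts <- as.integer(unlist(tStart))
  tagOriAll <- unlist(tOri)
  truth <- DataFrame(
    read_id = rep(ids, nt), tag_index = sequence(nt),
    start = starts, end = starts + tagLen,
    variant = ifelse(tagOriAll == "fw", "FW53", "RV53"),
    strand_class = tagOriAll)
  if (!nrow(truth)) truth <- .emptyTruth()
  segments <- DataFrame(read_id = rep(ids, lengths(segOriL)),
                        seg_index = sequence(lengths(segOriL)),
                        orientation = unlist(segOriL))
  reads <- QualityScaledDNAStringSet(
    DNAStringSet(setNames(seqs, ids)),
    PhredQuality(BStringSet(setNames(strrep("I", nchar(seqs)), ids))))
  sim <- new("TagSimulation", reads = reads, truth = truth,
             segments = segments, profile = unclass(profile))
  validObject(sim)
  sim
}

.emptyTruth <- function() DataFrame(
  read_id = character(), tag_index = integer(), start = integer(),
  end = integer(), variant = character(), strand_class = character())

# positions lying inside a homopolymer run (>= 2 identical adjacent bases)
.inHomopolymer <- function(bases) {
  n <- length(bases)
  if (n < 2L) return(logical(n))
  same <- bases[-1L] == bases[-n]
  c(same, FALSE) | c(FALSE, same)
}

.corruptRead <- function(bases, quals, errorRate, indelFraction,
                         homopolymerBias) {
  n <- length(bases)
  err <- which(runif(n) < errorRate)
  if (!length(err)) return(list(bases = bases, quals = quals))
  w <- rep(1, n)
  if (homopolymerBias != 1) w[.inHomopolymer(bases)] <- homopolymerBias
  # renormalise so the read-wide indel proportion stays indelFraction
  pIndel <- pmin(1, indelFraction * w / mean(w))
  isIndel <- runif(length(err)) < pIndel[err]
  ops <- ifelse(isIndel,
                ifelse(runif(length(err)) < 0.5, "ins", "del"), "sub")
  alphabet <- c("A", "C", "G", "T")
  # apply 3'->5' so earlier coordinates stay valid
  for (j in rev(seq_along(err))) {
    i <- err[j]
    if (ops[j] == "sub") {
      bases[i] <- sample(setdiff(alphabet, bases[i]), 1L)
      quals[i] <- 10L
    } else if (ops[j] == "del") {
      bases <- bases[-i]
      quals <- quals[-i]
    } else {
      ins <- sample(alphabet, 1L)
      bases <- append(bases, ins, after = i)
      quals <- append(quals, 10L, after = i)
    }
  }
  list(bases = bases, quals = quals)
}

.applyCorruption <- function(sim, perRead) {
  seqs <- as.character(simReads(sim))
  quals <- as.character(quality(simReads(sim)))
  out <- character(length(seqs))
  outq <- character(length(seqs))
  for (i in seq_along(seqs)) {
    r <- perRead(strsplit(seqs[i], "")[[1]],
                 utf8ToInt(quals[i]) - 33L, i)
    out[i] <- paste(r$bases, collapse = "")
    outq[i] <- intToUtf8(r$quals + 33L)
  }
  names(out) <- names(outq) <- names(simReads(sim))
  reads <- QualityScaledDNAStringSet(DNAStringSet(out),
                                     PhredQuality(BStringSet(outq)))
  prof <- sim@profile
  prof$corrupted <- TRUE
  initialize(sim, reads = reads, profile = prof)
}

#' Corrupt simulated reads with a 454-like error model
#'
#' Every base is hit independently with probability `errorRate`; an error is
#' a single-base insertion or deletion with probability `indelFraction`
#' (up-weighted inside homopolymer runs by `homopolymerBias` and
#' renormalised), otherwise a substitution to a uniformly random different
#' base. Error sites receive a fixed low quality (Q10). Ground-truth
#' coordinates are deliberately not updated: downstream matching must
#' tolerate the small positional drift indels cause.
#'
#' @param sim a [TagSimulation] from [simulateCleanReads()]
#' @param profile the [simProfile()] supplying the error parameters; defaults
#'   to the profile stored in `sim`
#' @return a [TagSimulation] with corrupted reads and unchanged truth
#' @export
corrupt454 <- function(sim, profile = NULL) {
  p <- if (is.null(profile)) sim@profile else unclass(profile)
  if (p$errorRate == 0) return(sim)
  set.seed(p$seed + 104729L)  # decoupled from the planting stream
  .applyCorruption(sim, function(bases, quals, i)
    .corruptRead(bases, quals, p$errorRate, p$indelFraction,
                 p$homopolymerBias))
}

#' Corrupt simulated reads with an Illumina-like error model
#'
#' Substitutions only (read lengths are conserved), with a substitution rate
#' that ramps linearly along the read from 0 at the 5' end to twice
#' `errorRate` at the 3' end, keeping the mean per-base rate at `errorRate`.
#'
#' @inheritParams corrupt454
#' @return a [TagSimulation] with corrupted reads and unchanged truth
#' @export
corruptIllumina <- function(sim, profile = NULL) {
  p <- if (is.null(profile)) sim@profile else unclass(profile)
  if (p$errorRate == 0) return(sim)
  set.seed(p$seed + 104729L)
  alphabet <- c("A", "C", "G", "T")
  .applyCorruption(sim, function(bases, quals, i) {
    n <- length(bases)
    rate <- 2 * p$errorRate * (seq_len(n) - 0.5) / n
    err <- which(runif(n) < rate)
    for (i2 in err) {
      bases[i2] <- sample(setdiff(alphabet, bases[i2]), 1L)
      quals[i2] <- 10L
    }
    list(bases = bases, quals = quals)
  })
}

#' Write a simulation to FASTQ plus a truth TSV
#'
#' @param sim a [TagSimulation]
#' @param fastq output FASTQ path
#' @param truthTsv optional path for the planted-tag table (`read_id`,
#'   `tag_index`, `start`, `end`, `variant`, `strand_class`)
#' @export
writeSimulation <- function(sim, fastq, truthTsv = NULL) {
  r <- simReads(sim)
  writeXStringSet(DNAStringSet(r), fastq, format = "fastq",
                  qualities = BStringSet(quality(r)))
  if (!is.null(truthTsv))
    utils::write.table(as.data.frame(simTruth(sim)), truthTsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fastq)
}
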