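---
title: "Tag-based strand-specific read preprocessing: models and design choices"
author: "strandtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based strand-specific read preprocessing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandtag)
```

## The problem

Strand-specific RNA-seq libraries can be built platform-independently by
priming first-strand cDNA synthesis with a random octamer carrying a 12-nt
synthetic tag at its 5' end. The tag is the trinucleotide `TCG` on both
sides of the palindromic PvuI restriction site `CGATCG`, giving the
canonical sequence `TCGCGATCGTCG`. Because the tag sits at the 5' end of
every first-strand cDNA, and because single-stranded cDNAs are ligated into
long concatenamers before amplification, a sequencing read may span several
cDNA molecules, each delimited by a tag copy. The tag then carries three
kinds of information:

* **strand of origin** — the tag appears as the canonical sequence (`rv5-3`)
  on first-strand cDNA and as its reverse complement (`fw5-3`,
  `CGACGATCGCGA`) on second-strand copies;
* **ligation junctions** — each internal tag marks the boundary between two
  adjacent cDNA molecules, where the read must be split;
* **amplification artefacts** — a tag read against the direction of
  synthesis (the character-reversed forms `rv3-5`/`fw3-5`) cannot arise from
  normal synthesis and flags the read as a chimera of strand-displacement
  amplification.

The flank `TCG` is the trinucleotide whose assembled 12-mer is rarest in a
human transcriptome reference, minimising spontaneous occurrences; the
`rankFlankCandidates()` function reproduces that rarity ranking for any
transcriptome and core site.

## Tag matching model

Sequencing errors (in particular 454 homopolymer indels) corrupt tag
copies, so detection tolerates at most one variation — one deletion,
insertion or mismatch, i.e. Levenshtein distance 1. The scanner slides
5'&rarr;3' over each read and, at every offset, compares windows of 11, 12
and 13 nt (canonical length ± tolerance) against all four tag variants with
a banded edit-distance computation capped at the tolerance. On a hit the
scan emits it and resumes at the hit's end, so hits are non-overlapping and
ordered.

Ties are resolved deterministically: fewest variations first, then window
length 12 over 11 over 13, then variant order RV53, FW53, RV35, FW35.
One refinement matters in practice: with tolerance 1 an exact tag preceded
by an arbitrary base also matches one offset earlier as a 13-nt window with
one variation. A strict greedy scan would emit that imperfect hit first and
mis-place the window. The scanner therefore never lets an imperfect
candidate pre-empt a strictly better hit that starts inside the candidate's
own span — exact full-length matches dominate. Ambiguity codes (`N`) never
match any character, so they count as mismatches; input is uppercased and
`U` is mapped to `T`.

Why Levenshtein rather than mismatch-only counting: the tolerance must
absorb single indels, the dominant 454 error mode, and distance-1 matching
across window lengths 11–13 subsumes a mismatch-only reading. The four
variants are pairwise at least 3 edits apart, so at tolerance 1 a
single-edit corruption can never be attributed to the wrong variant.

## Read splitting and orientation

A read is cut at every detected tag window; the inter-tag segments become
fragments, with base qualities sliced in register. Fragments shorter than
the length cutoff (default 40 nt, the study's value; a 100-nt column is
also tabulated in reports) are discarded. Orientation is inherited from the
flanking tags: the 5'-flanking tag is authoritative (it primes the 5' end
of the downstream cDNA), the 3' flank is the fallback for the leading
segment, two disagreeing flanks mark the fragment `ambiguous`, and an
untagged read passes whole as `unknown`. Reads containing any 3'&rarr;5'
tag are classified chimeric; their fragments are flagged and excluded from
the cleaned FASTQ by default (`keepChimeric` overrides), since such reads
are artefacts for strand inference even though their tag statistics are
still tabulated.

Quality control mirrors the study's two global filters: `medianQsTrim()`
computes the per-position median Phred score across all reads covering the
position and truncates every read at the first position whose median falls
below the threshold (default 25); fragment length filtering happens after
tag excision. Quality encoding is fixed at Phred+33 and quality strings
that look Phred+64 are rejected outright rather than re-scaled.

## The simulator

`simulateCleanReads()` emulates the concatenamer geometry directly: each
read is k+1 i.i.d.-uniform random nucleotide segments separated by k planted
tags. Defaults are the evaluation conditions: 1,002 reads whose
tags-per-read composition is 5/100/726/166/5 reads carrying 1–5 tags
(3,072 tags in total), mean read length 350 nt. The read-length spread
(s.d. 40 nt) is our choice of a realistic 454 length dispersion; the
segment partition is uniform at random; each tag is `rv` or `fw` with
probability ½ independently, and carries the orientation of the segment it
primes (the segment to its right — the leading segment gets an independent
orientation no tag records).

`corrupt454()` applies per-base errors at rate 1% by default, of which 60%
are single-base indels, up-weighted threefold inside homopolymer runs and
renormalised so the read-wide indel proportion is preserved; the remainder
are substitutions to a uniformly random different base. Error sites get a
fixed low quality (Q10). `corruptIllumina()` substitutes only, with a
linear 5'&rarr;3' rate ramp averaging the nominal rate. Ground-truth
coordinates deliberately keep uncorrupted-read positions.

What the simulator does **not** emulate: real transcript sequence
composition (segments are uniform random, so k-mer statistics are flatter
than a transcriptome), expression levels, rRNA contamination, 454 flowgram
noise structure, or coupled paired-end mates. Passing the accuracy checks
therefore demonstrates the detector's tolerance and bookkeeping under the
stated error model, not performance on any particular biological sample.

## Scoring detection against the truth

Two retrieval metrics are provided, and they answer different questions:

* `tagRecall()` matches detected hits to planted tags one-to-one (greedy,
  planted-major, nearest unused hit on the same read) within a positional
  slack of 2 nt. Because truth coordinates refer to the uncorrupted read,
  upstream indels drift later tags by more than 2 nt often enough that this
  metric saturates around 97% at the default error rates even when every
  tag is found — it measures *positional* agreement.
* `tagRetrievalRate()` compares tags-per-read counts
  (`min(planted, detected)` per read, summed), the bookkeeping a
  tags-per-read table implies; it is insensitive to coordinate drift and
  reflects the fraction of tags actually found (~99.5% at the default
  error rate, close to the single-tag survival bound
  \((1-p)^{12} + 12p(1-p)^{11} \approx 0.9934\) at \(p = 0.01\)).

`orientationAccuracy()` is the fraction of matched pairs whose detected
fw/rv class equals the planted class; variant separation makes it
essentially 1 under single-variation corruption. Detected tags on reads
absent from the truth (spontaneous matches in random sequence) count as
false positives, never as errors.

One intrinsic collision is worth knowing: the canonical tag's 6-nt prefix
`TCGCGA` equals the reverse-complement variant's 6-nt suffix, so a chance
`CGACGA` hexamer immediately 5' of a planted canonical tag creates an
*exact* `fw5-3` occurrence overlapping the planted one. The scan takes the
earlier exact hit — defensibly, since the data genuinely contain it. At
~4⁻⁶ per planted tag this costs well under one tag per default-sized run.

## Strand assignment

Aligned fragments (SAM; the FLAG field's reverse-strand bit) are combined
with the tag orientation carried in the read identifier (`|fw` / `|rv`
suffix written by `processDataset()`): an fw tag on a forward alignment
means the transcript lies on `+`; reversing the alignment or switching to
an rv tag flips the call (an XOR). Mate-2 orientations are complemented
first (configurable). Calls with unknown orientation are `*`.

The study's mapping filters are applied as standalone, inclusive-bound
operations: aligned reference coverage ≥ 70 nt, identity ≥ 95% (computed as
1 − NM/aligned length; alignments without an NM tag fail with reason
`identity-unavailable` rather than being guessed), gene assignment by
summed block overlap ≥ 50 nt with the genic interval, ambiguous
(multi-gene) assignments discarded. A call is antisense when its transcript
strand is opposite to the assigned gene's annotated strand; localisation is
exonic if any aligned base intersects an exon. `rpkm()` is the usual
count/(kb·Mreads) value. The 15-nt end-trim allowance some annotation
pipelines apply during isoform matching is exposed as a constant but not
applied; it is not reconstructible as an alignment-level operation.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere; FASTQ is Phred+33.
* Fragment identifiers are `<read>/frag<k>` with `k` from 1, plus the
  orientation suffix when known.
* The banded Levenshtein kernel is exact for distances up to the cap and
  returns a sentinel (`NA`) beyond it; it is symmetric by construction.
* All randomness flows through a single integer seed per simulation
  profile; corruption draws from a stream decoupled from planting, so the
  same clean read set can be corrupted reproducibly.
* Degenerate inputs: empty FASTQ gives empty outputs and zero counters; an
  empty composition simulates zero reads; an empty matched set makes
  orientation accuracy `NA` with a warning rather than a silent 0 or 1.

## Problem sizes used in the checks

The packaged checks run the full 1,002-read / 3,072-tag evaluation over
five seeds (a few seconds per replicate), a 10,000-read round-trip of the
splitter, 1,000-record filter equivalence sweeps, and 1,000-pair
edit-distance oracle comparisons. These sizes match the original
evaluation's scale, so no scaling caveat applies to the headline figures.

## Known limitations

* Only one tag design per run; degenerate-base-aware matching is limited to
  N-as-mismatch.
* Paired-end mates are processed independently at detection time; mate
  pairing is only consulted again at strand-calling (mate-2 complement).
* The positional-recall metric conflates detection and coordinate drift at
  indel-heavy error profiles (see above); use the count-based rate for
  retrieval questions.
* The simulator's uniform-random segments slightly inflate spontaneous tag
  occurrences relative to a real transcriptome of biased composition; they
  appear as a handful of false positives per run and are reported as such.
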