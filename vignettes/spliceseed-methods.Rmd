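---
title: "Methods: splice-aware seed-and-extend alignment in spliceseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-aware seed-and-extend alignment in spliceseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `spliceseed`, its tunable
parameters, the numerical conventions adopted where the method leaves
choices open, what the synthetic-data generator does and does not
emulate, and the known limitations. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The alignment model

`spliceseed` maps RNA-seq reads to a genome naively, without a
transcriptome annotation, in four stages.

**Read-side word lookup.** The index is built over the *reads*, not the
genome: every `word_size`-base word (default 16) of every read, in both
the given and the reverse-complement orientation, is recorded with its
read, offset and orientation. Indexing both orientations means the
reference is scanned exactly once, on its plus strand; alignments of the
reverse-complemented read carry the SAM reverse flag. Words containing
`N` are not indexed, and `N` never counts as a match anywhere in the
pipeline — a conservative convention, since an `N` carries no evidence of
identity.

Two masks protect seeding specificity:

* *Poly-A masking*: a word with at least `polyA_threshold` A's or T's
  (default 15 of 16) is dropped at build time, which prevents seeding on
  poly-A tails and their complements. For non-default word sizes the
  threshold scales as `word_size - 1`, overridable.
* *Repeat masking*: reference words occurring more than
  `max_db_word_count` times (default 60) are removed from the lookup.
  Only words already present in the reads are counted, on the reference
  plus strand; reverse-complement repeats are caught through the
  read-side reverse-orientation entries, which avoids double counting.
  A word occurring exactly at the cutoff is retained ("more than").

**Seeding.** The reference is scanned with a rolling word; each hit is
extended to the maximal exact run on its (read, reference) diagonal,
duplicate hits on a covered diagonal are merged, and runs of at least
`seed_len` bases (default 18) become seeds. The exact run of a seed must
sit inside one exon, so exons shorter than the seed length are not
recoverable by this design; they are rare in real annotation and the
package makes no special provision for them.

**Greedy gapped extension.** From each seed the alignment is extended
base by base under the scoring scheme *match +1, substitution −4, gap
open 0, gap extension −4 per base* (user-adjustable; base qualities never
affect the score). At a mismatch, a fixed table of 14 candidate
operations is tried strictly in order — substitutions of length 1 and 2,
insertions and deletions of lengths 1–3, first with 0 allowed
mismatches in their confirmation windows, then with 2:

| operation | length | required matches | allowed mismatches |
|---|---|---|---|
| substitution | 1 | 9 | 0 |
| insertion | 1 | 10 | 0 |
| deletion | 1 | 10 | 0 |
| insertion | 2 | 10 | 0 |
| deletion | 2 | 10 | 0 |
| insertion | 3 | 13 | 0 |
| deletion | 3 | 13 | 0 |
| substitution | 2 | 12 | 0 |
| insertion | 1 | 10 | 2 |
| deletion | 1 | 10 | 2 |
| insertion | 2 | 10 | 2 |
| deletion | 2 | 10 | 2 |
| insertion | 3 | 13 | 2 |
| deletion | 3 | 13 | 2 |

The requirement is interpreted as: within the window of
`required + allowed` bases following the applied operation, at least
`required` must match. This is the only reading consistent with the
paired columns of the table; where the window is truncated by a sequence
end, all remaining bases must match up to the allowed mismatches, so
events near the read end are not forbidden. The first satisfied
operation is applied; a single substitution is the fallback. The table
is replaceable through a plain-text config (`read_operation_table()`),
which is how the method would be retuned for indel-dominated chemistries.

Extension stops at a sequence end or when the running score drops more
than the *X-drop* bound below its maximum, then backtracks to the
maximum. The bound is the most penalised gapped operation in the active
table — a three-base gap, `|gap_open| + 3·|gap_extend|` = 12 under the
defaults — and is recomputed if the user changes penalties or the table.
Ties in the running maximum resolve to the earliest position (strictly
greater updates), giving the shortest maximal extension,
deterministically. Leftward extension is the mirror image: the same
table applied to the reversed sequences; nothing in the operation table
is direction-sensitive, so mirroring introduces no asymmetry.

Gaps that can slide at equal score are normalised to the upstream-most
equal-score placement in the orientation of the target, the convention
that keeps indel positions stable for downstream variant calling.

**Spliced chaining and junction resolution.** Local alignments of one
read on one reference and strand are clustered into loci (separated by
more than `max_intron`) and chained by dynamic programming to maximise
the combined score, defined as the sum of segment scores minus
`match × overlap` for the read overlap of each adjacent pair — overlap
bases are counted once; the subsequent junction re-scoring assigns them
exactly once to one side. Scoring is *splice-neutral*: introns carry no
reward or penalty, so a spliced placement and an equal-base continuous
placement (a processed retro-copy) score identically and neither is
preferred.

Where two segments meet on the read (possibly overlapping), every
junction offset in the overlap window is examined: the intron's boundary
dinucleotides are classified as canonical (GT-AG, or CT-AC for genes on
the minus strand), minor (GC-AG / CT-GC, then AT-AC / GT-AT) or
non-canonical, and the highest-priority class available wins. Minor and
non-canonical classes are considered only when both flanking alignments
score at least `splice_score_threshold` (default 50) — di-nucleotide
pairs are too frequent in a genome to trust on weak evidence — and the
same gate is applied to non-canonical sites, which the hierarchy implies
but does not state separately. Within a class, the offset with the
maximal re-scored split wins; remaining ties go to the upstream-most
donor, mirroring the gap-shift convention. For reads shorter than
`short_read_threshold` (default 100 bases) only GT-AG introns are ever
called. If no junction qualifies, the chain splits and the
highest-scoring piece represents the read — consistent with reporting
only the best partial alignment.

Segments separated by 1–10 unaligned read bases trigger *gap repair*: a
donor signal is searched within `repair_window` (4) bases of the left
segment's end; if found, the matching acceptor is searched at offsets
restoring read continuity with at most one extra 1-base indel, and the
segments are trimmed or extended to the signals (the pass is repeated
acceptor-first if needed). This recovers junctions despite a
substitution or small indel near the boundary, but because it is very
sensitive, only GT-AG (CT-AC) is accepted here. The extra indel is
placed at the junction edge, adjacent to the intron.

**Pair placement.** Candidate placements of the two mates are combined;
a combination is concordant when the mates share a reference, lie on
opposite strands and start within `max_pair_distance` (default 10⁶ bases
— RNA-seq fragments can span very long introns; the method itself states
no constraint, so this is a recorded default, not inferred intent). The
concordant combination with the maximal pair score — the plain sum of
mate scores, no proper-pair bonus — is reported as primary, which is
what lets a uniquely-mapping mate disambiguate its multi-mapping
partner. Without any concordant combination the mates are reported
independently. One primary per mapped read is guaranteed; ties break by
higher score, fewer introns, then smaller coordinate. MAPQ is a
convention: 60 unique, 1 best-of-several, 0 tied. Up to `max_secondary`
(10) secondary records are emitted.

## 2. Coordinates, output, containers

All internal coordinates are 0-based half-open; SAM output is 1-based.
SAM is written as v1.6 text with `@SQ` lines, soft clips (never hard
clips, so the record keeps the full sequence), `N` operations for
introns, and `NM`/`AS` tags; records optionally sort by (reference,
position, name). BAM stays out of scope — conversion belongs to
`samtools`. The tabular format is a documented stand-in for the
BLAST-style table (query, reference, percent identity, query and
reference extents, strand, score, edit distance, intron count, edit
string); the original's exact column set is not specified anywhere, so
ours is fixed and documented rather than guessed. A small SAM text
parser is included because the evaluation functions must also consume
SAM produced by other tools, and text SAM has no reader in the R
ecosystem (Rsamtools reads BAM).

## 3. The synthetic-data generator

`simulate_genome()` draws i.i.d. bases with `P(A)+P(T)` equal to a
tunable AT fraction, up to the ~80% AT of compositionally extreme
genomes. `simulate_transcripts_and_reads()` lays multi-exon transcripts
on disjoint genome regions with random strand, writes GT-AG signals (or
a requested fraction of minor signals) at intron boundaries, and samples
single or paired reads with i.i.d. substitutions and indels
(geometric lengths, mean 1.2, capped at 3 — inside the repertoire of the
operation table; configurable). Every read records its true genome
blocks and injected edits; the truth track serialises to tab-delimited
text.

One deliberate idealisation: after writing each splice signal the
generator resamples the intron boundary neighbourhood until no
equal-or-higher-priority signal exists at a shifted offset nearby, so
the true junction is the unique top-priority placement in the resolution
window. Without this, a fraction of simulated junctions would be
genuinely ambiguous (identical aligned sequence, equal score, two
canonical placements) and "exact recovery" would be ill-defined. Real
genomes *do* contain such ambiguous junctions; passing the clean-data
tests therefore demonstrates correctness of the machinery, not that
junction calls on real data are always unique. Other realities the
generator does not emulate: transcript abundance skew, overlapping
genes and alternative splicing, position-dependent error profiles,
intron-length and signal-usage distributions of real genomes, and
fragment-length biases.

Generator defaults used throughout the tests and the acceptance script
reflect a desk-scale Illumina-like benchmark: 100+100-base pairs,
fragments ~260 bases, exons 80–300 bases, introns bounded below by 50
bases, substitution rates from 0 up to a few percent (the nominal
6–55 mismatches/kb range of published simulated benchmarks).
The clean benchmark runs 5,000 pairs against a 1 Mb genome with 200
introns — large enough for stable rates, small enough for a laptop run
of a few minutes.

## 4. Evaluation machinery

Intron discovery requires exact donor/acceptor coordinates. For each
minimal coverage 1…100 (support above 100 folds into the top bin), TP
and FP are computed over the calls at that support, giving ROC points,
precision `p = TP/(TP+FP)`, recall `r = TP/(TP+FN)` and `F = 2pr/(p+r)`,
with `F = 0` when `TP = 0` and either FP or FN is positive, and recall
`NA` on an empty truth set. TP(c) and FP(c) are non-increasing in c by
construction.

Alignment truth categories follow the asymmetric convention that an
invented exon is worse than a missing one: *exact* = completely aligned,
no mismatch or indel, blocks identical to the truth; *partial* = every
aligned block contained in the truth (same reference and strand);
*misaligned* = any aligned part outside the truth; *unmapped* otherwise.
Mismatch QC recounts mismatches base-by-base against the reference over
primary records only, reporting mismatches per kb aligned
(`1000 · mismatches / aligned bases`), the per-cycle profile, the
substitution-type table (reported as reference>read base pairs; a finer
taxonomy was left configurable) and the aligned-length histogram.

## 5. Numerical choices and degenerate inputs

* Empty read batch: explicit error. Reads shorter than the word size
  contribute no postings, with a warning.
* `word_size` is limited to 8–26 so the 2-bit word key stays exact in a
  double (52-bit mantissa).
* Chain DP tie-breaks are positional and deterministic; identical inputs
  produce byte-identical edit scripts end to end.
* The seed-extension exact run is always a single maximal run per word
  hit; adjacent word hits on one diagonal merge into one run rather than
  union across mismatches.
* Intron length is bounded to `[30, 500000]` bases by default
  (configurable) to bound the chain search; the method itself states no
  bounds.
* Whether backtracking may split one extension into two locals at an
  interior maximum is undefined in the method description; `spliceseed`
  emits one local per seed.

## 6. Test design

Every operation is checked against an independent oracle: brute-force
enumeration for postings, chains (all permutations of all subsets at
n ≤ 5) and junction offsets; Smith–Waterman (`Biostrings`) for the
greedy extension on instances whose events are isolated by at least 13
matching bases with no coincidental boundary matches — the regime the
operation table is designed for, where the greedy score provably should
reach the optimum; and from-sequence recomputation for every score and
NM tag the package emits. The DP aligner exists only in the test suite,
never in the production path. The acceptance script regenerates all
headline quantities from scratch at the benchmark scale above.

## 7. Known limitations

* Single pass, no annotation: recurrent introns are not confirmed by a
  second pass, by design.
* Exons shorter than the seed length (18) are invisible to seeding, so
  a read crossing a very short middle exon aligns as its best partial.
* Greedy extension can carry a few coincidentally matching bases past an
  exon boundary on junction-edge reads; such reads are reported as the
  best partial alignment, slightly overrunning the truth interval.
* The pair model has no insert-size distribution and no mate rescue by
  local re-alignment; concordance is purely reference/strand/distance.
* Performance: the reference scan and extension are compiled, but
  chaining, junction resolution and I/O are R; the package targets
  method study at desk scale, not production throughput on full-size
  genomes.
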