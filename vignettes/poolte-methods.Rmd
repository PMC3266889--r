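---
title: "Calling TE insertions and estimating their population frequencies from Pool-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TE insertions and estimating their population frequencies from Pool-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolte)
```

## The problem

Pooled sequencing (Pool-Seq) sequences DNA from many individuals at once and
infers allele frequencies from read counts instead of genotypes. For
transposable elements (TEs) this is attractive because a paired-end fragment
straddling an insertion junction betrays the insertion even when it is absent
from the reference genome: one read anchors in unique genomic sequence, the
mate lands in a TE. The central methodological difficulty is
*ascertainment bias*: surveys restricted to insertions annotated in a
reference genome over-sample old, high-frequency insertions. `poolte`
implements a pipeline in which insertions present in the reference
("known") and absent from it ("novel") flow through exactly the same code
path, so their frequency estimates are directly comparable.

## The combined reference and fragment classification

Reads are expected to have been mapped against a *combined reference*: the
repeat-masked genome plus the (length-filtered, >= 40 bp) TE library as
extra contigs. Masking is coordinate-preserving (`mask_from_annotation()`
replaces bases with N and records the intervals), so a read next to a known
insertion anchors in unique sequence at its true coordinate while its mate
maps to the TE contig — exactly as at a novel insertion. The package does
not include a repeat-masking engine or a mapper; it consumes their outputs
(SAM/BAM) and, for self-contained work, provides a simulator.

Each restored read pair is classified exhaustively and exclusively:

* **PRESENCE** — one read in the genome, the mate in a TE contig. The
  signal is *forward* when the genome read is on the `+` strand (insertion
  3' of it) and *reverse* otherwise. The mapping quality retained for
  filtering is the genome read's; a mapping quality against a multi-copy TE
  library is meaningless.
* **PROPER_PAIR** — both reads on one genome contig, `+` read upstream of
  the `-` read, non-overlapping: potential evidence for the *absence* of an
  insertion between them.
* **UNINFORMATIVE** — everything else (TE–TE pairs, discordant pairs,
  unmapped mates).

## Directional clustering and forward/reverse joining

Presence fragments with mapping quality >= 15 are clustered per (contig,
direction, family) by single linkage on their anchor positions: a gap of
225 bp or more splits (the threshold is the fragment size plus twice its
standard deviation, exposed as `max_gap`); clusters need >= 3 supporting
fragments. Both defaults are tunable.

A forward and a reverse cluster of the same family are then joined into one
dual-direction call. Two positions describe each cluster: the *boundary*
(the edge of the read hull nearest the insertion — last position occupied
by a forward read, first by a reverse read) and the *outer* edge of that
same junction-adjacent read. Joining tests the masked-aware distance
between the two outer edges against an inclusive window of `[74, 250]` bp.
This choice deserves a note, because it is the one place where the
geometry forces a design decision. The boundaries themselves converge on
the junction from both sides, so their separation is near zero for any
clean insertion and can never fall in a window whose lower edge is one
read length. The outer-edge distance, by contrast, is about two read
lengths plus the junction gap for a clean junction (~150–200 bp here), has
a hard floor of exactly one read length (when the two junction reads
coincide), and — because masked bases are not counted — is identical for
insertions inside and outside the reference. Every stated property of the
joining window (its floor at the read length, its ceiling near the
fragment size, its indifference to reference status) holds for this
measurement and for no other we could construct. The window bounds are
parameters (`min_dist`, `max_dist`); the 250 bp ceiling is an empirical
choice tied to the fragment-size distribution.

Positions are approximations: the midpoint of the two boundaries for
dual-direction calls, otherwise the single boundary shifted 26 bp toward
the insertion (one third of the inner mate distance, the expected gap
between the innermost read and the junction). Calls are matched to an
annotation of reference TE insertions when family matches and supporting
reads lie within an inclusive 300 bp of the annotated span; matching is
one-to-one, nearest first. The label (`known_novel`) is carried for
reporting only — no estimator branches on it, and a test asserts that
flipping the labels leaves every frequency bit-identical.

## Frequency estimation

For each called side, a tally range of at most 100 bp is anchored at the
extreme *qualifying position* of the supporting reads — the outermost
start of a forward read, the outermost end of a reverse read — and extends
away from the insertion. Presence fragments are counted when their
qualifying genome-read position falls in the range; absence fragments are
proper pairs whose corresponding read edge (start of the 5' read for
forward-side ranges, end of the 3' read for reverse-side) falls in the
same range. Using one rule for both tallies is what makes the estimator
unbiased: any fragment whose qualifying position lands in the range is
counted exactly once, as presence if its haplotype carries the insertion
and as absence if not. Truncation to 100 bp prevents fragments with
unusually large inserts from inflating the absence window.

The per-side frequency is presence / (presence + absence); sides are
combined by unweighted mean (each side is an independent assessment), with
a coverage-weighted option. Sites with total coverage below 10 are
discarded, as are sites whose ranges overlap another call's ranges (both
members removed — frequency estimates at overlapping or nested insertions
are unreliable and the survivor would be arbitrary). An insertion with
estimated frequency above 0.95 is called *fixed*.

### The missed-insertion model

Among reference insertions actually present in the pool, each side of an
insertion is detected with some probability `p`. If detection of the two
sides is independent and `p` is homogeneous, the counts of
single-direction (`n1`) and dual-direction (`n2`) identifications satisfy
`n1 = 2p(1-p)nT` and `n2 = p^2 nT`, giving `p = 2n2/(n1 + 2n2)`,
`nT = n2/p^2`, and `n0 = nT - n1 - n2` insertions present but missed
entirely. `solve_detection_model()` inverts the model in closed form (kept
at full precision, rounded only for reporting);
`solve_detection_model_by_order()` applies it per TE order, since `p`
plausibly differs between orders.

## The sweep scan

Windowed Tajima's D is computed from a samtools text pileup. Calls with
base quality below 20 are dropped; positions with remaining depth above
250 are rejected as suspect; every surviving position is subsampled
without replacement to a uniform 30 calls, which are then treated as 30
sampled chromosomes under the classic Tajima (1989) estimators. The
pooled-specific variance corrections developed for Pool-Seq estimators are
deliberately *not* applied: the subsample-to-n-then-classic route is the
procedure this pipeline defines, and the subsample size, not the raw
depth, is the sample size. Windows are non-overlapping, 500 bp for D and
2,500 bp for diversity; a window is valid only if every position in it was
subsampled (a lenient mode exists but is off by default). D is undefined
when a window has no segregating sites. Segregating sites are counted
reference-free with a minimum non-major allele count of one.

Thresholds are the lower empirical (type-1) quantile (default 5%) of the
defined D values among valid windows, computed separately for the X
chromosome and the autosomes (their effective population sizes differ);
they are data products, not constants. A candidate positively selected
insertion must be fixed (frequency > 0.95), lie in a normally recombining
region (rate >= 1 cM/Mb; low-recombination runs are classed
centromere-proximal or telomere-proximal by which chromosome end they
touch), come from a family not flagged ancient (INE-1 by default — an
ancient family whose insertions predate any recent sweep), and have a
defined D below the threshold in the window containing it or an
immediately adjacent window (offsets -1, 0, +1; D at -2..+2 is reported
for context). Feature annotation prioritises stronger functional
constraint: CDS > 5'-UTR > 3'-UTR > exon > ncRNA > regulatory > intron >
intergenic.

## The simulator

`simulate_reference_and_library()`, `simulate_pool()` and
`simulate_pileup()` make every stage testable without external data. The
pool is modelled at the haplotype level: 226 haplotypes by default
(emulating a pool of 113 isofemale lines, two genomes each), each carrying
every configured insertion independently with its population frequency.
Fragments have normally distributed length (mean 225 bp, sd 15 bp) with
74 bp reads, are budgeted by mean haplotype length and drawn proportional
to haplotype length so that *physical coverage* holds per sequenced base.
Emitted alignments are truth alignments: a read overlapping an insertion
junction is assigned to the side holding the majority of its bases and
clipped at the junction, the way a local aligner resolves such reads.
In-reference insertions are spliced into the emitted reference (so known
insertions exist with annotated spans and the masked-genome version is
derivable); the coordinate bookkeeping maps every read to combined
reference coordinates, including proper pairs that span a masked span on
non-carrier haplotypes.

The pileup simulator draws neutral minor-allele counts from the
equilibrium spectrum (probability proportional to 1/k over the pool's
haplotypes) and binomial read counts — haplotypes sampled with
replacement, as pooled sequencing does. Inside configured sweep regions
the spectrum is pushed toward singletons, which drives windowed D
negative. What the simulator does *not* model: sequencing errors in
alignments, mapping ambiguity, indels, within-line inbreeding structure,
coalescent linkage between sites, or nested/clustered insertions. Passing
tests therefore demonstrate the pipeline's correctness under its own
assumptions, not robustness to mapper artefacts on real libraries.

## Numerical and scale choices

All internal coordinates are 0-based half-open; conversion to 1-based
SAM/GFF/pileup conventions happens only at I/O boundaries. Clustering uses
a strict gap comparison (a gap of exactly `max_gap` splits); the joining
window and the 300 bp annotation match are inclusive; the 10-fold coverage
filter is strict ("fewer than 10"), summed over both sides (a per-side
reading exists in the field; the summed one is the default and the flag to
change it is `min_coverage` applied to the summed column). F/R joining and
annotation matching break ties deterministically toward the smaller
coordinate, so all results are invariant to input order.

Test problem sizes were chosen to exercise the statistics at meaningful
scale while staying desk-sized: 200 simulated insertions (100 known/novel
pairs at matched frequencies uniform on [0.05, 1]) at 35-fold physical
coverage — which puts the mean per-site tally coverage near 31-fold, the
regime this design targets — for parameter recovery and side concordance;
500 neutral 500 bp windows for the Tajima's D calibration; an 80-site
two-frequency contrast (2% vs 20%) for the detection floor. At ~31-fold
site coverage, insertions below roughly 5–10% frequency rarely reach three
supporting fragments on either side, so their recall collapses — the
detection floor is a property of the coverage, not a bug, and deeper
sequencing raises it.

## Known limitations

Nested and clustered insertions are invisible by construction (their
tally ranges overlap and are filtered). Position estimates are
approximations, not breakpoints. Fixed sites can attract a small number of
false absence fragments (reads mis-spanning a junction), slightly
depressing frequency estimates near 1. The detection model assumes a
homogeneous `p` within each group it is applied to. The Tajima's D route
inherits the extra sampling noise of reads-from-pool versus
individuals-from-population; at subsample size 30 from 226 haplotypes this
bias is small (the neutral simulation centres within ±0.15 of zero) but it
is not zero.
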