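---
title: "Processing and visualizing pairwise whole-genome alignments"
author: "SyntenyViews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and visualizing pairwise whole-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SyntenyViews)
```

# The problem

Raw whole-genome pairwise alignments — whether produced by BLAST, by
LASTZ/chaining pipelines, or imported from public chain dumps — are noisy
representations of the orthology relation between two assemblies. The same
genomic region is typically covered by many short, partially overlapping,
partially redundant alignment segments; repeats generate contained
duplicates; and genuine biological duplications put one query region in
correspondence with several target regions. Before such alignments can be
displayed as a synteny map, or used to project annotation from one assembly
onto the other, they must be consolidated into a ranked set in which each
base has one *best* placement and additional placements are explicitly
flagged as secondary.

`SyntenyViews` implements that second-phase consolidation as an offline
library plus command-line tool: readers for the three raw formats (PAF,
UCSC chain, tabular BLAST), the merge/split/rank/reciprocity algorithm, a
MinHash (Mash) distance module that recommends aligner parameters for a
genome pair, coverage statistics, static SVG ideogram and dotplot views,
and a simulator that generates genome pairs with planted rearrangements
and exact ground truth.

# Data model and conventions

All coordinates inside the package are **0-based, half-open, on the
forward strand** of both sequences; orientation is a per-segment flag.
Reverse-strand coordinates in the input formats (chain `qStrand -`
counted from the sequence end, BLAST `sstart > send`) are normalized at
the I/O boundary, and display output (GFF3, tables, info panels) converts
to 1-based closed coordinates at the boundary in the other direction.

An `AlignmentSegment` stores its **ungapped blocks**: maximal runs of
aligned columns, matches *and* mismatches alike. Between consecutive
blocks there may be a query-side gap, a target-side gap, or both. Two
consequences of this definition are worth stating:

* a CIGAR run such as `50=2X` is a single 52-column block, because no gap
  interrupts the aligned columns;
* coverage statistics count block bases, not segment envelopes, so
  internal gaps never inflate coverage.

**Percent identity** is reported with the alignment-column convention,

$$\mathrm{pid} = 100 \cdot \frac{\text{matches}}
{\text{matches} + \text{mismatches} + \text{gap bases}},$$

i.e. gapped columns count against identity. Public viewers report
identity, gaps and mismatches jointly without fixing a formula; since the
choice is not externally determined, it is stated here and in the CLI
help. **Alignment length**, wherever the package reports one, is the
query-span length of the segment.

Segments parsed from PAF lines without a `cg:` CIGAR, or BLAST rows with
gaps but no `btop` column, carry no per-column detail. They are accepted
as single-diagonal-block segments flagged `lowres`; every downstream
operation works on them, but gap splitting degrades to whole-segment
granularity (there are no junctions to split at). This is logged once per
file.

# The consolidation pipeline

`processAlignments()` composes seven stages; each is exported separately
so intermediate states can be inspected.

1. **Canonical pre-sort.** The input is ordered by (query sequence, query
   start, target sequence, target start, orientation). Every later stage
   is deterministic given its input order, so the pipeline as a whole is
   invariant under permutations of its input — a property the test suite
   asserts directly.

2. **Merge adjacent** (`mergeAdjacent`). Two segments merge when they lie
   on the same sequence pair with the same orientation, are collinear,
   both intervening gaps are at most `mergeMaxGap`, and no third segment
   overlaps either intervening interval ("no conflicting alignments").
   Matches and mismatches are summed — statistics are never recomputed
   from sequence, because phase two deliberately never reads sequence —
   and the junction gaps join the merged segment's gap account. Applied
   to a fixpoint.

3. **Split on large gaps** (`splitOnGaps`). At each junction the gap
   length is `max(query gap, target gap)`; a segment splits wherever that
   gap reaches `min(gapSplitBp, gapSplitFrac × alignment length)`. The
   defaults are the published operating points: 50 bp absolute for
   same-or-closer species, 50 kb for distant species, 5% fractional in
   both modes, with the fraction evaluated on the pre-split query span.
   The source procedure lists the three criteria without stating how they
   combine; taking the minimum makes each criterion an upper bound on the
   other, which is the only combination under which both quoted
   thresholds can ever bind. Children inherit match statistics
   proportionally to their aligned columns with largest-remainder
   rounding, so matched bases are conserved exactly.

4. **Split at overlaps** (`splitAtOverlaps`). Wherever two segments
   overlap on the query or on the target, both are cut at the overlap
   boundaries, iterating to a fixpoint, so that on each axis any two
   segments are afterwards either range-identical or disjoint. Cuts
   between blocks fall at the junction; cuts inside a block bisect it
   exactly. No aligned base is created or destroyed.

5. **Drop contained duplicates** (`dropContained`). A segment is removed
   when both its ranges are contained in a single strictly higher-ranked
   segment of the same orientation and sequence pair; exact duplicates
   keep their first representative in rank order.

6. **Rank and assign reciprocity** (`rankSort`, `assignReciprocity`).
   The rank key is: assembly-level class (chromosome placements on both
   sides beat chromosome-on-one, which beats neither — sequences missing
   from the catalogue default to chromosome with a warning), then percent
   identity, then alignment length, then coordinates as a deterministic
   tie-break. Ranking by shared underlying sequence components is *not*
   modelled: component-level metadata (shared clone/BAC provenance) is an
   archive-internal resource with no public equivalent. The ranked
   segments are then scanned twice, once per axis: a segment is
   *query-best* iff no higher-ranked segment overlaps it on the query,
   and likewise *target-best* on the target. Reciprocity **3** marks
   segments best on both axes (reciprocal best-placed, "first pass");
   **1** query-side best only; **2** target-side best only ("second
   pass"). The source material never states which one-sided code is
   which, so the assignment here is a documented package convention.
   Segments best on neither axis are discarded and counted — they are
   redundant copies wholly dominated by better placements.

7. **Re-merge per reciprocity class** (`remerge`). `mergeAdjacent` runs
   again independently within each reciprocity class, stitching the
   fragments back into the longest representative stretches. Because the
   pipeline ends with a merge, re-processing its own output reproduces it
   (idempotence), even though a merge of short segments mid-pipeline can
   transiently be undone by the fractional gap-split rule.

Within the reciprocity-3 set, segments are pairwise non-overlapping on
the query *and* on the target — each base has at most one best placement.
The suite checks this exclusivity on every random instance, and checks
the reciprocity-3 set against an independent greedy oracle that claims
query and target intervals in rank order; on overlap-split input (where
same-axis overlaps are range-identical) the two formulations provably
coincide.

# Distance-based aligner recommendation

`sketchSequences()` builds a bottom-$s$ MinHash sketch of the canonical
$k$-mers (minimum of a 2-bit-encoded $k$-mer and its reverse complement)
with defaults $k = 21$, $s = 1000$ — the published defaults of the Mash
method. Hashing is a splitmix-style 64-bit finalizer with a fixed seed,
truncated to 53 bits so hash values stay exact in R doubles.
`mashDistance()` estimates Jaccard similarity $j$ from the bottom-$s$
sketch of the merged hash sets and returns

$$d = -\frac{1}{k}\,\ln\frac{2j}{1+j},$$

with $d = 0$ at $j = 1$ and a saturation value of 1 at $j = 0$.

`recommendAligner()` encodes the published operating rules keyed to that
distance: same-species pairs use BLAST (`word_size` 28, WindowMasker
`t_thres_pct` 99.5); cross-species pairs use BLAST `word_size` 28 below
$d = 0.05$ and 16 from 0.05 to 0.1 (`t_thres_pct` 98.5); pairs past 0.1
use LASTZ (`t_thres_pct` 97.5); past 0.3 no aligner is recommended, as
whole-genome alignment is likely uninformative at that distance.
Boundaries are left-closed ($d = 0.05 \to 16$, $d = 0.1 \to$ LASTZ), and
the advisory threshold is strictly greater than 0.3. The HoxD55
substitution-matrix note is attached for $d \ge 0.25$ — "most distant
pairs" is not quantified at the source, and 0.25 marks the upper portion
of the LASTZ band where alignments become sparse. Sketching parameters
for any published distance values are unstated, so cross-tool numeric
agreement with specific published distances is not claimed.

# Coverage statistics

`genomeCoverage()` reports the fraction of target-genome nucleotides
under the union of ungapped blocks (interval union, no double counting);
`cdsCoverage()` intersects that union with the union of all CDS intervals
— isoforms are merged first, so shared exons count once. Both accept a
reciprocity filter; best-only coverage is necessarily no larger than
all-reciprocity coverage, which the suite asserts as a monotonicity
property.

# Rendering

Both views are pure functions from a `SyntenyScene` to an SVG string —
identical scenes give byte-identical documents, which makes the "flip a
chromosome twice restores the image exactly" contract testable at the
byte level. The ideogram draws reciprocal best hits only unless
`includeNonBest` is set; the dotplot always draws all reciprocities
(duplications are precisely what it is for), with forward alignments as
positive-slope green lines and reverse alignments as negative-slope
purple lines. Size and orientation filters apply to both views. Connector
colors are keyed to the target chromosome with a fixed categorical
palette; the exact palette of any public viewer is unpublished, so any
fixed deterministic palette satisfies the display contract. Chromosomes
are ordered by natural sort of their names.

# The simulator

`simulatePair()` models the target genome as an ordered list of tiles
copied from a uniformly random query genome. Events edit the tile list —
inversion flips tile orientation in place, translocation and duplication
move or copy tiles across chromosomes, scramble shuffles a chromosome's
tiles, deletion removes them — and mutation is applied per tile while the
block structure is tracked, so the returned truth segments are exact by
construction, not re-estimated.

Defaults, chosen once as a realistic within-genus comparison and used by
the end-to-end validation: five 1 Mb chromosomes; one 100 kb inversion,
one 80 kb translocation, one 40 kb duplication, one chromosome scrambled
into 20 tiles; SNP rate 0.005; indel rate $10^{-4}$ with lengths 1–10 bp.
Indels are kept below the 50 bp split threshold so that ground truth
remains a tiling and recovery is measurable as a simple base fraction.
`fragmentAlignments()` then cuts the truth into pieces (200 cuts at full
scale), injects 10% overlapping redundant pieces and 10% contained
duplicates, and shuffles — the adversarial raw input the pipeline must
clean up. The end-to-end criterion asks `processAlignments()` to recover
at least 95% of truth matched bases in the reciprocity-3 set, to confine
reverse-orientation output to a single cluster at the inversion locus,
and to expose the duplication as a non-best segment.

What the simulator deliberately does **not** model: repeat families, GC
skew, realistic indel length spectra, segmental-duplication mosaics, or
polyploid subgenomes. Phase two never reads sequence, so these omissions
do not weaken the algorithmic tests; they do mean that passing tests
bound algorithm correctness, not alignment quality on real genomes —
phase one (the aligners themselves) is outside this package's scope.

# Numerical and degenerate-input choices

* Splitting allocates matched columns to children by largest-remainder
  rounding; totals are conserved exactly, which the conservation suite
  asserts over a random corpus.
* `merge_max_gap` defaults to the gap-split threshold, so merging never
  bridges a gap that splitting would immediately re-open at full scale.
* Empty inputs are legal everywhere: an empty PAF processes to an empty,
  header-only GFF3; an empty post-filter scene renders a valid SVG with a
  caption and a logged warning; an empty CDS set is an error (undefined
  coverage) rather than a silent 0.
* Ties in ranking are broken lexicographically by coordinates, making
  every pipeline stage deterministic; randomness exists only in the
  simulator and is fully seed-driven.
* Problem sizes in the test suite: 500 random instances of up to 10
  segments for the oracle comparison, a 300-instance corpus for the
  conservation and exclusivity laws, and one full 5 × 1 Mb scenario for
  end-to-end recovery.

# Known limitations

* Common-component merging and ranking (shared clone provenance between
  assemblies of the same species) is out of scope, as is running the
  aligners, WindowMasker, or chainNet themselves.
* The XLSX export writes a minimal single-sheet workbook (verified
  against openpyxl); it does not style cells or stream very large sets.
* Identity of merged segments is the weighted combination of its parts;
  no realignment is attempted.
* The reciprocity-code orientation (1 = query-best, 2 = target-best) is a
  package convention; consumers comparing against other tools should
  check codes 1 and 2 jointly, as the acceptance checks here do.
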