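# SyntenyViews

Post-processing and visualization of pairwise whole-genome assembly
alignments, for researchers comparing genome structure between two
assemblies — same-species assembly updates, cross-species synteny,
inversions, translocations and duplications.

Raw whole-genome alignments (from BLAST, LASTZ/chaining pipelines, or
public chain dumps) cover the same regions with many short, overlapping,
partially redundant segments. `SyntenyViews` consolidates them into a
ranked alignment set in which every base has at most one *reciprocal
best* placement, and renders the result as synteny ideograms and
dotplots.

## The algorithm at its core

Given raw alignment segments between a query and a target assembly, the
pipeline runs:

1. **merge** adjacent collinear segments when no conflicting alignment
   overlaps the intervening gaps (gap ≤ 50 bp by default);
2. **split on gaps**: a segment is cut at every junction whose gap
   (max of query- and target-side) reaches
   `min(gap_split_bp, 0.05 × alignment length)` — 50 bp for
   same-or-closer species, 50 kb for distant species;
3. **split at overlaps**, so that on each axis any two segments are
   range-identical or disjoint;
4. **drop** duplicates and low-quality segments contained in a single
   higher-ranked segment;
5. **rank** by assembly level (chromosome placements preferred over
   unplaced scaffolds), percent identity
   `100·matches/(matches+mismatches+gap_bases)`, and alignment length;
6. **two scans** — once over query ranges, once over target ranges —
   assign reciprocity: **3** = best on both axes (reciprocal
   best-placed), **1** = query-side best only, **2** = target-side best
   only; segments best on neither are discarded;
7. **re-merge** within each reciprocity class into the longest
   representative stretches.

Within the reciprocity-3 set, segments never overlap on either axis.

A MinHash module estimates the Mash distance
`d = −ln(2j/(1+j))/k` between two genomes (k = 21, sketch size 1000) and
recommends aligner parameters: BLAST `word_size` 28 below d = 0.05,
`word_size` 16 from 0.05 to 0.1, LASTZ above 0.1 (WindowMasker
`t_thres_pct` 99.5 / 98.5 / 97.5 for same-species BLAST / cross-species
BLAST / LASTZ), and an advisory past d = 0.3 that whole-genome alignment
is likely uninformative.

## Worked example

Simulate a 2 × 50 kb genome pair carrying a 10 kb inversion on
chromosome 2, fragment the truth into adversarial raw input (30 cuts,
10% redundant overlaps, 10% contained duplicates), and consolidate:

```r
library(SyntenyViews)

plan <- RearrangementPlan(seed = 11, nChromosomes = 2,
  chromosomeLength = 50000,
  events = data.frame(type = "inversion", chrom = 2, start = 15000,
                      size = 10000, dest_chrom = NA),
  snpRate = 0.005, indelRate = 1e-4)
sim    <- simulatePair(plan)
frags  <- fragmentAlignments(sim$truth, seed = 11, nCuts = 30,
                             overlapFraction = 0.1, duplicateFraction = 0.1)
ranked <- processAlignments(frags, sim$queryInfo, sim$targetInfo)
```

The stage log (standard error) shows the consolidation:

```
input=41 merged=17 gap_split=17 overlap_split=36 contained_dropped_to=24
reciprocity_kept=24 best_on_neither_discarded=0 remerged=4
```

and the ranked set recovers the planted structure — chromosome 1 intact,
chromosome 2 in three stretches with the inversion as a single
reverse-orientation reciprocal-best segment at 15,001–25,000:

```r
as.data.frame(ranked)
#>   query_seq query_start query_end target_seq target_start target_end
#> 1        Q1           1     50000         T1            1      50008
#> 2        Q2           1     15000         T2            1      15000
#> 3        Q2       15001     25000         T2        15001      24999
#> 4        Q2       25001     50000         T2        25000      49996
#>   orientation pct_identity reciprocity
#> 1     forward      99.4144           3
#> 2     forward      99.4200           3
#> 3     reverse      99.5800           3
#> 4     forward      99.3561           3

genomeCoverage(ranked, sim$targetInfo, reciprocityFilter = 3L)
#> [1] 99.96663
```

Coordinates are displayed 1-based inclusive; identities are slightly
below 100 because of the simulated SNPs and indels. Export and render:

```r
writeGFF3(ranked, "pair.gff3")
writeAlignmentTable(ranked, "pair.tsv", "tsv")
writeSVG(renderIdeogram(SyntenyScene(ranked)), "ideogram.svg")
writeSVG(renderDotplot(SyntenyScene(ranked)), "dotplot.svg")
```

Parameter recommendation for a cross-species pair at Mash distance 0.07:

```r
recommendAligner(0.07, sameSpecies = FALSE)
#> AlignerRecommendation (Mash distance 0.07)
#>   WindowMasker t_thres_pct: 98.5
#>   blastn -evalue 0.0001 -gapextend 1 -gapopen 2 -max_target_seqs 250
#>     -soft_masking true -task megablast -window_size 150 -word_size 16
```

The same operations are exposed as a CLI
(`inst/scripts/synteny-views`), with subcommands `process`, `ideogram`,
`dotplot`, `coverage`, `dist`, `recommend`, `simulate` and `info`.

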