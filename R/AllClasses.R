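#' @useDynLib SyntenyViews, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail read.delim write.table
NULL

## Internal coordinate convention: 0-based, half-open, forward strand on both
## sequences. Orientation is a segment-level flag; reverse-strand input
## coordinates (chain qStrand "-", BLAST sstart > send) are normalized at the
## I/O boundary.

#' SeqRange: a half-open interval on one assembly sequence
#'
#' Coordinates are 0-based, half-open (`start` inclusive, `end` exclusive),
#' always on the forward strand.
#'
#' @slot seqId sequence accession.
#' @slot start,end base offsets, `0 <= start < end`.
#' @slot assemblyId assembly accession ("" when unknown).
#' @export
setClass("SeqRange",
  representation(seqId = "character", start = "numeric", end = "numeric",
                 assemblyId = "character"),
  prototype(assemblyId = ""))

setValidity("SeqRange", function(object) {
  if (length(object@seqId) != 1L || !nzchar(object@seqId))
    return("seqId must be a single non-empty string")
  if (object@start < 0 || object@start >= object@end)
    return("require 0 <= start < end")
  TRUE
})

#' Construct a SeqRange
#'
#' @param seqId sequence accession.
#' @param start,end 0-based half-open interval bounds.
#' @param assemblyId optional assembly accession.
#' @return A [SeqRange-class] object.
#' @examples
#' SeqRange("chr1", 0, 100)
#' @export
SeqRange <- function(seqId, start, end, assemblyId = "") {
  new("SeqRange", seqId = as.character(seqId), start = as.numeric(start),
      end = as.numeric(end), assemblyId = as.character(assemblyId))
}

#' AlignmentSegment: one pairwise alignment between two assemblies
#'
#' The atom of the pipeline. A segment aligns a query range to a target
#' range in a single orientation and stores its ungapped block structure
#' (maximal runs of aligned columns) plus alignment statistics.
#'
#' Blocks are stored as a numeric matrix with columns `qstart`, `tstart`,
#' `length`, ordered by query start. Both block coordinate columns are
#' forward-strand; for a reverse-orientation segment target starts decrease
#' as query starts increase, and within a block query base `qstart + i`
#' pairs with target base `tstart + length - 1 - i`.
#'
#' @slot qname,tname query/target sequence accessions.
#' @slot qstart,qend,tstart,tend 0-based half-open spans.
#' @slot qassembly,tassembly assembly accessions ("" when unknown).
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot blocks ungapped block matrix (see Details).
#' @slot matches,mismatches aligned-column counts; their sum equals the
#'   total block length.
#' @slot gapCount number of gap openings.
#' @slot gapBases total unaligned bases inside the segment span.
#' @slot sourceId provenance string.
#' @slot lowres `TRUE` when the input format carried no per-column
#'   alignment detail (PAF without `cg:`, BLAST rows without `btop` that
#'   contain gaps); the block structure is then a single diagonal block and
#'   gap splitting degrades to whole-segment granularity.
#' @export
setClass("AlignmentSegment",
  representation(qname = "character", qstart = "numeric", qend = "numeric",
                 tname = "character", tstart = "numeric", tend = "numeric",
                 qassembly = "character", tassembly = "character",
                 orientation = "character", blocks = "matrix",
                 matches = "numeric", mismatches = "numeric",
                 gapCount = "numeric", gapBases = "numeric",
                 sourceId = "character", lowres = "logical"),
  prototype(qassembly = "", tassembly = "", orientation = "forward",
            matches = 0, mismatches = 0, gapCount = 0, gapBases = 0,
            sourceId = "", lowres = FALSE))

setValidity("AlignmentSegment", function(object) {
  b <- object@blocks
  if (!is.numeric(b) || ncol(b) != 3L)
    return("blocks must be a numeric matrix with columns qstart,tstart,length")
  if (nrow(b) < 1L) return("segment needs at least one block")
  if (any(b[, 3L] <= 0)) return("block lengths must be positive")
  if (!object@orientation %in% c("forward", "reverse"))
    return("orientation must be 'forward' or 'reverse'")
  if (is.unsorted(b[, 1L], strictly = TRUE) && nrow(b) > 1L)
    return("blocks must be sorted by query start")
  if (nrow(b) > 1L) {
    qe <- b[, 1L] + b[, 3L]
    if (any(b[-1L, 1L] < qe[-nrow(b)]))
      return("blocks overlap on the query")
    if (object@orientation == "forward") {
      te <- b[, 2L] + b[, 3L]
      if (any(b[-1L, 2L] < te[-nrow(b)]))
        return("forward blocks must ascend on the target")
    } else {
      if (any(b[-nrow(b), 2L] < b[-1L, 2L] + b[-1L, 3L]))
        return("reverse blocks must descend on the target")
    }
  }
  if (!object@lowres) {
    if (object@qstart != min(b[, 1L]) ||
        object@qend != max(b[, 1L] + b[, 3L]))
      return("query span must equal the block envelope")
    if (object@tstart != min(b[, 2L]) ||
        object@tend != max(b[, 2L] + b[, 3L]))
      return("target span must equal the block envelope")
  }
  if (object@matches + object@mismatches != sum(b[, 3L]))
    return("matches + mismatches must equal total block length")
  if (object@matches < 0 || object@mismatches < 0 ||
      object@gapBases < 0 || object@gapCount < 0)
    return("statistics must be non-negative")
  TRUE
})

#' AssemblyInfo: per-assembly sequence catalogue
#'
#' @slot assemblyId assembly accession.
#' @slot assemblyName display name.
#' @slot seqs data.frame with columns `seq_id`, `length`, `role`
#'   (`"chromosome"` or `"unplaced_scaffold"`).
#' @export
setClass("AssemblyInfo",
  representation(assemblyId = "character", assemblyName = "character",
                 seqs = "data.frame"),
  prototype(assemblyName = ""))

setValidity("AssemblyInfo", function(object) {
  s <- object@seqs
  if (!all(c("seq_id", "length", "role") %in% names(s)))
    return("seqs needs columns seq_id, length, role")
  if (anyDuplicated(s$seq_id)) return("duplicate seq_ids in assembly")
  if (any(s$length <= 0)) return("sequence lengths must be positive")
  if (!all(s$role %in% c("chromosome", "unplaced_scaffold")))
    return("role must be 'chromosome' or 'unplaced_scaffold'")
  TRUE
})

#' Construct an AssemblyInfo
#'
#' @param assemblyId assembly accession.
#' @param seqIds sequence accessions.
#' @param lengths sequence lengths in bases.
#' @param roles `"chromosome"` (default) or `"unplaced_scaffold"`, recycled.
#' @param name display name.
#' @return An [AssemblyInfo-class] object.
#' @examples
#' AssemblyInfo("asm1", c("chr1", "chr2"), c(1e6, 5e5))
#' @export
AssemblyInfo <- function(assemblyId, seqIds, lengths, roles = "chromosome",
                         name = assemblyId) {
  new("AssemblyInfo", assemblyId = as.character(assemblyId),
      assemblyName = as.character(name),
      seqs = data.frame(seq_id = as.character(seqIds),
                        length = as.numeric(lengths),
                        role = rep_len(as.character(roles), length(seqIds)),
                        stringsAsFactors = FALSE))
}

#' ProcessingParams: thresholds of the second-phase algorithm
#'
#' @slot speciesMode `"same_or_close"` or `"distant"`.
#' @slot gapSplitBp absolute gap-split threshold in bases (50 for
#'   same-or-closer species, 50,000 for distant species).
#' @slot gapSplitFrac fractional gap-split threshold (default 0.05 of the
#'   alignment's query-span length).
#' @slot mergeMaxGap maximum intervening gap merged across (defaults to
#'   `gapSplitBp`).
#' @export
setClass("ProcessingParams",
  representation(speciesMode = "character", gapSplitBp = "numeric",
                 gapSplitFrac = "numeric", mergeMaxGap = "numeric"))

setValidity("ProcessingParams", function(object) {
  if (!object@speciesMode %in% c("same_or_close", "distant"))
    return("speciesMode must be 'same_or_close' or 'distant'")
  if (object@gapSplitBp <= 0) return("gapSplitBp must be positive")
  if (object@gapSplitFrac <= 0 || object@gapSplitFrac >= 1)
    return("gapSplitFrac must be in (0, 1)")
  if (object@mergeMaxGap < 0) return("mergeMaxGap must be non-negative")
  TRUE
})

#' Construct ProcessingParams
#'
#' Defaults follow the species-proximity mode: a 50 bp absolute gap-split
#' threshold for same-or-closer species, 50 kb for distant species, and a
#' 5\% fractional threshold in both modes. The effective split threshold at
#' a junction is `min(gapSplitBp, gapSplitFrac * alignment length)`.
#'
#' @param speciesMode `"same_or_close"` (default) or `"distant"`.
#' @param gapSplitBp,gapSplitFrac,mergeMaxGap overrides of the defaults.
#' @return A [ProcessingParams-class] object.
#' @examples
#' ProcessingParams("distant")
#' @export
ProcessingParams <- function(speciesMode = c("same_or_close", "distant"),
                             gapSplitBp = NULL, gapSplitFrac = 0.05,
                             mergeMaxGap = NULL) {
  speciesMode <- match.arg(speciesMode)
  if (is.null(gapSplitBp))
    gapSplitBp <- if (speciesMode == "same_or_close") 50 else 50000
  if (is.null(mergeMaxGap)) mergeMaxGap <- gapSplitBp
  new("ProcessingParams", speciesMode = speciesMode,
      gapSplitBp = as.numeric(gapSplitBp),
      gapSplitFrac = as.numeric(gapSplitFrac),
      mergeMaxGap = as.numeric(mergeMaxGap))
}

#' RankedAlignmentSet: segments with reciprocity codes
#'
#' Output of [assignReciprocity()] / [processAlignments()]. Reciprocity 3
#' ("first pass") marks reciprocal best-placed segments, best on both the
#' query and the target scan; 1 marks query-side best only and 2 marks
#' target-side best only ("second pass"). Segments best on neither axis are
#' discarded and counted in `dropped`.
#'
#' @slot segments list of [AlignmentSegment-class].
#' @slot reciprocity integer vector (3, 2 or 1), parallel to `segments`.
#' @slot queryInfo,targetInfo [AssemblyInfo-class] or NULL.
#' @slot dropped number of segments best on neither axis.
#' @slot stageLog named numeric vector of per-stage segment counts.
#' @export
setClass("RankedAlignmentSet",
  representation(segments = "list", reciprocity = "integer",
                 queryInfo = "ANY", targetInfo = "ANY",
                 dropped = "numeric", stageLog = "numeric"),
  prototype(queryInfo = NULL, targetInfo = NULL, dropped = 0,
            stageLog = numeric(0)))

setValidity("RankedAlignmentSet", function(object) {
  if (length(object@segments) != length(object@reciprocity))
    return("segments and reciprocity lengths differ")
  if (length(object@reciprocity) &&
      !all(object@reciprocity %in% 1:3))
    return("reciprocity codes must be 1, 2 or 3")
  TRUE
})

#' Sketch: a MinHash bottom-s sketch of a sequence set
#'
#' @slot k k-mer size.
#' @slot s sketch size (maximum number of retained hashes).
#' @slot hashes ascending distinct hash values of canonical k-mers.
#' @export
setClass("Sketch",
  representation(k = "numeric", s = "numeric", hashes = "numeric"))

setValidity("Sketch", function(object) {
  if (object@k < 1 || object@s < 1) return("k and s must be >= 1")
  if (length(object@hashes) > object@s)
    return("more hashes than sketch size")
  if (is.unsorted(object@hashes, strictly = TRUE) &&
      length(object@hashes) > 1L)
    return("hashes must be strictly ascending")
  TRUE
})

#' AlignerRecommendation: aligner and parameters for an assembly pair
#'
#' @slot aligner `"BLAST"`, `"LASTZ"` or `"none"`.
#' @slot wordSize BLAST word size (NA unless aligner is BLAST).
#' @slot tThresPct WindowMasker `t_thres_pct` (99.5, 98.5 or 97.5).
#' @slot matrixNote `"HoxD55"` for the most distant LASTZ pairs, else NA.
#' @slot mashDistance the distance the recommendation was made for.
#' @slot advisory advisory text (alignment likely uninformative past
#'   distance 0.3), or NA.
#' @export
setClass("AlignerRecommendation",
  representation(aligner = "character", wordSize = "numeric",
                 tThresPct = "numeric", matrixNote = "character",
                 mashDistance = "numeric", advisory = "character"))

#' SyntenyScene: a filtered, oriented view of a ranked alignment set
#'
#' Holds everything the renderers need: the ranked alignments, both
#' assembly catalogues, display filters, flipped chromosomes, an optional
#' zoom viewport and optional gene annotation.
#'
#' @slot ranked [RankedAlignmentSet-class].
#' @slot queryInfo,targetInfo [AssemblyInfo-class].
#' @slot minSegmentLength size filter in bases (query-span length).
#' @slot orientationFilter `"all"`, `"forward_only"` or `"reverse_only"`.
#' @slot includeNonBest show reciprocity 1/2 segments in the ideogram
#'   (default FALSE: reciprocal best hits only). The dotplot always shows
#'   all reciprocities.
#' @slot flippedSequences seq ids drawn reversed in the ideogram.
#' @slot viewport NULL, or list(query =, target =) of [SeqRange-class]
#'   restricting the view to one chromosome pair region.
#' @slot genes NULL, or list with optional `query`/`target` GRanges of gene
#'   features (metadata column `gene_name`).
#' @export
setClass("SyntenyScene",
  representation(ranked = "RankedAlignmentSet", queryInfo = "AssemblyInfo",
                 targetInfo = "AssemblyInfo", minSegmentLength = "numeric",
                 orientationFilter = "character", includeNonBest = "logical",
                 flippedSequences = "character", viewport = "ANY",
                 genes = "ANY"),
  prototype(minSegmentLength = 0, orientationFilter = "all",
            includeNonBest = FALSE, flippedSequences = character(0),
            viewport = NULL, genes = NULL))

setValidity("SyntenyScene", function(object) {
  if (!object@orientationFilter %in% c("all", "forward_only", "reverse_only"))
    return("orientationFilter must be all/forward_only/reverse_only")
  if (!is.null(object@viewport)) {
    v <- object@viewport
    if (!is.list(v) || !all(c("query", "target") %in% names(v)))
      return("viewport must be list(query=, target=) of SeqRange")
    for (side in c("query", "target")) {
      r <- v[[side]]
      if (!is(r, "SeqRange")) return("viewport entries must be SeqRange")
      info <- if (side == "query") object@queryInfo else object@targetInfo
      len <- seqLength(info, r@seqId)
      if (is.na(len)) return(sprintf("viewport %s sequence unknown", side))
      if (r@end > len) return("viewport exceeds sequence length")
    }
  }
  TRUE
})

#' RearrangementPlan: recipe for a simulated genome pair
#'
#' The defaults describe the standard validation scenario: five 1 Mb
#' chromosomes carrying one 100 kb inversion, one 80 kb translocation, one
#' 40 kb duplication and one chromosome scrambled into 20 shuffled tiles,
#' with a SNP rate of 0.005 and an indel rate of 1e-4 (indel lengths 1-10
#' bp, below the 50 bp gap-split threshold).
#'
#' @slot seed integer seed driving all randomness.
#' @slot nChromosomes,chromosomeLength genome shape.
#' @slot events data.frame with columns `type` (inversion, translocation,
#'   duplication, scramble, deletion), `chrom` (1-based index), `start`
#'   (0-based offset), `size` (bases; for scramble: number of tiles),
#'   `dest_chrom` (NA except translocation/duplication).
#' @slot snpRate,indelRate per-base mutation rates in [0, 1).
#' @export
setClass("RearrangementPlan",
  representation(seed = "numeric", nChromosomes = "numeric",
                 chromosomeLength = "numeric", events = "data.frame",
                 snpRate = "numeric", indelRate = "numeric"))

setValidity("RearrangementPlan", function(object) {
  ev <- object@events
  need <- c("type", "chrom", "start", "size", "dest_chrom")
  if (nrow(ev) && !all(need %in% names(ev)))
    return("events needs columns type, chrom, start, size, dest_chrom")
  if (nrow(ev)) {
    if (!all(ev$type %in% c("inversion", "translocation", "duplication",
                            "scramble", "deletion")))
      return("unknown event type")
    if (any(ev$chrom < 1 | ev$chrom > object@nChromosomes))
      return("event chromosome out of range")
    span <- ifelse(ev$type == "scramble", 0, ev$size)
    if (any(ev$start < 0 | ev$start + span > object@chromosomeLength))
      return("event exceeds chromosome bounds")
    ## interval events on the same chromosome must not overlap
    iv <- ev[ev$type != "scramble", , drop = FALSE]
    if (nrow(iv) > 1L) {
      for (ch in unique(iv$chrom)) {
        sub <- iv[iv$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        if (nrow(sub) > 1L &&
            any(sub$start[-1L] < (sub$start + sub$size)[-nrow(sub)]))
          return("events overlap on a chromosome")
      }
    }
  }
  if (object@snpRate < 0 || object@snpRate >= 1 ||
      object@indelRate < 0 || object@indelRate >= 1)
    return("rates must be in [0, 1)")
  TRUE
})
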