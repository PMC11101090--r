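#' Construct an AlignmentSegment
#'
#' @param qname,tname query/target sequence accessions.
#' @param qstart,qend,tstart,tend 0-based half-open spans (forward strand).
#'   Derived from `blocks` when omitted.
#' @param orientation `"forward"` or `"reverse"`.
#' @param blocks numeric matrix with columns `qstart`, `tstart`, `length`
#'   (ungapped aligned runs, query-sorted). Defaults to a single block
#'   covering the spans.
#' @param matches,mismatches aligned-column counts. By default all columns
#'   are matches.
#' @param gapCount,gapBases gap statistics. Recomputed from the block
#'   junctions when NA.
#' @param qassembly,tassembly assembly accessions.
#' @param sourceId provenance string.
#' @param lowres flag for segments without exact block structure.
#' @return An [AlignmentSegment-class] object.
#' @examples
#' AlignmentSegment("q1", 0, 100, "t1", 500, 600)
#' @export
AlignmentSegment <- function(qname, qstart = NULL, qend = NULL,
                             tname, tstart = NULL, tend = NULL,
                             orientation = "forward", blocks = NULL,
                             matches = NULL, mismatches = 0,
                             gapCount = NA, gapBases = NA,
                             qassembly = "", tassembly = "",
                             sourceId = "", lowres = FALSE) {
  if (is.null(blocks)) {
    stopifnot(!is.null(qstart), !is.null(tstart))
    blocks <- cbind(qstart = qstart, tstart = tstart, length = qend - qstart)
  }
  blocks <- matrix(as.numeric(blocks), ncol = 3L,
                   dimnames = list(NULL, c("qstart", "tstart", "length")))
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  if (is.null(qstart) || lowres == FALSE) {
    qstart <- min(blocks[, 1L]); qend <- max(blocks[, 1L] + blocks[, 3L])
    tstart <- min(blocks[, 2L]); tend <- max(blocks[, 2L] + blocks[, 3L])
  }
  if (is.null(matches)) matches <- sum(blocks[, 3L]) - mismatches
  g <- .junctionGaps(blocks, orientation)
  if (is.na(gapBases)) gapBases <- sum(g$qgap) + sum(g$tgap)
  if (is.na(gapCount)) gapCount <- sum(g$qgap > 0) + sum(g$tgap > 0)
  new("AlignmentSegment", qname = as.character(qname),
      qstart = as.numeric(qstart), qend = as.numeric(qend),
      tname = as.character(tname), tstart = as.numeric(tstart),
      tend = as.numeric(tend), qassembly = as.character(qassembly),
      tassembly = as.character(tassembly),
      orientation = orientation, blocks = blocks,
      matches = as.numeric(matches), mismatches = as.numeric(mismatches),
      gapCount = as.numeric(gapCount), gapBases = as.numeric(gapBases),
      sourceId = as.character(sourceId), lowres = lowres)
}

## query- and target-side gap lengths at each internal block junction
.junctionGaps <- function(blocks, orientation) {
  n <- nrow(blocks)
  if (n < 2L) return(list(qgap = numeric(0), tgap = numeric(0)))
  qgap <- blocks[-1L, 1L] - (blocks[-n, 1L] + blocks[-n, 3L])
  tgap <- if (orientation == "forward")
    blocks[-1L, 2L] - (blocks[-n, 2L] + blocks[-n, 3L])
  else
    blocks[-n, 2L] - (blocks[-1L, 2L] + blocks[-1L, 3L])
  list(qgap = qgap, tgap = tgap)
}

#' Percent identity of a segment
#'
#' Computed as `100 * matches / (matches + mismatches + gapBases)`, the
#' alignment-column convention: gapped columns count in the denominator.
#'
#' @param segment an [AlignmentSegment-class].
#' @return Percentage in [0, 100].
#' @examples
#' s <- AlignmentSegment("q", 0, 100, "t", 0, 100, mismatches = 10)
#' percentIdentity(s)
#' @export
percentIdentity <- function(segment) {
  den <- segment@matches + segment@mismatches + segment@gapBases
  if (den <= 0) stop("invalid segment: zero identity denominator")
  100 * segment@matches / den
}

#' Alignment length of a segment
#'
#' Reported alignment length is the query-span length (`qend - qstart`).
#'
#' @param segment an [AlignmentSegment-class].
#' @return Length in bases.
#' @export
alignmentLength <- function(segment) segment@qend - segment@qstart

#' Query/target ranges of a segment
#' @param segment an [AlignmentSegment-class].
#' @return A [SeqRange-class].
#' @export
queryRange <- function(segment)
  SeqRange(segment@qname, segment@qstart, segment@qend, segment@qassembly)

#' @rdname queryRange
#' @export
targetRange <- function(segment)
  SeqRange(segment@tname, segment@tstart, segment@tend, segment@tassembly)

#' Project a query interval through a segment onto the target
#'
#' Walks the block structure and returns the target interval aligned to
#' `qInterval` (the envelope of the mapped bases, so unaligned bases at
#' internal junctions spanned by the interval are included). For reverse
#' orientation the returned interval is in forward target coordinates.
#'
#' @param segment an [AlignmentSegment-class].
#' @param qInterval a [SeqRange-class] overlapping the segment's query
#'   blocks, or a numeric `c(start, end)` pair.
#' @return A [SeqRange-class] on the target sequence.
#' @examples
#' s <- AlignmentSegment("q", 0, 100, "t", 500, 600)
#' projectToTarget(s, c(10, 20))
#' @export
projectToTarget <- function(segment, qInterval) {
  if (is(qInterval, "SeqRange")) {
    if (qInterval@seqId != segment@qname)
      stop("no-overlap: interval is on another sequence")
    lo <- qInterval@start; hi <- qInterval@end
  } else {
    lo <- qInterval[1L]; hi <- qInterval[2L]
  }
  b <- segment@blocks
  tpos <- c()
  for (i in seq_len(nrow(b))) {
    qs <- b[i, 1L]; ts <- b[i, 2L]; L <- b[i, 3L]
    a <- max(lo, qs); z <- min(hi, qs + L)
    if (a >= z) next
    if (segment@orientation == "forward") {
      tpos <- c(tpos, ts + (a - qs), ts + (z - qs))
    } else {
      tpos <- c(tpos, ts + (qs + L - z), ts + (qs + L - a))
    }
  }
  if (is.null(tpos))
    stop("no-overlap: interval does not intersect the aligned query range")
  SeqRange(segment@tname, min(tpos), max(tpos), segment@tassembly)
}

## ---- AssemblyInfo accessors ------------------------------------------------

#' Sequence length / role lookup in an AssemblyInfo
#'
#' @param info an [AssemblyInfo-class] (or NULL: length is NA, role
#'   defaults to chromosome).
#' @param seqId sequence accession(s).
#' @return `seqLength`: numeric (NA when unknown). `seqRole`: character.
#' @export
seqLength <- function(info, seqId) {
  if (is.null(info)) return(rep(NA_real_, length(seqId)))
  info@seqs$length[match(seqId, info@seqs$seq_id)]
}

#' @rdname seqLength
#' @export
seqRole <- function(info, seqId) {
  if (is.null(info)) return(rep("chromosome", length(seqId)))
  r <- info@seqs$role[match(seqId, info@seqs$seq_id)]
  r[is.na(r)] <- "chromosome"
  r
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "SeqRange", function(object) {
  cat(sprintf("SeqRange %s:%g-%g [%s)\n", object@seqId, object@start,
              object@end,
              if (nzchar(object@assemblyId)) object@assemblyId else "?"))
})

setMethod("show", "AlignmentSegment", function(object) {
  cat(sprintf(
    "AlignmentSegment %s:%g-%g -> %s:%g-%g (%s), %d block(s), %.2f%% id\n",
    object@qname, object@qstart, object@qend, object@tname, object@tstart,
    object@tend, object@orientation, nrow(object@blocks),
    percentIdentity(object)))
})

setMethod("show", "AssemblyInfo", function(object) {
  cat(sprintf("AssemblyInfo %s (%s): %d sequence(s), %g bases\n",
              object@assemblyId, object@assemblyName, nrow(object@seqs),
              sum(object@seqs$length)))
})

setMethod("show", "ProcessingParams", function(object) {
  cat(sprintf(
    "ProcessingParams [%s]: gap split %g bp / %g%%, merge gap %g bp\n",
    object@speciesMode, object@gapSplitBp, 100 * object@gapSplitFrac,
    object@mergeMaxGap))
})

setMethod("show", "RankedAlignmentSet", function(object) {
  tab <- table(factor(object@reciprocity, levels = 3:1))
  cat(sprintf(
    "RankedAlignmentSet: %d segment(s) (reciprocity 3/2/1: %d/%d/%d), %g discarded\n",
    length(object@segments), tab[["3"]], tab[["2"]], tab[["1"]],
    object@dropped))
})

setMethod("show", "Sketch", function(object) {
  cat(sprintf("Sketch: k=%g, s=%g, %d hash(es)\n", object@k, object@s,
              length(object@hashes)))
})

## ---- container accessors ---------------------------------------------------

#' Segments and reciprocity codes of a RankedAlignmentSet
#' @param x a [RankedAlignmentSet-class].
#' @return `segments()`: list of [AlignmentSegment-class];
#'   `reciprocity()`: integer vector; `stageLog()`: named counts.
#' @export
segments <- function(x) x@segments

#' @rdname segments
#' @export
reciprocity <- function(x) x@reciprocity

#' @rdname segments
#' @export
stageLog <- function(x) x@stageLog

setMethod("length", "RankedAlignmentSet", function(x) length(x@segments))

#' Subset a RankedAlignmentSet
#' @param x a [RankedAlignmentSet-class].
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RankedAlignmentSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, segments = x@segments[i],
             reciprocity = x@reciprocity[i])
})

#' Tabulate a RankedAlignmentSet as a data.frame
#'
#' One row per segment with 1-based inclusive display coordinates,
#' orientation, identity and gap statistics - the layout of the TSV/XLSX
#' export.
#'
#' @param x a [RankedAlignmentSet-class] or list of segments.
#' @param row.names,optional,... ignored (base generic signature).
#' @return A data.frame.
#' @export
setMethod("as.data.frame", "RankedAlignmentSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    .segmentsAsDataFrame(x@segments, x@reciprocity)
  })

.segmentsAsDataFrame <- function(segs, recip = rep(NA_integer_, length(segs))) {
  if (!length(segs)) {
    return(data.frame(query_assembly = character(0), query_seq = character(0),
      query_start = numeric(0), query_end = numeric(0),
      target_assembly = character(0), target_seq = character(0),
      target_start = numeric(0), target_end = numeric(0),
      orientation = character(0), pct_identity = numeric(0),
      matches = numeric(0), mismatches = numeric(0), gap_count = numeric(0),
      gap_bases = numeric(0), alignment_length = numeric(0),
      reciprocity = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    query_assembly = vapply(segs, slot, "", "qassembly"),
    query_seq = vapply(segs, slot, "", "qname"),
    query_start = vapply(segs, slot, 0, "qstart") + 1,
    query_end = vapply(segs, slot, 0, "qend"),
    target_assembly = vapply(segs, slot, "", "tassembly"),
    target_seq = vapply(segs, slot, "", "tname"),
    target_start = vapply(segs, slot, 0, "tstart") + 1,
    target_end = vapply(segs, slot, 0, "tend"),
    orientation = vapply(segs, slot, "", "orientation"),
    pct_identity = round(vapply(segs, percentIdentity, 0), 4),
    matches = vapply(segs, slot, 0, "matches"),
    mismatches = vapply(segs, slot, 0, "mismatches"),
    gap_count = vapply(segs, slot, 0, "gapCount"),
    gap_bases = vapply(segs, slot, 0, "gapBases"),
    alignment_length = vapply(segs, alignmentLength, 0),
    reciprocity = as.integer(recip),
    stringsAsFactors = FALSE)
}

## ---- internal segment surgery ---------------------------------------------

## Rebuild child segments from a partition of the block rows, allocating
## matched columns proportionally (largest-remainder, so totals are
## conserved exactly) and recomputing gap statistics from the junctions
## each child retains.
.childrenFromBlockBins <- function(seg, bins) {
  bins <- bins[vapply(bins, length, 0L) > 0L]
  total <- sum(seg@blocks[, 3L])
  cols <- vapply(bins, function(ix) sum(seg@blocks[ix, 3L]), 0)
  m <- floor(seg@matches * cols / total)
  rem <- seg@matches - sum(m)
  if (rem > 0) {
    frac <- seg@matches * cols / total - m
    ord <- order(frac, decreasing = TRUE)
    bump <- ord[seq_len(rem)]
    m[bump] <- m[bump] + 1
  }
  ## a child cannot have more matches than columns
  over <- m > cols
  while (any(over)) {
    excess <- sum(m[over] - cols[over])
    m[over] <- cols[over]
    room <- which(m < cols)
    for (i in room) {
      take <- min(excess, cols[i] - m[i]); m[i] <- m[i] + take
      excess <- excess - take
      if (excess == 0) break
    }
    over <- m > cols
  }
  lapply(seq_along(bins), function(i) {
    AlignmentSegment(seg@qname, tname = seg@tname,
      orientation = seg@orientation,
      blocks = seg@blocks[bins[[i]], , drop = FALSE],
      matches = m[i], mismatches = cols[i] - m[i],
      qassembly = seg@qassembly, tassembly = seg@tassembly,
      sourceId = seg@sourceId, lowres = seg@lowres)
  })
}

## Bisect block rows at axis positions that fall strictly inside a block.
## Returns a new block matrix (still query-sorted).
.bisectBlocks <- function(blocks, positions, axis, orientation) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    qs <- blocks[i, 1L]; ts <- blocks[i, 2L]; L <- blocks[i, 3L]
    if (axis == "query") {
      inside <- sort(positions[positions > qs & positions < qs + L])
      qcuts <- inside
    } else {
      inside <- sort(positions[positions > ts & positions < ts + L])
      qcuts <- if (orientation == "forward") qs + (inside - ts)
               else sort(qs + (ts + L - inside))
    }
    edges <- c(qs, qcuts, qs + L)
    for (j in seq_len(length(edges) - 1L)) {
      a <- edges[j]; z <- edges[j + 1L]; l <- z - a
      tsub <- if (orientation == "forward") ts + (a - qs)
              else ts + (qs + L - z)
      out[[length(out) + 1L]] <- c(a, tsub, l)
    }
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- c("qstart", "tstart", "length")
  mat[order(mat[, 1L]), , drop = FALSE]
}

## Cut a segment at the given axis positions (0-based offsets). Positions
## inside blocks bisect the block exactly; positions in inter-block gaps
## split at the junction. Returns a list of child segments.
.cutSegment <- function(seg, positions, axis = c("query", "target")) {
  axis <- match.arg(axis)
  span <- if (axis == "query") c(seg@qstart, seg@qend)
          else c(seg@tstart, seg@tend)
  positions <- sort(unique(positions[positions > span[1L] &
                                     positions < span[2L]]))
  if (!length(positions)) return(list(seg))
  blocks <- .bisectBlocks(seg@blocks, positions, axis, seg@orientation)
  key <- if (axis == "query") blocks[, 1L] else blocks[, 2L]
  bin <- findInterval(key, positions) + 1L
  bins <- split(seq_len(nrow(blocks)), bin)
  seg2 <- seg
  seg2@blocks <- blocks
  .childrenFromBlockBins(seg2, unname(bins))
}
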