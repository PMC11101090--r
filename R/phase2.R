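## Second-phase alignment processing: merge adjacent alignments, split on
## large gaps and at overlaps, drop contained duplicates, rank, assign
## reciprocity by a two-scan best-placement pass, and re-merge within each
## reciprocity class.

## canonical deterministic order, used before processing and as tie-break
.canonicalOrder <- function(segs) {
  order(vapply(segs, slot, "", "qname"),
        vapply(segs, slot, 0, "qstart"),
        vapply(segs, slot, "", "tname"),
        vapply(segs, slot, 0, "tstart"),
        vapply(segs, slot, "", "orientation"),
        vapply(segs, slot, 0, "qend"),
        vapply(segs, slot, 0, "tend"))
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## ---- merge -----------------------------------------------------------------

#' Merge adjacent collinear alignments
#'
#' Two segments merge iff they lie on the same sequence pair with the same
#' orientation, are collinear (query order matches target order under the
#' orientation), both intervening gaps are at most `params@mergeMaxGap`,
#' and no third segment overlaps either intervening interval. Merging
#' concatenates blocks and sums match/mismatch counts; applied to fixpoint.
#'
#' @param segs list of [AlignmentSegment-class] from one assembly pair.
#' @param params a [ProcessingParams-class].
#' @return List of merged segments in canonical order.
#' @export
mergeAdjacent <- function(segs, params = ProcessingParams()) {
  if (length(segs) < 2L) return(segs)
  maxGap <- params@mergeMaxGap
  repeat {
    segs <- segs[.canonicalOrder(segs)]
    qn <- vapply(segs, slot, "", "qname")
    qs <- vapply(segs, slot, 0, "qstart"); qe <- vapply(segs, slot, 0, "qend")
    tn <- vapply(segs, slot, "", "tname")
    ts <- vapply(segs, slot, 0, "tstart"); te <- vapply(segs, slot, 0, "tend")
    ori <- vapply(segs, slot, "", "orientation")
    grp <- paste(qn, tn, ori, vapply(segs, slot, "", "qassembly"),
                 vapply(segs, slot, "", "tassembly"), sep = "\r")
    merged <- FALSE
    for (g in unique(grp)) {
      ix <- which(grp == g)
      if (length(ix) < 2L) next
      ix <- ix[order(qs[ix])]
      for (p in seq_len(length(ix) - 1L)) {
        i <- ix[p]; j <- ix[p + 1L]
        qgap <- qs[j] - qe[i]
        tgap <- if (ori[i] == "forward") ts[j] - te[i] else ts[i] - te[j]
        if (qgap < 0 || tgap < 0 || qgap > maxGap || tgap > maxGap) next
        ## conflict: any third segment overlapping an intervening interval
        conflict <- FALSE
        if (qgap > 0) {
          others <- setdiff(which(qn == qn[i]), c(i, j))
          if (any(.overlaps(qs[others], qe[others], qe[i], qs[j])))
            conflict <- TRUE
        }
        if (!conflict && tgap > 0) {
          others <- setdiff(which(tn == tn[i]), c(i, j))
          tlo <- if (ori[i] == "forward") te[i] else te[j]
          thi <- if (ori[i] == "forward") ts[j] else ts[i]
          if (any(.overlaps(ts[others], te[others], tlo, thi)))
            conflict <- TRUE
        }
        if (conflict) next
        segs[[i]] <- .mergeTwo(segs[[i]], segs[[j]])
        segs[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  segs
}

.mergeTwo <- function(a, b) {
  AlignmentSegment(a@qname, tname = a@tname, orientation = a@orientation,
    blocks = rbind(a@blocks, b@blocks),
    matches = a@matches + b@matches,
    mismatches = a@mismatches + b@mismatches,
    qassembly = a@qassembly, tassembly = a@tassembly,
    sourceId = a@sourceId, lowres = a@lowres || b@lowres)
}

## ---- gap split -------------------------------------------------------------

#' Split alignments on large internal gaps
#'
#' At each internal block junction the gap length is the maximum of the
#' query-side and target-side gaps. A segment is split at every junction
#' where that gap is at least `min(params@gapSplitBp,
#' params@gapSplitFrac * alignment length)` - 50 bp absolute for
#' same-or-closer species, 50 kb for distant species, 5\% fractional in
#' both modes, evaluated on the pre-split query-span length. Children
#' inherit proportional match statistics; matched bases are conserved.
#'
#' @param segs an [AlignmentSegment-class] or a list of them.
#' @param params a [ProcessingParams-class].
#' @return List of segments.
#' @export
splitOnGaps <- function(segs, params = ProcessingParams()) {
  if (is(segs, "AlignmentSegment")) segs <- list(segs)
  out <- list()
  for (seg in segs) {
    thr <- min(params@gapSplitBp, params@gapSplitFrac * alignmentLength(seg))
    g <- .junctionGaps(seg@blocks, seg@orientation)
    big <- which(pmax(g$qgap, g$tgap) >= thr)
    if (!length(big)) { out[[length(out) + 1L]] <- seg; next }
    bins <- split(seq_len(nrow(seg@blocks)),
                  findInterval(seq_len(nrow(seg@blocks)) - 1L, big) + 1L)
    out <- c(out, .childrenFromBlockBins(seg, unname(bins)))
  }
  out
}

## ---- overlap split ---------------------------------------------------------

#' Split alignments where they intersect overlapping alignments
#'
#' For every pair of segments overlapping on the query or on the target,
#' both are cut at the overlap boundaries so that, per sequence, any two
#' output segments are either range-identical or range-disjoint on the
#' overlapping axis. Cuts between blocks fall at the junction; cuts inside
#' a block bisect it exactly. No aligned base is changed, only boundaries.
#'
#' @param segs list of [AlignmentSegment-class] from one assembly pair.
#' @return List of segments in canonical order.
#' @export
splitAtOverlaps <- function(segs) {
  if (length(segs) < 2L) return(segs)
  for (iter in seq_len(100L)) {
    changed <- FALSE
    for (axis in c("query", "target")) {
      sq <- if (axis == "query") "qname" else "tname"
      ss <- if (axis == "query") "qstart" else "tstart"
      se <- if (axis == "query") "qend" else "tend"
      nm <- vapply(segs, slot, "", sq)
      st <- vapply(segs, slot, 0, ss)
      en <- vapply(segs, slot, 0, se)
      pieces <- vector("list", length(segs))
      for (i in seq_along(segs)) {
        others <- which(nm == nm[i] & .overlaps(st, en, st[i], en[i]))
        others <- setdiff(others, i)
        cuts <- unique(c(st[others], en[others]))
        cuts <- cuts[cuts > st[i] & cuts < en[i]]
        if (length(cuts)) {
          pieces[[i]] <- .cutSegment(segs[[i]], cuts, axis)
          changed <- TRUE
        } else pieces[[i]] <- list(segs[[i]])
      }
      segs <- unlist(pieces, recursive = FALSE)
    }
    if (!changed) break
  }
  if (changed)
    warning("overlap splitting did not converge in 100 iterations")
  segs[.canonicalOrder(segs)]
}

## ---- ranking ---------------------------------------------------------------

## rank-key table: assembly-level class (2 chromosome on both, 1 on one,
## 0 on neither), identity, query-span length, then canonical coordinates.
## Common-component preference is not modelled (component metadata is an
## NCBI-internal resource).
.rankKeys <- function(segs, qInfo = NULL, tInfo = NULL) {
  qrole <- seqRole(qInfo, vapply(segs, slot, "", "qname"))
  trole <- seqRole(tInfo, vapply(segs, slot, "", "tname"))
  data.frame(
    class = (qrole == "chromosome") + (trole == "chromosome"),
    identity = vapply(segs, percentIdentity, 0),
    length = vapply(segs, alignmentLength, 0),
    qname = vapply(segs, slot, "", "qname"),
    qstart = vapply(segs, slot, 0, "qstart"),
    tname = vapply(segs, slot, "", "tname"),
    tstart = vapply(segs, slot, 0, "tstart"),
    stringsAsFactors = FALSE)
}

#' Sort segments by rank
#'
#' Descending by assembly-level class (chromosome-on-both, chromosome-on-
#' one, neither), then percent identity, then alignment length, with
#' lexicographic coordinates as a deterministic tie-break. Sequences
#' missing from the catalogues are treated as chromosomes.
#'
#' @param segs list of [AlignmentSegment-class].
#' @param qInfo,tInfo [AssemblyInfo-class] or NULL.
#' @return The list reordered from best to worst.
#' @export
rankSort <- function(segs, qInfo = NULL, tInfo = NULL) {
  if (length(segs) < 2L) return(segs)
  k <- .rankKeys(segs, qInfo, tInfo)
  segs[order(-k$class, -k$identity, -k$length, k$qname, k$qstart,
             k$tname, k$tstart)]
}

## ---- contained-duplicate dropping -----------------------------------------

#' Drop duplicates and contained low-quality alignments
#'
#' A segment is removed iff both its query and target ranges are contained
#' within those of a single strictly higher-ranked segment with the same
#' orientation and sequence pair. Exact duplicates keep their first
#' representative in rank order.
#'
#' @param segs list of [AlignmentSegment-class].
#' @param qInfo,tInfo [AssemblyInfo-class] or NULL (used for ranking).
#' @return List of surviving segments, in rank order.
#' @export
dropContained <- function(segs, qInfo = NULL, tInfo = NULL) {
  if (length(segs) < 2L) return(segs)
  segs <- rankSort(segs, qInfo, tInfo)
  qn <- vapply(segs, slot, "", "qname")
  qs <- vapply(segs, slot, 0, "qstart"); qe <- vapply(segs, slot, 0, "qend")
  tn <- vapply(segs, slot, "", "tname")
  ts <- vapply(segs, slot, 0, "tstart"); te <- vapply(segs, slot, 0, "tend")
  ori <- vapply(segs, slot, "", "orientation")
  sig <- paste(qn, qs, qe, tn, ts, te, ori, sep = "\r")
  keep <- !duplicated(sig)
  for (i in which(keep)) {
    j <- which(keep & seq_along(segs) < i & qn == qn[i] & tn == tn[i] &
               ori == ori[i] & qs <= qs[i] & qe >= qe[i] &
               ts <= ts[i] & te >= te[i] & sig != sig[i])
    if (length(j)) keep[i] <- FALSE
  }
  segs[keep]
}

## ---- reciprocity -----------------------------------------------------------

#' Assign reciprocity codes by two best-placement scans
#'
#' The rank-sorted segments are scanned twice, once on the query and once
#' on the target ranges. Scan 1 marks a segment query-best iff no
#' higher-ranked segment overlaps it on the query; scan 2 likewise on the
#' target. Reciprocity 3 = best on both scans (reciprocal best-placed,
#' "first pass"); 1 = query-side best only; 2 = target-side best only
#' ("second pass"). Segments best on neither axis are discarded and
#' counted. Input should already be overlap-split so same-axis overlaps
#' are range-identical.
#'
#' @param segs list of [AlignmentSegment-class], rank-sorted (the function
#'   rank-sorts defensively).
#' @param qInfo,tInfo [AssemblyInfo-class] or NULL.
#' @return A [RankedAlignmentSet-class].
#' @export
assignReciprocity <- function(segs, qInfo = NULL, tInfo = NULL) {
  segs <- rankSort(segs, qInfo, tInfo)
  n <- length(segs)
  qn <- vapply(segs, slot, "", "qname")
  qs <- vapply(segs, slot, 0, "qstart"); qe <- vapply(segs, slot, 0, "qend")
  tn <- vapply(segs, slot, "", "tname")
  ts <- vapply(segs, slot, 0, "tstart"); te <- vapply(segs, slot, 0, "tend")
  qbest <- logical(n); tbest <- logical(n)
  for (i in seq_len(n)) {
    hi <- seq_len(i - 1L)
    qbest[i] <- !any(qn[hi] == qn[i] & .overlaps(qs[hi], qe[hi], qs[i], qe[i]))
    tbest[i] <- !any(tn[hi] == tn[i] & .overlaps(ts[hi], te[hi], ts[i], te[i]))
  }
  recip <- ifelse(qbest & tbest, 3L, ifelse(qbest, 1L, ifelse(tbest, 2L, 0L)))
  keep <- recip > 0L
  new("RankedAlignmentSet", segments = segs[keep],
      reciprocity = recip[keep], queryInfo = qInfo, targetInfo = tInfo,
      dropped = sum(!keep))
}

#' Re-merge alignments within each reciprocity class
#'
#' [mergeAdjacent()] applied independently within each reciprocity class
#' to stitch adjacent alignments with no conflicting alignments into the
#' longest representative stretches; reciprocity labels are preserved.
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param params a [ProcessingParams-class].
#' @return A [RankedAlignmentSet-class].
#' @export
remerge <- function(ranked, params = ProcessingParams()) {
  segs <- list(); recip <- integer(0)
  for (r in c(3L, 2L, 1L)) {
    sub <- ranked@segments[ranked@reciprocity == r]
    if (!length(sub)) next
    sub <- mergeAdjacent(sub, params)
    segs <- c(segs, sub)
    recip <- c(recip, rep(r, length(sub)))
  }
  initialize(ranked, segments = segs, reciprocity = recip)
}

## ---- pipeline --------------------------------------------------------------

#' Run the full second-phase pipeline
#'
#' merge adjacent -> split on gaps -> split at overlaps -> drop contained
#' -> rank -> assign reciprocity -> re-merge per reciprocity class. The
#' input is canonically pre-sorted, so the output is independent of input
#' order. A per-stage segment-count log is emitted to standard error and
#' stored in the result's `stageLog`.
#'
#' @param raw list of [AlignmentSegment-class] from one assembly pair.
#' @param qInfo,tInfo [AssemblyInfo-class] or NULL. When supplied, every
#'   segment must reference catalogued sequences.
#' @param params a [ProcessingParams-class].
#' @param quiet suppress the stage log.
#' @return A [RankedAlignmentSet-class].
#' @examples
#' a <- AlignmentSegment("q1", 0, 100, "t1", 0, 100)
#' b <- AlignmentSegment("q1", 110, 200, "t1", 112, 202)
#' processAlignments(list(a, b), quiet = TRUE)
#' @export
processAlignments <- function(raw, qInfo = NULL, tInfo = NULL,
                              params = ProcessingParams(), quiet = FALSE) {
  .validateSegments(raw, qInfo, tInfo)
  log <- c(input = length(raw))
  if (!length(raw)) {
    return(new("RankedAlignmentSet", segments = list(),
               reciprocity = integer(0), queryInfo = qInfo,
               targetInfo = tInfo, stageLog = log))
  }
  segs <- raw[.canonicalOrder(raw)]
  segs <- mergeAdjacent(segs, params);    log["merged"] <- length(segs)
  segs <- splitOnGaps(segs, params);      log["gap_split"] <- length(segs)
  segs <- splitAtOverlaps(segs);          log["overlap_split"] <- length(segs)
  segs <- dropContained(segs, qInfo, tInfo)
  log["contained_dropped_to"] <- length(segs)
  ranked <- assignReciprocity(segs, qInfo, tInfo)
  log["reciprocity_kept"] <- length(ranked@segments)
  log["best_on_neither_discarded"] <- ranked@dropped
  ranked <- remerge(ranked, params)
  log["remerged"] <- length(ranked@segments)
  ranked@stageLog <- log
  if (!quiet)
    message(paste(sprintf("%s=%g", names(log), log), collapse = " "))
  ranked
}

.validateSegments <- function(segs, qInfo, tInfo) {
  bad <- character(0)
  if (!is.null(qInfo)) {
    qn <- vapply(segs, slot, "", "qname")
    bad <- c(bad, setdiff(qn, qInfo@seqs$seq_id))
  }
  if (!is.null(tInfo)) {
    tn <- vapply(segs, slot, "", "tname")
    bad <- c(bad, setdiff(tn, tInfo@seqs$seq_id))
  }
  if (length(bad))
    stop("segments reference unknown sequences: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}
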