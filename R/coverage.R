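## Alignment-coverage statistics: fraction of target genome and of CDS
## nucleotides covered by ungapped alignment blocks.

## IRangesList of target-side ungapped block intervals, per sequence
.targetBlockRanges <- function(segs) {
  if (!length(segs)) return(list())
  tn <- rep(vapply(segs, slot, "", "tname"),
            vapply(segs, function(s) nrow(s@blocks), 0L))
  starts <- unlist(lapply(segs, function(s) s@blocks[, 2L]))
  lens <- unlist(lapply(segs, function(s) s@blocks[, 3L]))
  ir <- split(IRanges::IRanges(start = starts + 1, width = lens), tn)
  lapply(ir, IRanges::reduce)
}

.filterByReciprocity <- function(ranked, reciprocityFilter) {
  ranked@segments[ranked@reciprocity %in% reciprocityFilter]
}

#' Genome coverage by ungapped alignment blocks
#'
#' Percentage of target-genome nucleotides covered by the union of the
#' target-side ungapped blocks (no double counting of overlaps).
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param tInfo target [AssemblyInfo-class].
#' @param reciprocityFilter reciprocity codes to include (default all;
#'   use `3` for reciprocal-best only).
#' @return Percentage in [0, 100].
#' @export
genomeCoverage <- function(ranked, tInfo, reciprocityFilter = c(1L, 2L, 3L)) {
  segs <- .filterByReciprocity(ranked, reciprocityFilter)
  .validateSegments(segs, NULL, tInfo)
  cov <- .targetBlockRanges(segs)
  covered <- sum(vapply(cov, function(r) sum(IRanges::width(r)), 0))
  100 * covered / sum(tInfo@seqs$length)
}

#' CDS coverage by ungapped alignment blocks
#'
#' Percentage of CDS nucleotides (the union of all CDS intervals on the
#' target assembly, so overlapping isoforms are not double-counted)
#' covered by the union of target-side ungapped blocks.
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param genes gene annotation as returned by [readGFF3Genes()], or a
#'   GRanges/GRangesList of CDS intervals (1-based closed).
#' @param tInfo target [AssemblyInfo-class].
#' @param reciprocityFilter reciprocity codes to include.
#' @return Percentage in [0, 100].
#' @export
cdsCoverage <- function(ranked, genes, tInfo,
                        reciprocityFilter = c(1L, 2L, 3L)) {
  cds <- if (is.list(genes) && !is(genes, "GRangesList")) genes$cds else genes
  gr <- if (is(cds, "GRangesList")) unlist(cds) else cds
  if (length(gr) == 0L) stop("undefined coverage: empty CDS set")
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 tInfo@seqs$seq_id)
  if (length(bad))
    stop("CDS reference unknown sequences: ", paste(bad, collapse = ", "))
  cdsBySeq <- lapply(
    split(IRanges::IRanges(GenomicRanges::start(gr),
                           GenomicRanges::end(gr)),
          as.character(GenomicRanges::seqnames(gr))),
    IRanges::reduce)
  segs <- .filterByReciprocity(ranked, reciprocityFilter)
  .validateSegments(segs, NULL, tInfo)
  cov <- .targetBlockRanges(segs)
  total <- sum(vapply(cdsBySeq, function(r) sum(IRanges::width(r)), 0))
  hit <- 0
  for (sq in names(cdsBySeq)) {
    if (!sq %in% names(cov)) next
    hit <- hit + sum(IRanges::width(
      IRanges::intersect(cdsBySeq[[sq]], cov[[sq]])))
  }
  100 * hit / total
}

#' Write a coverage report
#'
#' TSV with one row per reciprocity filter: assembly pair, optional Mash
#' distance, genome coverage and (when annotation is given) CDS coverage.
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param tInfo target [AssemblyInfo-class].
#' @param path output TSV.
#' @param genes optional annotation (see [cdsCoverage()]).
#' @param qInfo optional query [AssemblyInfo-class] (for the pair label).
#' @param mashDistance optional distance to record.
#' @return Invisibly, the report data.frame.
#' @export
coverageReport <- function(ranked, tInfo, path, genes = NULL, qInfo = NULL,
                           mashDistance = NA_real_) {
  filters <- list(all = c(1L, 2L, 3L), best_only = 3L)
  rows <- lapply(names(filters), function(f) {
    data.frame(
      query_assembly = if (!is.null(qInfo)) qInfo@assemblyId else "",
      target_assembly = tInfo@assemblyId,
      mash_distance = mashDistance,
      reciprocity_filter = f,
      genome_pct = round(genomeCoverage(ranked, tInfo, filters[[f]]), 4),
      cds_pct = if (!is.null(genes))
        round(cdsCoverage(ranked, genes, tInfo, filters[[f]]), 4)
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
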