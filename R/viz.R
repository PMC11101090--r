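## Static SVG rendering: ideogram view (chromosome rows linked by ribbon
## connectors) and dotplot view. Rendering is pure - the same scene always
## produces byte-identical SVG.

.palette <- c("#4E79A7", "#F28E2B", "#59A14F", "#E15759", "#76B7B2",
              "#EDC948", "#B07AA1", "#FF9DA7", "#9C755F", "#BAB0AC",
              "#1F77B4", "#2CA02C")
.fwdColor <- "green"
.revColor <- "purple"

## natural sort: numeric runs compare numerically (chr2 before chr10)
.naturalOrder <- function(x) {
  key <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    r <- regmatches(s, m)[[1L]]
    if (length(r))
      regmatches(s, m) <- list(sprintf("%012d", as.numeric(r)))
    s
  }, "")
  order(key, x)
}

#' Construct a SyntenyScene
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param queryInfo,targetInfo [AssemblyInfo-class] catalogues (taken from
#'   `ranked` when present there).
#' @param minSegmentLength size filter: hide segments with query span
#'   shorter than this many bases.
#' @param orientationFilter `"all"`, `"forward_only"` or `"reverse_only"`.
#' @param includeNonBest show non-best (reciprocity 1/2) segments in the
#'   ideogram; default FALSE (reciprocal best hits only).
#' @param flippedSequences seq ids to draw reversed in the ideogram.
#' @param viewport optional `list(query =, target =)` of [SeqRange-class].
#' @param genes optional `list(query =, target =)` of GRanges with a
#'   `gene_name` metadata column.
#' @return A [SyntenyScene-class].
#' @export
SyntenyScene <- function(ranked, queryInfo = ranked@queryInfo,
                         targetInfo = ranked@targetInfo,
                         minSegmentLength = 0,
                         orientationFilter = "all",
                         includeNonBest = FALSE,
                         flippedSequences = character(0),
                         viewport = NULL, genes = NULL) {
  if (is.null(queryInfo))
    queryInfo <- .inferInfo(ranked@segments, "query")
  if (is.null(targetInfo))
    targetInfo <- .inferInfo(ranked@segments, "target")
  new("SyntenyScene", ranked = ranked, queryInfo = queryInfo,
      targetInfo = targetInfo, minSegmentLength = minSegmentLength,
      orientationFilter = orientationFilter,
      includeNonBest = includeNonBest,
      flippedSequences = flippedSequences, viewport = viewport,
      genes = genes)
}

## fallback catalogue when no metadata accompanies the alignments
.inferInfo <- function(segs, side) {
  nm <- vapply(segs, slot, "", if (side == "query") "qname" else "tname")
  en <- vapply(segs, slot, 0, if (side == "query") "qend" else "tend")
  asm <- if (length(segs))
    vapply(segs, slot, "", if (side == "query") "qassembly" else "tassembly")[1L]
  else ""
  if (!nzchar(asm)) asm <- side
  if (!length(nm)) return(AssemblyInfo(asm, "seq1", 1))
  AssemblyInfo(asm, unique(nm),
               vapply(unique(nm), function(s) max(en[nm == s]), 0))
}

#' Flip a chromosome in a scene
#'
#' Toggles a sequence in the flipped set, so inverted alignments to it
#' render in the same relative orientation. Flipping twice restores the
#' original scene (and its rendering, byte for byte).
#'
#' @param scene a [SyntenyScene-class].
#' @param seqId sequence accession to toggle.
#' @return The modified scene.
#' @export
flipSequence <- function(scene, seqId) {
  f <- scene@flippedSequences
  scene@flippedSequences <- if (seqId %in% f) setdiff(f, seqId)
                            else c(f, seqId)
  scene
}

## segments passing the scene filters; the dotplot always keeps non-best
.sceneSegments <- function(scene, view = c("ideogram", "dotplot")) {
  view <- match.arg(view)
  segs <- scene@ranked@segments
  recip <- scene@ranked@reciprocity
  keep <- rep(TRUE, length(segs))
  if (view == "ideogram" && !scene@includeNonBest) keep <- recip == 3L
  ori <- vapply(segs, slot, "", "orientation")
  if (scene@orientationFilter == "forward_only") keep <- keep & ori == "forward"
  if (scene@orientationFilter == "reverse_only") keep <- keep & ori == "reverse"
  keep <- keep & vapply(segs, alignmentLength, 0) >= scene@minSegmentLength
  if (!is.null(scene@viewport)) {
    v <- scene@viewport
    keep <- keep &
      vapply(segs, slot, "", "qname") == v$query@seqId &
      vapply(segs, slot, 0, "qstart") < v$query@end &
      vapply(segs, slot, 0, "qend") > v$query@start &
      vapply(segs, slot, "", "tname") == v$target@seqId &
      vapply(segs, slot, 0, "tstart") < v$target@end &
      vapply(segs, slot, 0, "tend") > v$target@start
  }
  list(segments = segs[keep], reciprocity = recip[keep])
}

## chromosome layout across a horizontal span: x offsets and scales
.chromLayout <- function(info, x0, width, gap = 8) {
  ids <- info@seqs$seq_id[.naturalOrder(info@seqs$seq_id)]
  lens <- seqLength(info, ids)
  scale <- (width - gap * (length(ids) - 1L)) / sum(lens)
  xs <- x0 + cumsum(c(0, head(lens * scale + gap, -1L)))
  list(ids = ids, lens = lens, x = setNames(xs, ids),
       w = setNames(lens * scale, ids), scale = scale)
}

.mapPos <- function(layout, seqId, pos, flipped = character(0)) {
  x <- layout$x[[seqId]]; w <- layout$w[[seqId]]; len <-
    layout$lens[match(seqId, layout$ids)]
  frac <- pos / len
  if (seqId %in% flipped) x + w * (1 - frac) else x + w * frac
}

.svgOpen <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height))
}

.fmt <- function(x) sprintf("%.2f", x)

.chromRow <- function(layout, y, h, label, flipped) {
  out <- sprintf('<text x="4" y="%s" font-size="11" class="row-label">%s</text>',
                 .fmt(y + h - 4), .xmlEscape(label))
  for (id in layout$ids) {
    out <- c(out, sprintf(
      paste0('<rect x="%s" y="%s" width="%s" height="%d" rx="4" ',
             'fill="#E8E8E8" stroke="#555" class="chromosome" ',
             'data-seq="%s"/>'),
      .fmt(layout$x[[id]]), .fmt(y), .fmt(layout$w[[id]]), h,
      .xmlEscape(id)))
    lab <- if (id %in% flipped) paste0(id, " (flipped)") else id
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
      .fmt(layout$x[[id]] + layout$w[[id]] / 2), .fmt(y - 4),
      .xmlEscape(lab)))
  }
  out
}

## coordinate ruler under a chromosome row (ticks at a power-of-ten step)
.ruler <- function(layout, y) {
  step <- 10^floor(log10(max(layout$lens) / 4))
  out <- character(0)
  for (id in layout$ids) {
    len <- layout$lens[match(id, layout$ids)]
    at <- seq(0, len, by = step)
    px <- layout$x[[id]] + at / len * layout$w[[id]]
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999" class="tick"/>',
      .fmt(px), .fmt(y), .fmt(px), .fmt(y + 3)))
  }
  out
}

.geneGlyphs <- function(genes, layout, y, flipped) {
  out <- character(0)
  if (is.null(genes)) return(out)
  sq <- as.character(GenomicRanges::seqnames(genes))
  keep <- sq %in% layout$ids
  genes <- genes[keep]; sq <- sq[keep]
  nm <- if (!is.null(genes$gene_name)) as.character(genes$gene_name)
        else as.character(seq_along(genes))
  for (i in seq_along(genes)) {
    x1 <- .mapPos(layout, sq[i], GenomicRanges::start(genes)[i] - 1, flipped)
    x2 <- .mapPos(layout, sq[i], GenomicRanges::end(genes)[i], flipped)
    out <- c(out, sprintf(
      paste0('<rect x="%s" y="%s" width="%s" height="4" fill="#C0392B" ',
             'class="gene" data-name="%s"/>'),
      .fmt(min(x1, x2)), .fmt(y), .fmt(max(abs(x2 - x1), 0.75)),
      .xmlEscape(nm[i])))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="8" class="gene-label">%s</text>',
      .fmt(min(x1, x2)), .fmt(y - 2), .xmlEscape(nm[i])))
  }
  out
}

#' Render the ideogram view
#'
#' Two horizontal chromosome rows (query above target) with one ribbon
#' connector per alignment that passes the scene filters (reciprocal best
#' only by default). Connectors are colored by target chromosome; flipped
#' chromosomes are drawn reversed, so reverse-orientation alignments to a
#' flipped chromosome render untwisted. Gene glyphs and name labels are
#' drawn when annotation is attached to the scene.
#'
#' @param scene a [SyntenyScene-class].
#' @return A single character string holding the SVG document.
#' @export
renderIdeogram <- function(scene) {
  width <- 1200L; height <- 420L
  qy <- 110; ty <- 290; h <- 18
  sel <- .sceneSegments(scene, "ideogram")
  segs <- sel$segments
  if (!is.null(scene@viewport)) {
    qInfo <- .viewportInfo(scene@queryInfo, scene@viewport$query)
    tInfo <- .viewportInfo(scene@targetInfo, scene@viewport$target)
  } else {
    qInfo <- scene@queryInfo; tInfo <- scene@targetInfo
  }
  ql <- .chromLayout(qInfo, 60, width - 80)
  tl <- .chromLayout(tInfo, 60, width - 80)
  svg <- .svgOpen(width, height)
  svg <- c(svg, sprintf(
    '<title>%s vs %s</title>', .xmlEscape(qInfo@assemblyId),
    .xmlEscape(tInfo@assemblyId)))
  tcolor <- setNames(rep_len(.palette, length(tl$ids)), tl$ids)
  if (!length(segs)) {
    warning("no alignments pass the scene filters")
    svg <- c(svg, sprintf(
      '<text x="%d" y="%d" text-anchor="middle" class="caption">%s</text>',
      width %/% 2L, height %/% 2L,
      "No alignments to display under the current filters"))
  } else {
    vp <- scene@viewport
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      qs <- s@qstart; qe <- s@qend; ts <- s@tstart; te <- s@tend
      if (!is.null(vp)) {
        qs <- max(qs, vp$query@start); qe <- min(qe, vp$query@end)
        pr <- projectToTarget(s, c(qs, qe))
        ts <- max(pr@start, vp$target@start); te <- min(pr@end, vp$target@end)
      }
      qx1 <- .mapPos(ql, s@qname, qs, scene@flippedSequences)
      qx2 <- .mapPos(ql, s@qname, qe, scene@flippedSequences)
      flipTwist <- s@orientation == "reverse"
      tx1 <- .mapPos(tl, s@tname, if (flipTwist) te else ts,
                     scene@flippedSequences)
      tx2 <- .mapPos(tl, s@tname, if (flipTwist) ts else te,
                     scene@flippedSequences)
      svg <- c(svg, sprintf(
        paste0('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" ',
               'fill-opacity="0.55" stroke="none" class="connector" ',
               'data-orientation="%s" data-reciprocity="%d"/>'),
        .fmt(qx1), .fmt(qy + h), .fmt(qx2), .fmt(qy + h),
        .fmt(tx2), .fmt(ty), .fmt(tx1), .fmt(ty),
        tcolor[[s@tname]], s@orientation, sel$reciprocity[i]))
    }
  }
  svg <- c(svg,
    .chromRow(ql, qy, h, qInfo@assemblyName, scene@flippedSequences),
    .chromRow(tl, ty, h, tInfo@assemblyName, scene@flippedSequences),
    .ruler(ql, qy + h + 2), .ruler(tl, ty + h + 2))
  if (!is.null(scene@genes)) {
    svg <- c(svg, .geneGlyphs(scene@genes$query, ql, qy - 24,
                              scene@flippedSequences),
             .geneGlyphs(scene@genes$target, tl, ty + h + 14,
                         scene@flippedSequences))
  }
  paste(c(svg, "</svg>"), collapse = "\n")
}

## single-sequence catalogue restricted to a viewport range
.viewportInfo <- function(info, r) {
  AssemblyInfo(info@assemblyId, r@seqId, r@end, name = info@assemblyName)
}

#' Render the dotplot view
#'
#' Target coordinates on the X axis against query coordinates on the Y
#' axis, as a whole-genome grid of chromosome-pair cells (or a single-cell
#' zoom when the scene has a viewport). Forward alignments are drawn as
#' positive-slope green lines and reverse alignments as negative-slope
#' purple lines. The dotplot shows both reciprocal best-placed and
#' non-best placed alignments regardless of the scene's `includeNonBest`
#' setting; size and orientation filters still apply.
#'
#' @param scene a [SyntenyScene-class].
#' @return A single character string holding the SVG document.
#' @export
renderDotplot <- function(scene) {
  width <- 900L; height <- 700L
  x0 <- 90; y0 <- 40; plotW <- width - 130; plotH <- height - 120
  sel <- .sceneSegments(scene, "dotplot")
  segs <- sel$segments
  vp <- scene@viewport
  if (!is.null(vp)) {
    qInfo <- .viewportInfo(scene@queryInfo, vp$query)
    tInfo <- .viewportInfo(scene@targetInfo, vp$target)
  } else {
    qInfo <- scene@queryInfo; tInfo <- scene@targetInfo
  }
  tl <- .chromLayout(tInfo, x0, plotW, gap = 0)
  ## vertical layout reuses the horizontal helper, then maps to y
  qlay <- .chromLayout(qInfo, 0, plotH, gap = 0)
  mapY <- function(seqId, pos) {
    y0 + plotH - (qlay$x[[seqId]] - 0 +
                  pos / qlay$lens[match(seqId, qlay$ids)] *
                  qlay$w[[seqId]])
  }
  svg <- .svgOpen(width, height)
  svg <- c(svg, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="white" stroke="#333"/>',
                        .fmt(x0), .fmt(y0), .fmt(plotW), .fmt(plotH)))
  ## cell boundaries
  for (id in tl$ids) {
    bx <- tl$x[[id]] + tl$w[[id]]
    svg <- c(svg, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#DDD" class="grid"/>',
      .fmt(bx), .fmt(y0), .fmt(bx), .fmt(y0 + plotH)))
    svg <- c(svg, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
      .fmt(tl$x[[id]] + tl$w[[id]] / 2), .fmt(y0 + plotH + 14),
      .xmlEscape(id)))
  }
  for (id in qlay$ids) {
    by <- mapY(id, 0)
    svg <- c(svg, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#DDD" class="grid"/>',
      .fmt(x0), .fmt(by), .fmt(x0 + plotW), .fmt(by)))
    svg <- c(svg, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="end">%s</text>',
      .fmt(x0 - 4), .fmt(mapY(id, qlay$lens[match(id, qlay$ids)] / 2) + 3),
      .xmlEscape(id)))
  }
  if (!length(segs)) {
    warning("no alignments pass the scene filters")
    svg <- c(svg, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" class="caption">%s</text>',
      .fmt(x0 + plotW / 2), .fmt(y0 + plotH / 2),
      "No alignments to display under the current filters"))
  } else {
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      qs <- s@qstart; qe <- s@qend; ts <- s@tstart; te <- s@tend
      if (!is.null(vp)) {
        qs <- max(qs, vp$query@start); qe <- min(qe, vp$query@end)
        ts <- max(ts, vp$target@start); te <- min(te, vp$target@end)
      }
      x1 <- .mapPos(tl, s@tname, ts); x2 <- .mapPos(tl, s@tname, te)
      if (s@orientation == "forward") {
        y1 <- mapY(s@qname, qs); y2 <- mapY(s@qname, qe)
        col <- .fwdColor
      } else {
        y1 <- mapY(s@qname, qe); y2 <- mapY(s@qname, qs)
        col <- .revColor
      }
      svg <- c(svg, sprintf(
        paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" ',
               'stroke-width="1.5" class="alignment" data-orientation="%s" ',
               'data-reciprocity="%d"/>'),
        .fmt(x1), .fmt(y1), .fmt(x2), .fmt(y2), col, s@orientation,
        sel$reciprocity[i]))
    }
  }
  svg <- c(svg, sprintf(
    '<text x="%s" y="%s" font-size="12" text-anchor="middle">%s</text>',
    .fmt(x0 + plotW / 2), .fmt(height - 8), .xmlEscape(tInfo@assemblyId)))
  svg <- c(svg, sprintf(
    paste0('<text x="14" y="%s" font-size="12" text-anchor="middle" ',
           'transform="rotate(-90 14 %s)">%s</text>'),
    .fmt(y0 + plotH / 2), .fmt(y0 + plotH / 2),
    .xmlEscape(qInfo@assemblyId)))
  paste(c(svg, "</svg>"), collapse = "\n")
}

#' Information-panel record for a segment
#'
#' The textual record behind the viewer's segment info panel: both
#' accessions with 1-based inclusive display coordinates, orientation,
#' percent identity, number of gaps and mismatches, alignment length and
#' reciprocity.
#'
#' @param segment an [AlignmentSegment-class].
#' @param reciprocity optional reciprocity code to report.
#' @return A named list.
#' @export
segmentInfo <- function(segment, reciprocity = NA_integer_) {
  list(query_accession = segment@qname,
       query_assembly = segment@qassembly,
       query_start = segment@qstart + 1,
       query_end = segment@qend,
       target_accession = segment@tname,
       target_assembly = segment@tassembly,
       target_start = segment@tstart + 1,
       target_end = segment@tend,
       orientation = segment@orientation,
       percent_identity = percentIdentity(segment),
       gap_count = segment@gapCount,
       mismatches = segment@mismatches,
       alignment_length = alignmentLength(segment),
       reciprocity = as.integer(reciprocity))
}

#' Write an SVG document to a file
#' @param svg character scalar returned by a renderer.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeSVG <- function(svg, path) {
  writeLines(svg, path, useBytes = TRUE)
  invisible(path)
}
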