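## GFF3 export/import of processed alignment sets, and gene/CDS ingest.

.gff3Escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a ranked alignment set as GFF3
#'
#' One `match` feature per segment, anchored on the target assembly in
#' 1-based closed coordinates. The `Target` attribute carries the query
#' placement (1-based coordinates plus strand), and writer-defined
#' attributes carry identity, gap/mismatch counts, the reciprocity code
#' and the exact block structure (`blocks=qstart:tstart:length,...`,
#' 0-based), so [readGFF3Alignments()] round-trips losslessly. Features
#' are ordered by (target sequence, start, rank).
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeGFF3 <- function(ranked, path) {
  segs <- ranked@segments
  recip <- ranked@reciprocity
  lines <- "##gff-version 3"
  qi <- ranked@queryInfo; ti <- ranked@targetInfo
  if (!is.null(qi))
    lines <- c(lines, sprintf("#!query-assembly %s", qi@assemblyId))
  if (!is.null(ti)) {
    lines <- c(lines, sprintf("#!target-assembly %s", ti@assemblyId),
               sprintf("##sequence-region %s 1 %g", ti@seqs$seq_id,
                       ti@seqs$length))
  }
  if (length(segs)) {
    ord <- order(vapply(segs, slot, "", "tname"),
                 vapply(segs, slot, 0, "tstart"), seq_along(segs))
    segs <- segs[ord]; recip <- recip[ord]
    feat <- vapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      blocks <- paste(sprintf("%g:%g:%g", s@blocks[, 1L], s@blocks[, 2L],
                              s@blocks[, 3L]), collapse = ",")
      attrs <- sprintf(paste0(
        "ID=align%d;Target=%s %g %g %s;pct_identity=%.4f;matches=%g;",
        "mismatches=%g;gap_count=%g;gap_bases=%g;reciprocity=%d;blocks=%s"),
        i, .gff3Escape(s@qname), s@qstart + 1, s@qend,
        if (s@orientation == "forward") "+" else "-",
        percentIdentity(s), s@matches, s@mismatches, s@gapCount, s@gapBases,
        recip[i], blocks)
      if (s@lowres) attrs <- paste0(attrs, ";low_resolution=true")
      sprintf("%s\tSyntenyViews\tmatch\t%g\t%g\t%.4f\t+\t.\t%s",
              .gff3Escape(s@tname), s@tstart + 1, s@tend,
              percentIdentity(s), attrs)
    }, "")
    lines <- c(lines, feat)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked alignment set back from GFF3
#'
#' Inverse of [writeGFF3()]: reconstructs segments (including block
#' structure) and reciprocity codes from the writer's attribute set.
#'
#' @param path a GFF3 file produced by [writeGFF3()].
#' @return A [RankedAlignmentSet-class] (assembly catalogues are rebuilt
#'   from the `##sequence-region` pragmas when present).
#' @export
readGFF3Alignments <- function(path) {
  lines <- readLines(path)
  qasm <- sub("^#!query-assembly ", "",
              grep("^#!query-assembly ", lines, value = TRUE))
  tasm <- sub("^#!target-assembly ", "",
              grep("^#!target-assembly ", lines, value = TRUE))
  if (!length(qasm)) qasm <- ""
  if (!length(tasm)) tasm <- ""
  regions <- grep("^##sequence-region ", lines, value = TRUE)
  tInfo <- NULL
  if (length(regions) && nzchar(tasm)) {
    parts <- strsplit(sub("^##sequence-region ", "", regions), " ")
    tInfo <- AssemblyInfo(tasm, vapply(parts, `[`, "", 1L),
                          as.numeric(vapply(parts, `[`, "", 3L)))
  }
  feats <- lines[!startsWith(lines, "#") & nzchar(lines)]
  segs <- list(); recip <- integer(0)
  for (ln in feats) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) stop("malformed GFF3 feature line: ", ln)
    attrs <- strsplit(strsplit(f[9L], ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    a <- setNames(vapply(attrs, function(kv)
      paste(kv[-1L], collapse = "="), ""),
      vapply(attrs, `[`, "", 1L))
    tg <- strsplit(a[["Target"]], " ", fixed = TRUE)[[1L]]
    bl <- do.call(rbind, lapply(
      strsplit(strsplit(a[["blocks"]], ",", fixed = TRUE)[[1L]],
               ":", fixed = TRUE), as.numeric))
    colnames(bl) <- c("qstart", "tstart", "length")
    lowres <- identical(unname(a["low_resolution"]), "true")
    seg <- AlignmentSegment(tg[1L],
      qstart = if (lowres) as.numeric(tg[2L]) - 1 else NULL,
      qend = if (lowres) as.numeric(tg[3L]) else NULL,
      tname = f[1L],
      tstart = if (lowres) as.numeric(f[4L]) - 1 else NULL,
      tend = if (lowres) as.numeric(f[5L]) else NULL,
      orientation = if (tg[4L] == "+") "forward" else "reverse",
      blocks = bl, matches = as.numeric(a[["matches"]]),
      mismatches = as.numeric(a[["mismatches"]]),
      gapCount = as.numeric(a[["gap_count"]]),
      gapBases = as.numeric(a[["gap_bases"]]),
      qassembly = qasm, tassembly = tasm,
      sourceId = a[["ID"]], lowres = lowres)
    segs[[length(segs) + 1L]] <- seg
    recip <- c(recip, as.integer(a[["reciprocity"]]))
  }
  new("RankedAlignmentSet", segments = segs, reciprocity = recip,
      queryInfo = NULL, targetInfo = tInfo)
}

#' Read gene and CDS features from GFF3
#'
#' Imports `gene` and `CDS` features (via rtracklayer) and groups CDS
#' intervals under their parent genes. CDS rows whose parent chain does
#' not resolve to a known gene are skipped with a warning.
#'
#' @param path a GFF3 annotation file.
#' @return A list with `genes` (GRanges, metadata columns `gene_id`,
#'   `gene_name`) and `cds` (GRangesList parallel to `genes`).
#' @export
readGFF3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- as.character(gr$ID)
  type <- as.character(gr$type)
  isGene <- type == "gene"
  genes <- gr[isGene]
  geneIds <- as.character(genes$ID)
  geneNames <- if (!is.null(genes$Name)) as.character(genes$Name) else geneIds
  geneNames[is.na(geneNames)] <- geneIds[is.na(geneNames)]
  ## resolve each CDS to a gene ancestor (direct, or via one mRNA level)
  parentOf <- function(x) {
    idx <- match(x, ids)
    out <- rep(NA_character_, length(x))
    ok <- !is.na(idx)
    if (any(ok)) {
      p <- gr$Parent[idx[ok]]
      out[ok] <- vapply(p, function(v) if (length(v)) as.character(v[1L])
                        else NA_character_, "")
    }
    out
  }
  cdsGr <- gr[type == "CDS"]
  cdsParent <- vapply(cdsGr$Parent, function(v)
    if (length(v)) as.character(v[1L]) else NA_character_, "")
  anc <- cdsParent
  for (hop in 1:3) {
    unresolved <- !(anc %in% geneIds) & !is.na(anc)
    if (!any(unresolved)) break
    anc[unresolved] <- parentOf(anc[unresolved])
  }
  bad <- is.na(anc) | !(anc %in% geneIds)
  if (any(bad)) {
    warning(sum(bad), " CDS feature(s) with unresolvable parent skipped")
    cdsGr <- cdsGr[!bad]; anc <- anc[!bad]
  }
  cdsBy <- S4Vectors::split(cdsGr, factor(anc, levels = geneIds))
  names(genes) <- geneIds
  genes$gene_id <- geneIds
  genes$gene_name <- geneNames
  list(genes = genes, cds = cdsBy)
}
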