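## Readers for the three raw alignment formats the pipeline ingests.
## All coordinates are normalized on ingest to the internal convention:
## 0-based half-open, forward strand, orientation as a segment flag.

#' Read pairwise alignments in PAF format
#'
#' One segment per line. With a `cg:Z:` CIGAR tag the block structure and
#' mismatch/gap statistics are exact; without it a single diagonal block
#' with the column-10 match count is synthesized and the segment is
#' flagged low-resolution (gap splitting then degrades to whole-segment
#' granularity; logged once per file).
#'
#' @param path file path (or connection) of a PAF file.
#' @param qassembly,tassembly assembly accessions recorded on segments.
#' @return List of [AlignmentSegment-class].
#' @export
readPAF <- function(path, qassembly = "", tassembly = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  segs <- vector("list", length(lines))
  anyLowres <- FALSE
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop(sprintf("PAF parse error at line %d: expected >= 12 columns", ln))
    num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
    if (anyNA(num))
      stop(sprintf("PAF parse error at line %d: non-numeric coordinate", ln))
    strand <- f[5L]
    if (!strand %in% c("+", "-"))
      stop(sprintf("PAF parse error at line %d: bad strand '%s'", ln, strand))
    qstart <- num[2L]; qend <- num[3L]
    tstart <- num[5L]; tend <- num[6L]; nmatch <- num[7L]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", f[-(1:12)], value = TRUE))
    orientation <- if (strand == "+") "forward" else "reverse"
    if (length(cg) == 1L) {
      dec <- .decodeCigar(cg, qstart, qend, tstart, orientation)
      ## M-only CIGARs carry no mismatch positions; reconcile counts with
      ## the column-10 match count
      if (dec$mismatches == 0 && nmatch < dec$matches) {
        dec$mismatches <- dec$matches - nmatch
        dec$matches <- nmatch
      }
      segs[[ln]] <- AlignmentSegment(f[1L], tname = f[6L],
        orientation = orientation, blocks = dec$blocks,
        matches = dec$matches, mismatches = dec$mismatches,
        qassembly = qassembly, tassembly = tassembly,
        sourceId = sprintf("paf:%d", ln))
    } else {
      anyLowres <- TRUE
      segs[[ln]] <- .lowresSegment(f[1L], qstart, qend, f[6L], tstart, tend,
        orientation, nmatch, qassembly, tassembly, sprintf("paf:%d", ln))
    }
  }
  if (anyLowres)
    message("PAF input without cg: CIGAR: block structure is approximate, ",
            "gap splitting degrades to whole-segment granularity")
  segs
}

## single-diagonal-block stand-in when per-column detail is unavailable
.lowresSegment <- function(qname, qstart, qend, tname, tstart, tend,
                           orientation, matches, qassembly, tassembly,
                           sourceId) {
  span <- min(qend - qstart, tend - tstart)
  matches <- min(matches, span)
  gapBases <- (qend - qstart - span) + (tend - tstart - span)
  AlignmentSegment(qname, qstart, qend, tname, tstart, tend,
    orientation = orientation,
    blocks = cbind(qstart, if (orientation == "forward") tstart
                   else tend - span, span),
    matches = matches, mismatches = span - matches,
    gapCount = as.numeric(gapBases > 0), gapBases = gapBases,
    qassembly = qassembly, tassembly = tassembly,
    sourceId = sourceId, lowres = gapBases > 0)
}

## Decode a minimap2-style CIGAR (= X M I D ops) into blocks + statistics.
## The target is consumed forward; the query forward for "+", backward
## from qend for "-". Blocks are maximal runs of aligned columns (= X M).
.decodeCigar <- function(cg, qstart, qend, tstart, orientation) {
  ops <- regmatches(cg, gregexpr("[0-9]+[=XMIDN]", cg))[[1L]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
    stop("malformed CIGAR string: ", cg)
  len <- as.numeric(sub("[=XMIDN]", "", ops))
  op <- sub("[0-9]+", "", ops)
  q <- if (orientation == "forward") qstart else qend
  t <- tstart
  mismatches <- 0
  blocks <- list(); run <- NULL  # run = c(qlo, tlo, len) of open aligned run
  flush <- function() {
    if (!is.null(run)) blocks[[length(blocks) + 1L]] <<- run
    run <<- NULL
  }
  for (i in seq_along(op)) {
    L <- len[i]
    if (op[i] %in% c("=", "X", "M")) {
      if (op[i] == "X") mismatches <- mismatches + L
      if (orientation == "forward") {
        if (is.null(run)) run <- c(q, t, 0)
        run[3L] <- run[3L] + L
        q <- q + L
      } else {
        q <- q - L
        if (is.null(run)) run <- c(q, t, L) else run <- c(q, run[2L], run[3L] + L)
      }
      t <- t + L
    } else if (op[i] == "I") {          # query-only bases
      flush()
      q <- q + if (orientation == "forward") L else -L
    } else {                            # D/N: target-only bases
      flush()
      t <- t + L
    }
  }
  flush()
  blocks <- do.call(rbind, blocks)
  colnames(blocks) <- c("qstart", "tstart", "length")
  list(blocks = blocks, matches = sum(blocks[, 3L]) - mismatches,
       mismatches = mismatches)
}

#' Read pairwise alignments in UCSC chain format
#'
#' One segment per chain. Reverse-strand query coordinates (counted from
#' the sequence end, per the chain convention) are normalized to the
#' forward strand; chains whose block sums disagree with the header
#' coordinates raise a parse error naming the chain id.
#'
#' @param path file path of a chain file.
#' @param qassembly,tassembly assembly accessions recorded on segments.
#' @return List of [AlignmentSegment-class].
#' @export
readChain <- function(path, qassembly = "", tassembly = "") {
  lines <- readLines(path)
  segs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    h <- strsplit(ln, "[ \t]+")[[1L]]
    if (h[1L] != "chain" || length(h) < 12L)
      stop(sprintf("chain parse error at line %d: bad header", i))
    tName <- h[3L]; tSize <- as.numeric(h[4L])
    tStart <- as.numeric(h[6L]); tEnd <- as.numeric(h[7L])
    qName <- h[8L]; qSize <- as.numeric(h[9L]); qStrand <- h[10L]
    qStart <- as.numeric(h[11L]); qEnd <- as.numeric(h[12L])
    chainId <- if (length(h) >= 13L) h[13L] else "?"
    if (h[5L] != "+")
      stop(sprintf("chain %s: target strand must be '+'", chainId))
    ## block triples until a bare size line
    sizes <- c(); dts <- c(); dqs <- c()
    repeat {
      i <- i + 1L
      if (i > length(lines))
        stop(sprintf("chain %s: truncated block list", chainId))
      b <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      if (length(b) == 1L && nzchar(b)) {
        sizes <- c(sizes, as.numeric(b)); dts <- c(dts, 0); dqs <- c(dqs, 0)
        break
      }
      if (length(b) != 3L)
        stop(sprintf("chain %s: bad block line %d", chainId, i))
      sizes <- c(sizes, as.numeric(b[1L]))
      dts <- c(dts, as.numeric(b[2L])); dqs <- c(dqs, as.numeric(b[3L]))
    }
    i <- i + 1L
    if (sum(sizes) + sum(dts) != tEnd - tStart ||
        sum(sizes) + sum(dqs) != qEnd - qStart)
      stop(sprintf("chain %s: block sums disagree with header", chainId))
    tpos <- tStart + cumsum(c(0, (sizes + dts)[-length(sizes)]))
    qpos <- qStart + cumsum(c(0, (sizes + dqs)[-length(sizes)]))
    if (qStrand == "+") {
      blocks <- cbind(qpos, tpos, sizes)
      orientation <- "forward"
    } else {
      blocks <- cbind(qSize - qpos - sizes, tpos, sizes)
      orientation <- "reverse"
    }
    colnames(blocks) <- c("qstart", "tstart", "length")
    segs[[length(segs) + 1L]] <- AlignmentSegment(qName, tname = tName,
      orientation = orientation, blocks = blocks,
      matches = sum(sizes), mismatches = 0,
      qassembly = qassembly, tassembly = tassembly,
      sourceId = sprintf("chain:%s", chainId))
  }
  segs
}

#' Read pairwise alignments in tabular BLAST format
#'
#' Expects outfmt-6 columns `qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send` (evalue/bitscore tolerated), optionally with a
#' 13th `btop` column from which exact blocks are reconstructed. BLAST's
#' 1-based inclusive coordinates are converted; `sstart > send` encodes
#' reverse orientation.
#'
#' @param path file path of a BLAST tabular file.
#' @param qassembly,tassembly assembly accessions recorded on segments.
#' @return List of [AlignmentSegment-class].
#' @export
readBlastTab <- function(path, qassembly = "", tassembly = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  segs <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L)
      stop(sprintf("BLAST parse error at line %d: expected >= 10 columns", ln))
    num <- suppressWarnings(as.numeric(f[3:10]))
    if (anyNA(num))
      stop(sprintf("BLAST parse error at line %d: non-numeric field", ln))
    alen <- num[2L]; mism <- num[3L]
    qstart <- num[5L] - 1; qend <- num[6L]
    sstart <- num[7L]; send <- num[8L]
    if (sstart <= send) {
      orientation <- "forward"; tstart <- sstart - 1; tend <- send
    } else {
      orientation <- "reverse"; tstart <- send - 1; tend <- sstart
    }
    btop <- if (length(f) >= 13L) f[13L] else NA_character_
    src <- sprintf("blast:%d", ln)
    if (!is.na(btop) && grepl("^([0-9]+|[A-Za-z-]{2})+$", btop)) {
      dec <- .decodeBtop(btop, qstart, tstart, tend, orientation)
      segs[[ln]] <- AlignmentSegment(f[1L], tname = f[2L],
        orientation = orientation, blocks = dec$blocks,
        matches = dec$matches, mismatches = dec$mismatches,
        qassembly = qassembly, tassembly = tassembly, sourceId = src)
    } else {
      aligned <- (qend - qstart) + (tend - tstart) - alen
      matches <- aligned - mism
      gapBases <- alen - aligned
      if (gapBases == 0) {
        segs[[ln]] <- AlignmentSegment(f[1L], tname = f[2L],
          orientation = orientation,
          blocks = cbind(qstart, tstart, aligned),
          matches = matches, mismatches = mism,
          qassembly = qassembly, tassembly = tassembly, sourceId = src)
      } else {
        seg <- .lowresSegment(f[1L], qstart, qend, f[2L], tstart, tend,
          orientation, matches, qassembly, tassembly, src)
        segs[[ln]] <- seg
      }
    }
  }
  segs
}

## BLAST trace-back operations: numbers are match runs; letter pairs are
## (query char, subject char) - base/base = mismatch column, base/'-' =
## subject gap, '-'/base = query gap. Query always walks forward;
## the subject walks backward from its high end for reverse hits.
.decodeBtop <- function(btop, qstart, tstart, tend, orientation) {
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Za-z-]{2}", btop))[[1L]]
  q <- qstart
  t <- if (orientation == "forward") tstart else tend
  dirT <- if (orientation == "forward") 1 else -1
  mismatches <- 0
  blocks <- list(); run <- NULL
  addAligned <- function(L) {
    if (orientation == "forward") {
      if (is.null(run)) run <<- c(q, t, 0)
      run[3L] <<- run[3L] + L
      q <<- q + L; t <<- t + L
    } else {
      t <<- t - L
      if (is.null(run)) run <<- c(q, t, L)
      else run <<- c(run[1L], t, run[3L] + L)
      q <<- q + L
    }
  }
  flush <- function() {
    if (!is.null(run)) blocks[[length(blocks) + 1L]] <<- run
    run <<- NULL
  }
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      addAligned(as.numeric(tok))
    } else {
      a <- substr(tok, 1L, 1L); b <- substr(tok, 2L, 2L)
      if (a != "-" && b != "-") {
        mismatches <- mismatches + 1
        addAligned(1)
      } else if (b == "-") {        # query base over subject gap
        flush(); q <- q + 1
      } else {                      # subject base over query gap
        flush(); t <- t + dirT
      }
    }
  }
  flush()
  blocks <- do.call(rbind, blocks)
  colnames(blocks) <- c("qstart", "tstart", "length")
  list(blocks = blocks, matches = sum(blocks[, 3L]) - mismatches,
       mismatches = mismatches)
}

#' Read alignments with format auto-detection
#'
#' Sniffs the content: a `chain` header means chain format, a line whose
#' fifth column is a strand sign means PAF, otherwise tabular BLAST.
#'
#' @param path input file.
#' @param format `"auto"` (default), `"paf"`, `"chain"` or `"blast"`.
#' @param qassembly,tassembly assembly accessions recorded on segments.
#' @return List of [AlignmentSegment-class].
#' @export
readAlignments <- function(path, format = c("auto", "paf", "chain", "blast"),
                           qassembly = "", tassembly = "") {
  format <- match.arg(format)
  if (format == "auto") {
    probe <- readLines(path, n = 50L)
    probe <- probe[nzchar(trimws(probe))]
    format <- if (!length(probe)) "paf"
      else if (any(startsWith(trimws(probe), "chain "))) "chain"
      else {
        f <- strsplit(probe[1L], "\t", fixed = TRUE)[[1L]]
        if (length(f) >= 12L && f[5L] %in% c("+", "-")) "paf"
        else if (length(f) >= 10L) "blast"
        else stop("cannot auto-detect alignment format of ", path)
      }
  }
  switch(format,
    paf = readPAF(path, qassembly, tassembly),
    chain = readChain(path, qassembly, tassembly),
    blast = readBlastTab(path, qassembly, tassembly))
}
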