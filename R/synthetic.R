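## Simulated genome pairs with planted rearrangements and exact ground
## truth. The target genome is built as an ordered list of tiles copied
## from the query (optionally inverted, moved, duplicated or deleted),
## then point mutations and short indels are applied per tile while the
## exact block structure is tracked. Phase-two processing never reads
## sequence, so composition is deliberately uniform.

#' Construct a RearrangementPlan
#'
#' With `events = NULL` and at least five chromosomes the standard
#' validation scenario is planted: a 10\%-of-chromosome inversion on
#' chromosome 1, an 8\% translocation from chromosome 2 to 3, a 4\%
#' duplication from chromosome 4 into 2, and chromosome 5 scrambled into
#' 20 shuffled tiles.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param nChromosomes,chromosomeLength genome shape (default 5 x 1 Mb).
#' @param events event data.frame (see [RearrangementPlan-class]) or NULL.
#' @param snpRate,indelRate per-base mutation rates (defaults 0.005 and
#'   1e-4; indel lengths are 1-10 bp).
#' @return A [RearrangementPlan-class].
#' @examples
#' RearrangementPlan(seed = 7)
#' @export
RearrangementPlan <- function(seed = 1, nChromosomes = 5,
                              chromosomeLength = 1e6, events = NULL,
                              snpRate = 0.005, indelRate = 1e-4) {
  if (is.null(events)) {
    events <- if (nChromosomes >= 5) {
      L <- chromosomeLength
      data.frame(
        type = c("inversion", "translocation", "duplication", "scramble"),
        chrom = c(1, 2, 4, 5),
        start = c(round(0.4 * L), round(0.3 * L), round(0.5 * L), 0),
        size = c(round(0.1 * L), round(0.08 * L), round(0.04 * L), 20),
        dest_chrom = c(NA, 3, 2, NA),
        stringsAsFactors = FALSE)
    } else {
      data.frame(type = character(0), chrom = numeric(0),
                 start = numeric(0), size = numeric(0),
                 dest_chrom = numeric(0), stringsAsFactors = FALSE)
    }
  }
  new("RearrangementPlan", seed = as.numeric(seed),
      nChromosomes = as.numeric(nChromosomes),
      chromosomeLength = as.numeric(chromosomeLength),
      events = events, snpRate = as.numeric(snpRate),
      indelRate = as.numeric(indelRate))
}

setMethod("show", "RearrangementPlan", function(object) {
  cat(sprintf(
    "RearrangementPlan: seed %g, %g x %g bp, %d event(s), snp %g, indel %g\n",
    object@seed, object@nChromosomes, object@chromosomeLength,
    nrow(object@events), object@snpRate, object@indelRate))
})

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## ---- tile algebra ----------------------------------------------------------
## a tile is list(qchrom, qstart, qend, orient, dup)

.newTile <- function(qchrom, qstart, qend, orient = "forward", dup = FALSE)
  list(qchrom = qchrom, qstart = qstart, qend = qend, orient = orient,
       dup = dup)

## split every (forward) tile containing qpos on query chromosome `chrom`
.splitTilesAt <- function(tiles, chrom, qpos) {
  lapply(tiles, function(chromTiles) {
    out <- list()
    for (tl in chromTiles) {
      if (tl$qchrom == chrom && tl$qstart < qpos && qpos < tl$qend) {
        if (tl$orient != "forward")
          stop("plan events may not intersect an inverted region")
        out <- c(out, list(.newTile(tl$qchrom, tl$qstart, qpos,
                                    dup = tl$dup),
                           .newTile(tl$qchrom, qpos, tl$qend,
                                    dup = tl$dup)))
      } else out <- c(out, list(tl))
    }
    out
  })
}

## indices (chrom, pos) of tiles fully inside [s, e) on query chrom
.tilesInside <- function(tiles, chrom, s, e) {
  hits <- list()
  for (ci in seq_along(tiles)) {
    for (ti in seq_along(tiles[[ci]])) {
      tl <- tiles[[ci]][[ti]]
      if (tl$qchrom == chrom && tl$qstart >= s && tl$qend <= e && !tl$dup)
        hits[[length(hits) + 1L]] <- c(ci, ti)
    }
  }
  hits
}

.removeTiles <- function(tiles, hits) {
  taken <- list()
  byChrom <- split(vapply(hits, `[`, 0, 2L), vapply(hits, `[`, 0, 1L))
  for (ci in names(byChrom)) {
    ix <- sort(byChrom[[ci]])
    taken <- c(taken, tiles[[as.integer(ci)]][ix])
    tiles[[as.integer(ci)]] <- tiles[[as.integer(ci)]][-ix]
  }
  list(tiles = tiles, taken = taken)
}

.insertTiles <- function(tiles, destChrom, newTiles) {
  at <- sample(0:length(tiles[[destChrom]]), 1L)
  tiles[[destChrom]] <- append(tiles[[destChrom]], newTiles, after = at)
  tiles
}

## ---- simulation ------------------------------------------------------------

#' Simulate a rearranged genome pair with ground truth
#'
#' Generates a uniform-composition query genome, builds the target as a
#' tile-rearranged, mutated copy, and returns the exact orthologous
#' mapping as truth segments: reverse orientation for inversions,
#' cross-chromosome placement for translocations, one extra truth segment
#' (flagged `truth_dup`) for each duplication. Fully reproducible from
#' the plan seed.
#'
#' @param plan a [RearrangementPlan-class].
#' @return List with `query`/`target` (`DNAStringSet`), `queryInfo` /
#'   `targetInfo` ([AssemblyInfo-class]), `truth` (list of
#'   [AlignmentSegment-class]) and `events` (the plan's event table).
#' @export
simulatePair <- function(plan) {
  validObject(plan)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(plan@seed %% .Machine$integer.max)
  n <- plan@nChromosomes; L <- plan@chromosomeLength
  qnames <- paste0("Q", seq_len(n)); tnames <- paste0("T", seq_len(n))
  qseqs <- lapply(seq_len(n), function(i)
    sample(.BASES, L, replace = TRUE))
  names(qseqs) <- qnames

  tiles <- lapply(seq_len(n), function(i) list(.newTile(i, 0, L)))
  ev <- plan@events
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$type == "scramble") {
      chromTiles <- tiles[[e$chrom]]
      spans <- vapply(chromTiles, function(tl) tl$qend - tl$qstart, 0)
      nt <- max(2L, round(e$size))
      ## split the chromosome into nt roughly equal tiles, then shuffle
      bounds <- round(seq(0, sum(spans), length.out = nt + 1L))
      for (b in bounds[-c(1L, nt + 1L)])
        tiles <- .splitTilesAt(tiles, e$chrom, b)
      tiles[[e$chrom]] <- sample(tiles[[e$chrom]])
      next
    }
    s <- e$start; z <- e$start + e$size
    tiles <- .splitTilesAt(tiles, e$chrom, s)
    tiles <- .splitTilesAt(tiles, e$chrom, z)
    hits <- .tilesInside(tiles, e$chrom, s, z)
    if (e$type == "inversion") {
      for (h in hits) {
        tl <- tiles[[h[1L]]][[h[2L]]]
        tl$orient <- if (tl$orient == "forward") "reverse" else "forward"
        tiles[[h[1L]]][[h[2L]]] <- tl
      }
      ## reverse the order of the inverted tiles in place
      if (length(hits) > 1L) {
        ci <- hits[[1L]][1L]
        ix <- sort(vapply(hits, `[`, 0, 2L))
        tiles[[ci]][ix] <- tiles[[ci]][rev(ix)]
      }
    } else if (e$type == "deletion") {
      tiles <- .removeTiles(tiles, hits)$tiles
    } else if (e$type == "translocation") {
      rm <- .removeTiles(tiles, hits)
      tiles <- .insertTiles(rm$tiles, e$dest_chrom, rm$taken)
    } else if (e$type == "duplication") {
      copies <- lapply(.removeTiles(tiles, hits)$taken, function(tl) {
        tl$dup <- TRUE; tl
      })
      tiles <- .insertTiles(tiles, e$dest_chrom, copies)
    }
  }

  truth <- list()
  tseqs <- vector("list", n)
  for (ci in seq_len(n)) {
    offset <- 0
    pieces <- list()
    for (tl in tiles[[ci]]) {
      mut <- .mutateTile(qseqs[[tl$qchrom]], tl, plan)
      M <- length(mut$seq)
      prod <- mut$seq
      blocks <- mut$blocks   # columns: q_local, p_local, length
      if (tl$orient == "reverse") {
        prod <- rev(unname(.COMP[prod]))
        tloc <- offset + (M - (blocks[, 2L] + blocks[, 3L]))
      } else {
        tloc <- offset + blocks[, 2L]
      }
      segBlocks <- cbind(qstart = tl$qstart + blocks[, 1L],
                         tstart = tloc, length = blocks[, 3L])
      truth[[length(truth) + 1L]] <- AlignmentSegment(
        qnames[tl$qchrom], tname = tnames[ci], orientation = tl$orient,
        blocks = segBlocks,
        matches = sum(blocks[, 3L]) - mut$mismatches,
        mismatches = mut$mismatches,
        qassembly = "simQ", tassembly = "simT",
        sourceId = if (tl$dup) "truth_dup" else "truth")
      pieces[[length(pieces) + 1L]] <- prod
      offset <- offset + M
    }
    tseqs[[ci]] <- paste(vapply(pieces, paste, "", collapse = ""),
                         collapse = "")
  }
  query <- Biostrings::DNAStringSet(
    vapply(qseqs, paste, "", collapse = ""))
  names(query) <- qnames
  target <- Biostrings::DNAStringSet(unlist(tseqs))
  names(target) <- tnames
  list(query = query, target = target,
       queryInfo = AssemblyInfo("simQ", qnames, rep(L, n),
                                name = "simulated query"),
       targetInfo = AssemblyInfo("simT", tnames,
                                 Biostrings::width(target),
                                 name = "simulated target"),
       truth = truth, events = ev)
}

## Copy a query slice, apply SNPs and indels, and track the alignment
## block structure in tile-local coordinates (query offset, product
## offset, length).
.mutateTile <- function(qseq, tl, plan) {
  len <- tl$qend - tl$qstart
  bases <- qseq[(tl$qstart + 1):tl$qend]
  nSnp <- rbinom(1L, len, plan@snpRate)
  snpPos <- sort(sample.int(len, nSnp))
  if (nSnp) {
    shift <- sample.int(3L, nSnp, replace = TRUE)
    idx <- match(bases[snpPos], .BASES)
    bases[snpPos] <- .BASES[(idx - 1L + shift) %% 4L + 1L]
  }
  nInd <- rbinom(1L, len, plan@indelRate)
  out <- list(); blocks <- list()
  q <- 0; p <- 0
  if (nInd) {
    pos <- sort(sample.int(len - 1L, min(nInd, len - 1L)))
    sizes <- sample.int(10L, length(pos), replace = TRUE)
    isIns <- runif(length(pos)) < 0.5
    for (i in seq_along(pos)) {
      if (pos[i] <= q) next                       # overlapping a prior indel
      runLen <- pos[i] - q
      out[[length(out) + 1L]] <- bases[(q + 1):pos[i]]
      blocks[[length(blocks) + 1L]] <- c(q, p, runLen)
      p <- p + runLen; q <- pos[i]
      if (isIns[i]) {
        out[[length(out) + 1L]] <- sample(.BASES, sizes[i], replace = TRUE)
        p <- p + sizes[i]
      } else {
        q <- min(q + sizes[i], len - 1L)          # keep a trailing block
      }
    }
  }
  if (q < len) {
    out[[length(out) + 1L]] <- bases[(q + 1):len]
    blocks[[length(blocks) + 1L]] <- c(q, p, len - q)
  }
  blocks <- do.call(rbind, blocks)
  ## mismatches: SNPs falling inside retained aligned runs
  inBlock <- rep(FALSE, len)
  for (i in seq_len(nrow(blocks)))
    inBlock[(blocks[i, 1L] + 1):(blocks[i, 1L] + blocks[i, 3L])] <- TRUE
  list(seq = unlist(out), blocks = blocks, mismatches = sum(inBlock[snpPos]))
}

#' Fragment truth alignments into raw phase-one-like input
#'
#' Cuts truth segments into pieces, injects overlapping redundant pieces
#' and contained duplicates, and shuffles the order - the adversarial
#' input [processAlignments()] is expected to clean up. Reproducible from
#' the seed.
#'
#' @param truth list of [AlignmentSegment-class] (from [simulatePair()]).
#' @param seed integer seed.
#' @param nCuts number of random cut points distributed over the truth
#'   segments (weighted by length).
#' @param overlapFraction fraction of pieces to add again as overlapping
#'   redundant sub-alignments.
#' @param duplicateFraction fraction of pieces to add again as strictly
#'   contained duplicates.
#' @return List of [AlignmentSegment-class], shuffled.
#' @export
fragmentAlignments <- function(truth, seed = 1, nCuts = 0,
                               overlapFraction = 0, duplicateFraction = 0) {
  if (!length(truth)) stop("truth must be non-empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  pieces <- truth
  for (k in seq_len(nCuts)) {
    w <- vapply(pieces, alignmentLength, 0)
    cuttable <- which(w >= 4)
    if (!length(cuttable)) break
    i <- sample(cuttable, 1L, prob = w[cuttable])
    s <- pieces[[i]]
    pos <- s@qstart + sample.int(alignmentLength(s) - 2L, 1L)
    kids <- .cutSegment(s, pos, "query")
    pieces <- c(pieces[-i], kids)
  }
  subPiece <- function(seg, a, z) {
    kids <- .cutSegment(seg, c(a, z), "query")
    qs <- vapply(kids, slot, 0, "qstart")
    qe <- vapply(kids, slot, 0, "qend")
    kids[[which(qs < z & qe > a)[1L]]]
  }
  nOv <- round(overlapFraction * length(pieces))
  for (k in seq_len(nOv)) {
    src <- truth[[sample.int(length(truth), 1L)]]
    span <- alignmentLength(src)
    if (span < 10) next
    sz <- min(span - 2, sample(1000:20000, 1L))
    a <- src@qstart + sample.int(span - sz, 1L)
    pieces[[length(pieces) + 1L]] <- subPiece(src, a, a + sz)
  }
  nDup <- round(duplicateFraction * length(pieces))
  for (k in seq_len(nDup)) {
    src <- pieces[[sample.int(length(pieces), 1L)]]
    span <- alignmentLength(src)
    if (span < 8) next
    a <- src@qstart + max(1, round(span * 0.25))
    z <- src@qend - max(1, round(span * 0.25))
    if (z - a < 2) next
    pieces[[length(pieces) + 1L]] <- subPiece(src, a, z)
  }
  for (i in seq_along(pieces)) pieces[[i]]@sourceId <- sprintf("frag%d", i)
  pieces[sample.int(length(pieces))]
}
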