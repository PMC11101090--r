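# Builders shared across the suite: toy segments, random instances for
# property tests, and the brute-force reciprocity oracle.

seg <- function(qname = "q1", qstart, qend, tname = "t1", tstart, tend,
                orientation = "forward", mismatches = 0, ...) {
  AlignmentSegment(qname, qstart, qend, tname, tstart, tend,
                   orientation = orientation, mismatches = mismatches, ...)
}

# a two-block segment with given junction gaps (query-side, target-side)
gappedSeg <- function(qstart = 0, span = 10000, qgap = 0, tgap = 0,
                      firstLen = round(span / 2), qname = "q1",
                      tname = "t1", tstart = 0, mismatches = 0) {
  l2 <- span - firstLen - qgap
  blocks <- rbind(c(qstart, tstart, firstLen),
                  c(qstart + firstLen + qgap, tstart + firstLen + tgap, l2))
  AlignmentSegment(qname, tname = tname, blocks = blocks,
                   mismatches = mismatches)
}

toyInfo <- function(id = "asm", seqs = c(q1 = 10000, t1 = 10000),
                    roles = "chromosome") {
  AssemblyInfo(id, names(seqs), unname(seqs), roles)
}

# random single-block instances on a small coordinate grid; overlaps and
# nesting are frequent by construction
randomInstance <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:10, 1)
  lapply(seq_len(n), function(i) {
    qlen <- sample(10:200, 1)
    tlen <- qlen
    qs <- sample(0:800, 1)
    ts <- sample(0:800, 1)
    AlignmentSegment(sample(c("q1", "q2"), 1), qs, qs + qlen,
                     sample(c("t1", "t2"), 1), ts, ts + tlen,
                     orientation = sample(c("forward", "reverse"), 1),
                     mismatches = sample(0:5, 1))
  })
}

# random multi-block segment with internal gaps, for conservation tests
randomGappedSegment <- function() {
  nb <- sample(2:5, 1)
  q <- sample(0:100, 1); t <- sample(0:100, 1)
  blocks <- matrix(0, nb, 3)
  for (b in seq_len(nb)) {
    len <- sample(5:80, 1)
    blocks[b, ] <- c(q, t, len)
    q <- q + len + sample(0:120, 1)
    t <- t + len + sample(0:120, 1)
  }
  AlignmentSegment("q1", tname = "t1", blocks = blocks,
                   mismatches = sample(0:3, 1))
}

totalMatches <- function(segs) sum(vapply(segs, slot, 0, "matches"))

# Independent greedy oracle: two passes over the rank-ordered segments,
# each claiming intervals on one axis; reciprocity 3 = wins both claims.
# Works on plain tuples, not on the pipeline's segment machinery.
oracleRecip3 <- function(rankedSegs) {
  df <- data.frame(
    qn = vapply(rankedSegs, slot, "", "qname"),
    qs = vapply(rankedSegs, slot, 0, "qstart"),
    qe = vapply(rankedSegs, slot, 0, "qend"),
    tn = vapply(rankedSegs, slot, "", "tname"),
    ts = vapply(rankedSegs, slot, 0, "tstart"),
    te = vapply(rankedSegs, slot, 0, "tend"))
  claimAxis <- function(nm, s, e) {
    claimed <- data.frame(nm = character(0), s = numeric(0), e = numeric(0))
    won <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      hit <- claimed$nm == nm[i] & claimed$s < e[i] & s[i] < claimed$e
      if (!any(hit)) {
        won[i] <- TRUE
        claimed <- rbind(claimed,
                         data.frame(nm = nm[i], s = s[i], e = e[i]))
      }
    }
    won
  }
  qwon <- claimAxis(df$qn, df$qs, df$qe)
  twon <- claimAxis(df$tn, df$ts, df$te)
  which(qwon & twon)
}

segSignature <- function(s)
  paste(s@qname, s@qstart, s@qend, s@tname, s@tstart, s@tend,
        s@orientation)
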