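test_that("adjacent collinear alignments merge and sum their statistics", {
  a <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  b <- seg(qstart = 110, qend = 200, tstart = 112, tend = 202)
  out <- mergeAdjacent(list(a, b), ProcessingParams(mergeMaxGap = 50))
  expect_length(out, 1)
  m <- out[[1]]
  expect_equal(c(m@qstart, m@qend), c(0, 200))
  expect_equal(c(m@tstart, m@tend), c(0, 202))
  # gap bases grow by the 10 bp query-side and 12 bp target-side gaps
  expect_equal(m@gapBases, 22)
  expect_equal(m@matches, 190)

  # a third segment aligning part of the intervening query interval
  # elsewhere is a conflict: no merge
  c3 <- seg(qstart = 102, qend = 108, tname = "t2", tstart = 0, tend = 6)
  out <- mergeAdjacent(list(a, b, c3), ProcessingParams(mergeMaxGap = 50))
  expect_length(out, 3)

  # opposite orientations never merge
  brev <- seg(qstart = 110, qend = 200, tstart = 112, tend = 202,
              orientation = "reverse")
  out <- mergeAdjacent(list(a, brev), ProcessingParams(mergeMaxGap = 50))
  expect_length(out, 2)
})

test_that("reverse-orientation collinear runs merge too", {
  # query ascending, target descending: a reverse diagonal cut in two
  a <- AlignmentSegment("q1", tname = "t1", orientation = "reverse",
                        blocks = cbind(0, 200, 100))
  b <- AlignmentSegment("q1", tname = "t1", orientation = "reverse",
                        blocks = cbind(110, 80, 100))
  out <- mergeAdjacent(list(a, b), ProcessingParams(mergeMaxGap = 50))
  expect_length(out, 1)
  expect_equal(out[[1]]@orientation, "reverse")
  expect_equal(c(out[[1]]@qstart, out[[1]]@qend), c(0, 210))
  expect_equal(c(out[[1]]@tstart, out[[1]]@tend), c(80, 300))
})

test_that("gap splitting applies the min(absolute, fractional) threshold", {
  p <- ProcessingParams("same_or_close")
  # 10 kb span: fractional 5% = 500, absolute 50 binds
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 60), p), 2)
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 40), p), 1)
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 50), p), 2)

  # distant mode, 10 kb span: 5% = 500 binds before 50 kb
  pd <- ProcessingParams("distant")
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 600), pd), 2)
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 400), pd), 1)

  # the junction gap is the max of query- and target-side gaps
  expect_length(splitOnGaps(gappedSeg(span = 10000, qgap = 0, tgap = 60),
                            p), 2)
})

test_that("gap splitting conserves matched bases and recomputes gaps", {
  s <- gappedSeg(span = 10000, qgap = 60, tgap = 10, mismatches = 7)
  kids <- splitOnGaps(s, ProcessingParams())
  expect_equal(totalMatches(kids), s@matches)
  expect_equal(sum(vapply(kids, slot, 0, "mismatches")), s@mismatches)
  # children have no internal junctions left
  expect_true(all(vapply(kids, function(k) k@gapBases, 0) == 0))
})

test_that("overlap splitting cuts both segments at projected boundaries", {
  a <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  b <- seg(qstart = 50, qend = 150, tstart = 300, tend = 400)
  out <- splitAtOverlaps(list(a, b))
  spans <- sort(vapply(out, function(s) paste(s@qstart, s@qend), ""))
  expect_equal(spans, c("0 50", "100 150", "50 100", "50 100"))

  # disjoint segments are untouched
  d1 <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  d2 <- seg(qstart = 200, qend = 300, tstart = 200, tend = 300)
  expect_length(splitAtOverlaps(list(d1, d2)), 2)

  # nesting cuts the outer segment into three pieces
  outer <- seg(qstart = 0, qend = 300, tstart = 0, tend = 300)
  inner <- seg(qstart = 100, qend = 200, tname = "t2", tstart = 0,
               tend = 100)
  out <- splitAtOverlaps(list(outer, inner))
  expect_length(out, 4)
  pieces <- vapply(out, function(s) paste(s@qstart, s@qend), "")
  expect_setequal(pieces[vapply(out, slot, "", "tname") == "t1"],
                  c("0 100", "100 200", "200 300"))
})

test_that("after overlap splitting, same-axis overlaps are range-identical", {
  set.seed(21)
  for (rep in 1:40) {
    out <- splitAtOverlaps(randomInstance())
    qn <- vapply(out, slot, "", "qname")
    qs <- vapply(out, slot, 0, "qstart"); qe <- vapply(out, slot, 0, "qend")
    tn <- vapply(out, slot, "", "tname")
    ts <- vapply(out, slot, 0, "tstart"); te <- vapply(out, slot, 0, "tend")
    for (i in seq_along(out)) for (j in seq_len(i - 1L)) {
      if (qn[i] == qn[j] && qs[i] < qe[j] && qs[j] < qe[i])
        expect_true(qs[i] == qs[j] && qe[i] == qe[j])
      if (tn[i] == tn[j] && ts[i] < te[j] && ts[j] < te[i])
        expect_true(ts[i] == ts[j] && te[i] == te[j])
    }
  }
})

test_that("contained duplicates and dominated segments are dropped", {
  a <- seg(qstart = 0, qend = 200, tstart = 0, tend = 200)
  b <- seg(qstart = 50, qend = 100, tstart = 50, tend = 100,
           mismatches = 5)                      # nested both axes, worse
  expect_length(dropContained(list(a, b)), 1)

  # nested on the query only: retained
  c2 <- seg(qstart = 50, qend = 100, tstart = 500, tend = 550,
            mismatches = 5)
  expect_length(dropContained(list(a, c2)), 2)

  # exact duplicates keep one representative
  expect_length(dropContained(list(a, seg(qstart = 0, qend = 200,
                                          tstart = 0, tend = 200))), 1)

  # different orientation protects a nested segment
  brev <- AlignmentSegment("q1", tname = "t1", orientation = "reverse",
                           blocks = cbind(50, 50, 50), mismatches = 0)
  expect_length(dropContained(list(a, brev)), 2)
})

test_that("ranking prefers chromosomes, then identity, then length", {
  qInfo <- AssemblyInfo("qa", c("q1", "q2"), c(10000, 10000),
                        c("chromosome", "unplaced_scaffold"))
  tInfo <- AssemblyInfo("ta", c("t1", "t2"), c(10000, 10000),
                        c("chromosome", "unplaced_scaffold"))
  chrChr <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  chrScaf <- seg(qstart = 200, qend = 300, tname = "t2", tstart = 0,
                 tend = 100)
  out <- rankSort(list(chrScaf, chrChr), qInfo, tInfo)
  expect_equal(out[[1]]@tname, "t1")

  hi <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100,
            mismatches = 1)
  lo <- seg(qstart = 200, qend = 300, tstart = 200, tend = 300,
            mismatches = 5)
  expect_equal(rankSort(list(lo, hi))[[1]]@qstart, 0)

  # equal class and identity: longer first
  long <- seg(qstart = 0, qend = 400, tstart = 0, tend = 400)
  short <- seg(qstart = 500, qend = 600, tstart = 500, tend = 600)
  expect_equal(rankSort(list(short, long))[[1]]@qend, 400)

  # full tie: lower query start first
  s1 <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  s2 <- seg(qstart = 200, qend = 300, tstart = 200, tend = 300)
  expect_equal(rankSort(list(s2, s1))[[1]]@qstart, 0)
})

test_that("two-scan reciprocity separates best, one-sided and dominated", {
  # disjoint everywhere: both reciprocal best
  a <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  b <- seg(qstart = 200, qend = 300, tstart = 200, tend = 300)
  r <- assignReciprocity(list(a, b))
  expect_equal(sort(reciprocity(r)), c(3L, 3L))

  # shared query range, disjoint targets, a higher-ranked: a=3, b=2
  hi <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  lo <- seg(qstart = 0, qend = 100, tstart = 500, tend = 600,
            mismatches = 5)
  r <- assignReciprocity(list(lo, hi))
  expect_equal(reciprocity(r)[vapply(segments(r), slot, 0, "tstart") == 0], 3L)
  expect_equal(reciprocity(r)[vapply(segments(r), slot, 0, "tstart") == 500],
               2L)

  # dominated on both axes by distinct higher-ranked segments: discarded
  c1 <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  c2 <- seg(qstart = 200, qend = 300, tstart = 200, tend = 300,
            mismatches = 1)
  c3 <- seg(qstart = 0, qend = 100, tstart = 200, tend = 300,
            mismatches = 5)
  r <- assignReciprocity(list(c1, c2, c3))
  expect_equal(length(segments(r)), 2)
  expect_equal(r@dropped, 1)
})

test_that("re-merge stitches within a reciprocity class only", {
  a <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  b <- seg(qstart = 110, qend = 200, tstart = 110, tend = 200)
  rk <- new("RankedAlignmentSet", segments = list(a, b),
            reciprocity = c(3L, 3L))
  out <- remerge(rk, ProcessingParams())
  expect_length(segments(out), 1)
  expect_equal(reciprocity(out), 3L)

  rk2 <- new("RankedAlignmentSet", segments = list(a, b),
             reciprocity = c(3L, 2L))
  out2 <- remerge(rk2, ProcessingParams())
  expect_length(segments(out2), 2)

  one <- new("RankedAlignmentSet", segments = list(a), reciprocity = 3L)
  expect_length(segments(remerge(one)), 1)
})

test_that("the pipeline composes: collinear toys, duplications, empties", {
  # three conflict-free collinear segments end as one reciprocity-3 run
  s1 <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  s2 <- seg(qstart = 110, qend = 200, tstart = 110, tend = 200)
  s3 <- seg(qstart = 210, qend = 300, tstart = 210, tend = 300)
  r <- processAlignments(list(s1, s2, s3), quiet = TRUE)
  expect_length(segments(r), 1)
  expect_equal(reciprocity(r), 3L)
  expect_equal(segments(r)[[1]]@qend, 300)

  # a duplication: one query region aligned to two target regions gives
  # one reciprocal-best and one non-best segment
  dup1 <- seg(qstart = 0, qend = 100, tstart = 0, tend = 100)
  dup2 <- seg(qstart = 0, qend = 100, tstart = 500, tend = 600,
              mismatches = 2)
  r <- processAlignments(list(dup1, dup2), quiet = TRUE)
  expect_equal(sort(reciprocity(r)), c(2L, 3L))

  r0 <- processAlignments(list(), quiet = TRUE)
  expect_length(segments(r0), 0)

  # unknown sequences are a validation error listing offenders
  info <- toyInfo(seqs = c(q1 = 10000))
  expect_error(processAlignments(list(seg(qstart = 0, qend = 10,
                                          qname = "qX", tstart = 0,
                                          tend = 10)),
                                 qInfo = info, quiet = TRUE), "qX")
})

test_that("processing is invariant under input permutation", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- randomInstance(8)
    r1 <- processAlignments(inst, quiet = TRUE)
    r2 <- processAlignments(inst[sample(length(inst))], quiet = TRUE)
    sig1 <- paste(vapply(segments(r1), segSignature, ""), reciprocity(r1))
    sig2 <- paste(vapply(segments(r2), segSignature, ""), reciprocity(r2))
    expect_equal(sort(sig1), sort(sig2))
  }
})

test_that("processing its own output is a fixpoint", {
  set.seed(32)
  for (rep in 1:10) {
    inst <- randomInstance(8)
    r1 <- processAlignments(inst, quiet = TRUE)
    r2 <- processAlignments(segments(r1), quiet = TRUE)
    sig1 <- sort(vapply(segments(r1), segSignature, ""))
    sig2 <- sort(vapply(segments(r2), segSignature, ""))
    expect_equal(sig2, sig1)
  }
})
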