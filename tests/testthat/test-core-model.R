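test_that("segment validity enforces the block and statistic invariants", {
  expect_error(AlignmentSegment("q", 0, 100, "t", 0, 100, matches = 90),
               "matches \\+ mismatches")
  expect_error(new("AlignmentSegment", qname = "q", qstart = 0, qend = 50,
                   tname = "t", tstart = 0, tend = 50,
                   orientation = "sideways",
                   blocks = cbind(0, 0, 50), matches = 50, mismatches = 0,
                   gapCount = 0, gapBases = 0, sourceId = "", lowres = FALSE,
                   qassembly = "", tassembly = ""),
               "orientation")
  # overlapping blocks rejected
  expect_error(AlignmentSegment("q", tname = "t",
                                blocks = rbind(c(0, 0, 60), c(50, 70, 60))),
               "overlap")
  # reverse-orientation blocks must descend on the target
  expect_silent(AlignmentSegment("q", tname = "t", orientation = "reverse",
                                 blocks = rbind(c(0, 100, 50), c(60, 40, 50))))
  expect_error(AlignmentSegment("q", tname = "t", orientation = "reverse",
                                blocks = rbind(c(0, 0, 50), c(60, 60, 50))),
               "descend")
})

test_that("percent identity follows the alignment-column convention", {
  expect_equal(percentIdentity(seg(qstart = 0, qend = 100,
                                   tstart = 0, tend = 100)), 100)
  expect_equal(percentIdentity(seg(qstart = 0, qend = 100, tstart = 0,
                                   tend = 100, mismatches = 10)), 90)
  # matches=90, mismatches=5, gap_bases=5 -> 90 (arithmetic check:
  # 100 * 90 / (90 + 5 + 5))
  s <- gappedSeg(span = 100, qgap = 5, tgap = 0, firstLen = 50,
                 mismatches = 5)
  expect_equal(s@matches, 90)
  expect_equal(s@gapBases, 5)
  expect_equal(percentIdentity(s), 90)
})

test_that("projection walks blocks on both orientations", {
  fwd <- seg(qstart = 0, qend = 100, tstart = 500, tend = 600)
  p <- projectToTarget(fwd, c(10, 20))
  expect_equal(c(p@start, p@end), c(510, 520))

  rev <- AlignmentSegment("q1", tname = "t1", orientation = "reverse",
                          blocks = cbind(0, 500, 100))
  p <- projectToTarget(rev, c(0, 10))
  expect_equal(c(p@start, p@end), c(590, 600))

  # two blocks with a 30 bp target-side gap; interval spanning the gap
  # maps to a target interval that includes the 30 unaligned bases:
  # q[40,60) -> block1 tail t[540,550) + gap t[550,580) + block2 head
  # t[580,590)
  gap <- AlignmentSegment("q1", tname = "t1",
                          blocks = rbind(c(0, 500, 50), c(50, 580, 50)))
  p <- projectToTarget(gap, c(40, 60))
  expect_equal(c(p@start, p@end), c(540, 590))

  expect_error(projectToTarget(fwd, c(200, 300)), "no-overlap")
})

test_that("projection is an involution under orientation", {
  set.seed(11)
  for (rep in 1:25) {
    s <- randomGappedSegment()
    qlo <- s@qstart + sample.int(max(1, alignmentLength(s) - 2), 1) - 1
    qhi <- min(s@qend, qlo + sample.int(50, 1))
    tIv <- tryCatch(projectToTarget(s, c(qlo, qhi)), error = function(e) NULL)
    if (is.null(tIv)) next
    # project back through the mirrored segment (swap axes)
    mirrored <- AlignmentSegment(s@tname, tname = s@qname,
      orientation = s@orientation,
      blocks = if (s@orientation == "forward")
        cbind(s@blocks[, 2L], s@blocks[, 1L], s@blocks[, 3L])
      else cbind(s@blocks[nrow(s@blocks):1, 2L],
                 s@blocks[nrow(s@blocks):1, 1L],
                 s@blocks[nrow(s@blocks):1, 3L]),
      matches = s@matches, mismatches = s@mismatches)
    back <- projectToTarget(mirrored, c(tIv@start, tIv@end))
    # the round trip must cover every aligned base of the interval
    # (gap bases inside the interval need not survive)
    b <- s@blocks
    qAligned <- unlist(lapply(seq_len(nrow(b)), function(k) {
      a <- max(qlo, b[k, 1L]); z <- min(qhi, b[k, 1L] + b[k, 3L])
      if (a < z) c(a, z) else NULL
    }))
    expect_lte(back@start, min(qAligned))
    expect_gte(back@end, max(qAligned))
  }
})

test_that("0-based half-open and 1-based closed coordinates round-trip", {
  set.seed(12)
  for (rep in 1:50) {
    start0 <- sample(0:1000, 1)
    len <- sample(1:500, 1)
    end0 <- start0 + len
    # to GFF3 display convention and back
    start1 <- start0 + 1; end1 <- end0
    expect_equal(start1 - 1, start0)
    expect_equal(end1, end0)
    expect_equal(end1 - start1 + 1, len)
  }
})

test_that("accessors report span, ranges and info-panel fields", {
  s <- seg(qstart = 10, qend = 110, tstart = 200, tend = 300,
           orientation = "reverse", mismatches = 4)
  expect_equal(alignmentLength(s), 100)
  expect_equal(queryRange(s)@start, 10)
  expect_equal(targetRange(s)@end, 300)
  rec <- segmentInfo(s, 3L)
  expect_equal(rec$query_start, 11)      # 1-based display coordinates
  expect_equal(rec$query_end, 110)
  expect_equal(rec$orientation, "reverse")
  expect_equal(rec$mismatches, 4)
  expect_equal(rec$percent_identity, percentIdentity(s))
  expect_equal(rec$reciprocity, 3L)
})

test_that("assembly catalogues validate and answer lookups", {
  info <- AssemblyInfo("a1", c("c1", "s1"), c(1000, 500),
                       c("chromosome", "unplaced_scaffold"))
  expect_equal(seqLength(info, "s1"), 500)
  expect_equal(seqRole(info, c("c1", "s1")), c("chromosome",
                                               "unplaced_scaffold"))
  expect_equal(seqRole(NULL, "x"), "chromosome")
  expect_true(is.na(seqLength(info, "nope")))
  expect_error(AssemblyInfo("a", c("c1", "c1"), c(10, 20)), "duplicate")
})

test_that("processing parameter defaults follow the species mode", {
  same <- ProcessingParams()
  dist <- ProcessingParams("distant")
  expect_equal(same@gapSplitBp, 50)
  expect_equal(dist@gapSplitBp, 50000)
  expect_equal(same@gapSplitFrac, 0.05)
  expect_equal(same@mergeMaxGap, 50)
  expect_error(ProcessingParams(gapSplitFrac = 1.5), "gapSplitFrac")
})
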