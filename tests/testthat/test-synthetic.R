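# small plans keep the unit tests fast; the full-scale scenario runs in
# the acceptance suite

test_that("a zero-event, zero-rate plan yields identity truth", {
  plan <- RearrangementPlan(seed = 1, nChromosomes = 2,
                            chromosomeLength = 5000,
                            events = data.frame(), snpRate = 0,
                            indelRate = 0)
  sim <- simulatePair(plan)
  expect_equal(length(sim$truth), 2)
  for (i in 1:2) {
    s <- sim$truth[[i]]
    expect_equal(c(s@qstart, s@qend), c(0, 5000))
    expect_equal(s@orientation, "forward")
    expect_equal(s@mismatches, 0)
  }
  expect_equal(unname(as.character(sim$query)),
               unname(as.character(sim$target)))
})

test_that("an inversion yields exactly one reverse truth segment", {
  plan <- RearrangementPlan(seed = 2, nChromosomes = 1,
                            chromosomeLength = 50000,
                            events = data.frame(type = "inversion",
                                                chrom = 1, start = 10000,
                                                size = 10000,
                                                dest_chrom = NA),
                            snpRate = 0, indelRate = 0)
  sim <- simulatePair(plan)
  ori <- vapply(sim$truth, slot, "", "orientation")
  expect_equal(sum(ori == "reverse"), 1)
  inv <- sim$truth[[which(ori == "reverse")]]
  expect_equal(c(inv@qstart, inv@qend), c(10000, 20000))
  # the inverted target region is the reverse complement of the query
  qseq <- Biostrings::subseq(sim$query[["Q1"]], 10001, 20000)
  tseq <- Biostrings::subseq(sim$target[["T1"]], inv@tstart + 1, inv@tend)
  expect_equal(as.character(tseq),
               as.character(Biostrings::reverseComplement(qseq)))
})

test_that("translocation, duplication and deletion move truth as planned", {
  ev <- data.frame(
    type = c("translocation", "duplication", "deletion"),
    chrom = c(1, 1, 2),
    start = c(10000, 30000, 10000),
    size = c(5000, 4000, 3000),
    dest_chrom = c(2, 2, NA))
  plan <- RearrangementPlan(seed = 3, nChromosomes = 2,
                            chromosomeLength = 50000, events = ev,
                            snpRate = 0, indelRate = 0)
  sim <- simulatePair(plan)
  tn <- vapply(sim$truth, slot, "", "tname")
  qn <- vapply(sim$truth, slot, "", "qname")
  src <- vapply(sim$truth, slot, "", "sourceId")
  # translocated and duplicated tiles land on T2
  expect_true(any(qn == "Q1" & tn == "T2"))
  expect_equal(sum(src == "truth_dup"), 1)
  # the duplicated query region is covered by two truth segments
  qs <- vapply(sim$truth, slot, 0, "qstart")
  expect_equal(sum(qn == "Q1" & qs == 30000), 2)
  # the deleted region is in no truth segment
  qe <- vapply(sim$truth, slot, 0, "qend")
  del <- qn == "Q2" & qs < 13000 & qe > 10000
  expect_false(any(del))
  # target chromosome lengths reflect the moves (duplication copies,
  # it does not remove)
  expect_equal(seqLength(sim$targetInfo, "T1"), 50000 - 5000)
  expect_equal(seqLength(sim$targetInfo, "T2"), 50000 + 5000 + 4000 - 3000)
})

test_that("scrambling tiles one chromosome into shuffled truth segments", {
  plan <- RearrangementPlan(seed = 4, nChromosomes = 1,
                            chromosomeLength = 40000,
                            events = data.frame(type = "scramble",
                                                chrom = 1, start = 0,
                                                size = 20, dest_chrom = NA),
                            snpRate = 0, indelRate = 0)
  sim <- simulatePair(plan)
  expect_equal(length(sim$truth), 20)
  # the dotplot of the truth set confines 20 lines to the single cell
  rk <- new("RankedAlignmentSet", segments = sim$truth,
            reciprocity = rep(3L, 20),
            queryInfo = sim$queryInfo, targetInfo = sim$targetInfo)
  svg <- renderDotplot(SyntenyScene(rk))
  doc <- xml2::read_xml(svg); xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "//line[@class='alignment']"), 20)
  # truth tiles the query exactly once
  qs <- sort(vapply(sim$truth, slot, 0, "qstart"))
  qe <- sort(vapply(sim$truth, slot, 0, "qend"))
  expect_equal(qs[1], 0)
  expect_equal(qe[20], 40000)
  expect_equal(qs[-1], qe[-20])
})

test_that("mutation rates show up in truth statistics and sequences", {
  plan <- RearrangementPlan(seed = 5, nChromosomes = 1,
                            chromosomeLength = 20000,
                            events = data.frame(), snpRate = 0.01,
                            indelRate = 5e-4)
  sim <- simulatePair(plan)
  mm <- sum(vapply(sim$truth, slot, 0, "mismatches"))
  expect_gt(mm, 100)   # ~200 expected
  expect_lt(mm, 400)
  gaps <- sum(vapply(sim$truth, slot, 0, "gapBases"))
  expect_gt(gaps, 10)  # ~10 indels of 1-10 bp
  id <- percentIdentity(sim$truth[[1]])
  expect_gt(id, 97); expect_lt(id, 99.9)
})

test_that("simulation is deterministic from the seed", {
  p <- RearrangementPlan(seed = 9, nChromosomes = 2,
                         chromosomeLength = 10000)
  a <- simulatePair(p); b <- simulatePair(p)
  expect_identical(as.character(a$target), as.character(b$target))
  expect_equal(vapply(a$truth, segSignature, ""),
               vapply(b$truth, segSignature, ""))
  p2 <- RearrangementPlan(seed = 10, nChromosomes = 2,
                          chromosomeLength = 10000)
  expect_false(identical(as.character(simulatePair(p2)$query),
                         as.character(a$query)))
})

test_that("plan validation rejects out-of-bounds and overlapping events", {
  expect_error(RearrangementPlan(
    seed = 1, nChromosomes = 1, chromosomeLength = 1000,
    events = data.frame(type = "inversion", chrom = 1, start = 900,
                        size = 200, dest_chrom = NA)), "bounds")
  expect_error(RearrangementPlan(
    seed = 1, nChromosomes = 1, chromosomeLength = 10000,
    events = data.frame(type = c("inversion", "deletion"), chrom = 1,
                        start = c(1000, 1500), size = c(1000, 1000),
                        dest_chrom = NA)), "overlap")
})

test_that("fragmentation without cuts permutes the truth", {
  plan <- RearrangementPlan(seed = 6, nChromosomes = 2,
                            chromosomeLength = 10000)
  sim <- simulatePair(plan)
  frags <- fragmentAlignments(sim$truth, seed = 1, nCuts = 0)
  expect_equal(sort(vapply(frags, segSignature, "")),
               sort(vapply(sim$truth, segSignature, "")))
})

test_that("fragmentation plants cuts, overlaps and contained duplicates", {
  plan <- RearrangementPlan(seed = 7, nChromosomes = 2,
                            chromosomeLength = 50000,
                            events = data.frame(), snpRate = 0.002,
                            indelRate = 0)
  sim <- simulatePair(plan)
  frags <- fragmentAlignments(sim$truth, seed = 2, nCuts = 30,
                              overlapFraction = 0.2,
                              duplicateFraction = 0.2)
  expect_gt(length(frags), 32)
  # matched bases at least those of the truth (injected copies add more)
  expect_gte(totalMatches(frags), totalMatches(sim$truth))
  # at least one fragment strictly contained in another on both axes
  qs <- vapply(frags, slot, 0, "qstart"); qe <- vapply(frags, slot, 0, "qend")
  ts <- vapply(frags, slot, 0, "tstart"); te <- vapply(frags, slot, 0, "tend")
  qn <- vapply(frags, slot, "", "qname"); tn <- vapply(frags, slot, "", "tname")
  contained <- FALSE
  for (i in seq_along(frags)) {
    hit <- qn == qn[i] & tn == tn[i] & qs <= qs[i] & qe >= qe[i] &
      ts <= ts[i] & te >= te[i] &
      (qs < qs[i] | qe > qe[i] | ts < ts[i] | te > te[i])
    if (any(hit)) { contained <- TRUE; break }
  }
  expect_true(contained)
  # deterministic from the seed
  frags2 <- fragmentAlignments(sim$truth, seed = 2, nCuts = 30,
                               overlapFraction = 0.2,
                               duplicateFraction = 0.2)
  expect_equal(vapply(frags2, segSignature, ""),
               vapply(frags, segSignature, ""))
})

test_that("processing recovers a small simulated pair end to end", {
  plan <- RearrangementPlan(seed = 8, nChromosomes = 2,
                            chromosomeLength = 50000,
                            events = data.frame(
                              type = "inversion", chrom = 1,
                              start = 20000, size = 8000,
                              dest_chrom = NA),
                            snpRate = 0.005, indelRate = 1e-4)
  sim <- simulatePair(plan)
  frags <- fragmentAlignments(sim$truth, seed = 3, nCuts = 40,
                              overlapFraction = 0.1,
                              duplicateFraction = 0.1)
  r <- processAlignments(frags, sim$queryInfo, sim$targetInfo,
                         quiet = TRUE)
  best <- segments(r)[reciprocity(r) == 3L]
  expect_gte(totalMatches(best) / totalMatches(sim$truth), 0.95)
  ori <- vapply(best, slot, "", "orientation")
  inv <- best[ori == "reverse"]
  expect_gte(length(inv), 1)
  qs <- vapply(inv, slot, 0, "qstart"); qe <- vapply(inv, slot, 0, "qend")
  expect_gte(min(qs), 20000 - 100)
  expect_lte(max(qe), 28000 + 100)
})
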