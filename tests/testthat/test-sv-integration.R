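test_that("depth caller finds planted events and stays quiet on flat tracks", {
  flat <- CoverageTrack("chr1", 250L, rep(50, 4000))
  expect_length(callDepthCnvs(flat, baseDepth = 50), 0L)

  ev <- GRanges("chr1", IRanges(500001, 502000), copyNumber = 1L)
  trk <- simulateCoverage(ev, 1e6, binSize = 250, baseDepth = 50, seed = 31)
  calls <- callDepthCnvs(trk, baseDepth = 50)
  expect_length(calls, 1L)
  expect_equal(mcols(calls)$svtype, "DEL")
  expect_lte(abs(start(calls) - 500001), 250L)       # within one bin
  expect_lte(abs(end(calls) - 502000), 250L)
  expect_equal(mcols(calls)$copyNumber, 1L)

  ev0 <- GRanges("chr1", IRanges(500001, 504000), copyNumber = 0L)
  trk0 <- simulateCoverage(ev0, 1e6, binSize = 250, baseDepth = 50, seed = 32)
  calls0 <- callDepthCnvs(trk0, baseDepth = 50)
  expect_equal(mcols(calls0)$copyNumber, 0L)
  expect_error(callDepthCnvs(trk0, baseDepth = 0), "> 0")
})

test_that("probe segmenter requires supported runs beyond the threshold", {
  quiet <- ProbeSet("chr1", seq(1000, 50000, by = 1000), rep(0.01, 50))
  expect_length(segmentProbes(quiet), 0L)

  v <- rep(0, 50); v[20:29] <- -1
  pr <- ProbeSet("chr1", seq(1000, 50000, by = 1000), v)
  calls <- segmentProbes(pr)
  expect_length(calls, 1L)
  expect_equal(mcols(calls)$svtype, "DEL")
  expect_equal(start(calls), 20000)
  expect_equal(end(calls), 29000)
  expect_equal(mcols(calls)$copyNumber, 1L)

  v2 <- rep(0, 50); v2[20:21] <- -1                  # below min_probes
  expect_length(segmentProbes(ProbeSet("chr1", seq(1000, 50000, 1000), v2)), 0L)
  expect_error(ProbeSet("chr1", c(5, 3, 9), c(0, 0, 0)), "increasing")
})

test_that("cross-sample consensus matches brute force and ignores sample order", {
  set.seed(9)
  for (rep in 1:30) {
    sets <- lapply(1:3, function(i) randomCallsetDf(sample(2:6, 1L)))
    mine <- consensusAcrossSamples(lapply(sets, dfToCalls),
                                   minReciprocalOverlap = 0.5)
    ref <- naiveConsensus(sets, 0.5)
    mineDf <- unique(data.frame(start = start(mine), end = end(mine),
                                svtype = mcols(mine)$svtype))
    refDf <- unique(ref[order(ref$start, ref$end, ref$svtype), ])
    rownames(mineDf) <- rownames(refDf) <- NULL
    expect_equal(mineDf, refDf[order(refDf$start, refDf$end, refDf$svtype), ],
                 ignore_attr = TRUE)
    ## permuting samples changes nothing
    perm <- consensusAcrossSamples(lapply(sets[c(3, 1, 2)], dfToCalls),
                                   minReciprocalOverlap = 0.5)
    expect_equal(start(mine), start(perm))
    expect_equal(end(mine), end(perm))
  }
})

test_that("consensus boundary behavior follows the support rule", {
  same <- dfToCalls(data.frame(start = 100, end = 600, svtype = "DEL"))
  cons <- consensusAcrossSamples(list(same, same, same, same, same))
  expect_length(cons, 1L)
  expect_equal(mcols(cons)$nSupport, 5L)

  missingOne <- list(same, same, same, same, dfToCalls(randomCallsetDf(1L))[0])
  expect_length(consensusAcrossSamples(missingOne), 0L)

  ## exactly 60% reciprocal overlap at a 50% threshold is retained
  a <- dfToCalls(data.frame(start = 1, end = 100, svtype = "DEL"))
  b <- dfToCalls(data.frame(start = 41, end = 140, svtype = "DEL"))
  expect_equal(reciprocalOverlap(1, 100, 41, 140), 0.6)
  expect_length(consensusAcrossSamples(list(a, b)), 1L)
  expect_error(consensusAcrossSamples(list()), "empty")
})

test_that("three-way overlap assigns each merged event one Venn region", {
  one <- dfToCalls(data.frame(start = 100, end = 500, svtype = "DEL"))
  vn <- threewayOverlap(one, one, one)
  expect_equal(unname(vn["all_three"]), 1L)
  expect_equal(sum(vn), 1L)

  d1 <- dfToCalls(data.frame(start = 100, end = 200, svtype = "DEL"))
  d2 <- dfToCalls(data.frame(start = 1000, end = 1100, svtype = "DEL"))
  d3 <- dfToCalls(data.frame(start = 5000, end = 5100, svtype = "DEL"))
  vn2 <- threewayOverlap(d1, d2, d3)
  expect_equal(unname(vn2[c("acgh_only", "depth_only", "pairedend_only")]),
               c(1L, 1L, 1L))
  expect_equal(sum(vn2), 3L)

  ## planted sharing structure: 2 in all three, 1 acgh+depth, 1 depth only
  shared <- data.frame(start = c(100, 9000), end = c(600, 9700),
                       svtype = "DEL")
  ad <- data.frame(start = 3000, end = 3400, svtype = "DUP")
  dOnly <- data.frame(start = 6000, end = 6200, svtype = "DEL")
  vn3 <- threewayOverlap(dfToCalls(rbind(shared, ad)),
                         dfToCalls(rbind(shared, ad, dOnly)),
                         dfToCalls(shared))
  expect_equal(unname(vn3["all_three"]), 2L)
  expect_equal(unname(vn3["acgh_depth"]), 1L)
  expect_equal(unname(vn3["depth_only"]), 1L)
  expect_equal(sum(vn3), 4L)                         # Venn conservation
})

test_that("complexity classification counts overlapping depth calls", {
  acgh <- dfToCalls(data.frame(start = 1000, end = 9000, svtype = "DEL"),
                    source = "acgh")
  one <- dfToCalls(data.frame(start = 2000, end = 3000, svtype = "DEL"))
  many <- dfToCalls(data.frame(start = c(2000, 4000, 6000, 8500),
                               end = c(2500, 4500, 6500, 9500),
                               svtype = c("DEL", "DEL", "DEL", "DUP")))
  expect_equal(classifyAcghComplexity(acgh, one)$class, "simple")
  r <- classifyAcghComplexity(acgh, many)
  expect_equal(r$class, "complex")
  expect_equal(r$containedCalls, 4L)                 # overlap, not containment
  empty <- classifyAcghComplexity(acgh, one[0])
  expect_equal(empty$class, "simple")
  expect_true(empty$unsupported)

  ## monotonicity: adding a contained call never turns complex into simple
  set.seed(5)
  for (rep in 1:20) {
    calls <- dfToCalls(randomCallsetDf(sample(1:5, 1L), span = 8000L))
    before <- classifyAcghComplexity(acgh, calls)
    extra <- dfToCalls(data.frame(start = 4000, end = 4200, svtype = "DEL"))
    after <- classifyAcghComplexity(acgh, c(calls, extra))
    expect_gte(after$containedCalls, before$containedCalls)
    if (before$class == "complex") expect_equal(after$class, "complex")
  }
})
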