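test_that("constitutional caller separates full-copy from single-copy variants", {
  ## clean constitutional site
  ac <- data.frame(pos = c(10L, 50L), ref = c("A", "T"), alt = c("G", "C"),
                   count = c(200L, 8L))
  pu <- TransgenePileup(100L, 29L, rep(200L, 100L), ac)
  calls <- callConstitutionalVariants(pu)
  expect_equal(calls$constitutional$pos, 10L)
  expect_equal(calls$constitutional$fraction, 1)
  ## 8/200 = 0.04 is above 1/31 and far above the error rate: partial
  expect_equal(calls$partial$pos, 50L)

  ## shallow positions are skipped with a warning
  puS <- TransgenePileup(100L, 29L, c(10L, rep(200L, 99L)),
                         data.frame(pos = 1L, ref = "A", alt = "G",
                                    count = 10L))
  expect_warning(res <- callConstitutionalVariants(puS), "minDepth")
  expect_equal(nrow(res$constitutional), 0L)
})

test_that("single-copy detection power matches the binomial closed form", {
  ## power of the partial-variant call for one copy of a c-copy array:
  ## detected iff X >= max(ceiling(d/(c+2)), critical value of the
  ## binomial error test); closed form by enumeration (the oracle), then
  ## compared with the empirical rate over repeated binomial draws
  cN <- 10L; d <- 300L; err <- 0.005; alpha <- 0.01
  pAlt <- 1 / cN
  kFloor <- ceiling(d / (cN + 2))
  kSig <- qbinom(1 - alpha, d, err) + 1L
  while (binom.test(kSig, d, err, alternative = "greater")$p.value >= alpha)
    kSig <- kSig + 1L
  kDet <- max(kFloor, kSig)
  closedForm <- 1 - pbinom(kDet - 1L, d, pAlt)

  set.seed(77)
  hits <- 0L; nRep <- 200L
  for (i in seq_len(nRep)) {
    x <- rbinom(1L, d, pAlt)
    pu <- TransgenePileup(10L, cN, rep(d, 10L),
                          data.frame(pos = 5L, ref = "A", alt = "G",
                                     count = x)[x > 0L, , drop = FALSE])
    res <- callConstitutionalVariants(pu, errorRate = err, alpha = alpha)
    hits <- hits + (nrow(res$partial) == 1L)
  }
  expect_lt(abs(hits / nRep - closedForm), 0.05)
})

test_that("error-free read segmentation recovers construction boundaries exactly", {
  set.seed(13)
  hostV <- sample(c("A", "C", "G", "T"), 30000, TRUE)
  tgV <- sample(c("A", "C", "G", "T"), 8000, TRUE)
  ## pin junction-adjacent bases so the constructed chimeras below cannot
  ## carry accidental 1 bp homology that would legitimately shift an
  ## anchor-exact boundary
  tgV[2001] <- "A"; hostV[11001] <- "C"              # host|tg junction
  tgV[2000] <- "G"; hostV[11000] <- "T"
  hostV[20500] <- "A"; hostV[1801] <- "C"            # fwd|rc junction
  hostV[20501] <- "G"; hostV[1800] <- "T"            # rc right edge
  host <- paste(hostV, collapse = "")
  tg <- paste(tgV, collapse = "")

  ## pure host read: one + strand block covering the read
  r1 <- substr(host, 5001, 7000)
  b1 <- segmentChimericRead(r1, host, tg)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$label, "host")
  expect_equal(b1$strand, "+")
  expect_equal(c(b1$readStart, b1$readEnd), c(1L, 2000L))
  expect_equal(c(b1$refStart, b1$refEnd), c(5001L, 7000L))

  ## chimeric host|transgene read: junction located exactly
  r2 <- paste0(substr(host, 10001, 11000), substr(tg, 2001, 3000))
  b2 <- segmentChimericRead(r2, host, tg)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$label, c("host", "transgene"))
  expect_equal(b2$readEnd[1L], 1000L)
  expect_equal(b2$readStart[2L], 1001L)
  expect_equal(b2$refEnd[1L], 11000L)
  expect_equal(b2$refStart[2L], 2001L)

  ## reverse-complemented host segment reported on the minus strand
  rcSeg <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(host, 20001, 20500))))
  r3 <- paste0(substr(host, 1001, 1800), rcSeg)
  b3 <- segmentChimericRead(r3, host, tg)
  expect_equal(b3$strand, c("+", "-"))
  expect_equal(c(b3$refStart[2L], b3$refEnd[2L]), c(20001L, 20500L))
  expect_equal(c(b3$readStart[2L], b3$readEnd[2L]), c(801L, 1300L))

  ## reads shorter than k yield no blocks
  expect_equal(nrow(segmentChimericRead("ACGTACGT", host, tg)), 0L)
})

test_that("junction round-trip recovers the truth model on error-free reads", {
  cfg <- junctionConfig(hostWindow = c(100001L, 170000L),
                        deletion = c(125001L, 145001L),
                        inversion = c(144801L, 145000L),
                        nInsertedBases = 4L, microhomologyLenDownstream = 2L,
                        upstreamMonomerRange = c(4001L, 9000L),
                        downstreamMonomerRange = c(1L, 7000L),
                        monomerLength = 9000L, oriRange = c(1500L, 1700L),
                        readLengthMean = 8000, readErrorRate = 0,
                        nSpanningReads = 2L, seed = 17)
  refs <- simulateIntegrationReferences(cfg)
  sim <- simulateIntegrationReads(refs$config, refs$host, refs$monomer)
  blocks <- segmentChimericReads(sim$reads, refs$host, refs$monomer)
  model <- reconstructJunction(blocks, sim$reads, refs$host, refs$monomer,
                               cfg$hostWindow, oriRange = cfg$oriRange)

  expect_true(junctionFound(model))
  expect_equal(deletionSpan(model), deletionSpan(sim$truth))
  expect_equal(inversionSpan(model), as.numeric(inversionSpan(sim$truth)))
  expect_equal(insertedBases(model), insertedBases(sim$truth))
  expect_equal(junctionMicrohomology(model)$downstream$length,
               junctionMicrohomology(sim$truth)$downstream$length)
  ## breakpoint-adjacent monomer flags: upstream copy lacks the origin,
  ## downstream copy retains it; both miss a cohesive end
  expect_false(model@monomerTruncations$upstream$oriFunctional)
  expect_true(model@monomerTruncations$downstream$oriFunctional)
  expect_false(model@monomerTruncations$upstream$cohesiveEndPresent)

  ## reads with no transgene content: a no-junction result, not an error
  hostOnly <- Biostrings::DNAStringSet(substr(refs$host, 1000, 9000))
  bl0 <- segmentChimericReads(hostOnly, refs$host, refs$monomer)
  m0 <- reconstructJunction(bl0, hostOnly, refs$host, refs$monomer,
                            cfg$hostWindow)
  expect_false(junctionFound(m0))
})

test_that("microhomology equals exhaustive brute force", {
  expect_equal(microhomology("AAACGT", "GTCCC")$length, 2L)
  expect_equal(microhomology("AAACGT", "GTCCC")$sequence, "GT")
  expect_equal(microhomology("AAAA", "CCCC")$length, 0L)
  long <- strrep("ACGTC", 10)
  expect_equal(microhomology(long, long)$length, 25L)   # cap
  set.seed(19)
  for (rep in 1:120) {
    l <- paste(sample(c("A", "C"), sample(3:30, 1L), TRUE), collapse = "")
    r <- paste(sample(c("A", "C"), sample(3:30, 1L), TRUE), collapse = "")
    expect_equal(microhomology(l, r)$length, naiveMicrohomology(l, r))
  }
})
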