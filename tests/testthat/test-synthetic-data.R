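test_that("parental catalogs honor the requested sharing structure", {
  ## forced identity / disjointness
  c1 <- simulateParentalCatalogs(500, sharedFraction = 1, seed = 1)
  expect_setequal(catalogA(c1), catalogB(c1))
  c0 <- simulateParentalCatalogs(500, sharedFraction = 0, seed = 1)
  expect_length(intersect(catalogA(c0), catalogB(c0)), 0L)
  ## measured sharing within sampling error of the request
  cm <- simulateParentalCatalogs(10000, sharedFraction = 0.5, seed = 1)
  jac <- length(intersect(catalogA(cm), catalogB(cm))) /
    length(union(catalogA(cm), catalogB(cm)))
  expect_lt(abs(jac - 0.5), 0.02)
  ## known set always contains both catalogs
  expect_true(all(union(catalogA(cm), catalogB(cm)) %in% knownSet(cm)))
  expect_error(simulateParentalCatalogs(0), "positive")
  expect_error(simulateParentalCatalogs(10, sharedFraction = 1.5), "\\[0, 1\\]")
})

test_that("colony simulation is deterministic and conserves founder alleles", {
  cat0 <- simulateParentalCatalogs(800, 0.5, 0.25, seed = 2)
  cfg <- pedigreeConfig(nGenerations = 6, nBreedingFemales = 8,
                        deNovoRate = 0, seed = 5)
  tb <- simulateColony(cat0, cfg, nSampledAnimals = 4)
  ## with no de novo input, every sampled allele existed in a founder
  ## haplotype, i.e. in the parental catalogs (no extras planted)
  expect_true(all(variantKeys(tb) %in% union(catalogA(cat0), catalogB(cat0))))
  expect_true(all(truthClasses(tb) %in% c("both_parents", "a_only", "b_only")))

  ## same seed, byte-identical VCF
  tb2 <- simulateColony(cat0, cfg, nSampledAnimals = 4)
  f1 <- tempfile(); f2 <- tempfile()
  writeVcfMinimal(tb, f1, seed = 5L); writeVcfMinimal(tb2, f2, seed = 5L)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulateColony(cat0, cfg, nSampledAnimals = 100),
               "cannot sample")
})

test_that("planted founder extras carry their truth classes", {
  cat0 <- simulateParentalCatalogs(600, 0.5, 0.4, seed = 3)
  cfg <- pedigreeConfig(nGenerations = 4, nBreedingFemales = 10,
                        deNovoRate = 0.5, seed = 9)
  tb <- simulateColony(cat0, cfg, nSampledAnimals = 6,
                       founderKnownExtra = 60, founderPrivate = 60)
  tc <- table(truthClasses(tb))
  expect_gt(tc[["known_nonparental"]], 0L)
  expect_gt(tc[["private"]], 0L)
  ## truth classes agree with set-membership classification
  cls <- classifyOrigin(variantKeys(tb), cat0)
  expect_equal(as.character(cls), truthClasses(tb))
})

test_that("coverage follows copy-number dosage", {
  empty <- plantCnvTruth(0, 2.5e6, seed = 1)
  trk <- simulateCoverage(empty, 2.5e6, binSize = 250, baseDepth = 50,
                          seed = 2)
  expect_length(binDepths(trk), 10000L)
  expect_lt(abs(mean(binDepths(trk)) - 50) / 50, 0.02)

  ev <- GRanges("chr1", IRanges(c(10001, 40001), c(20000, 90000)),
                copyNumber = c(0L, 3L))
  trk2 <- simulateCoverage(ev, 1e5, binSize = 250, baseDepth = 50, seed = 3)
  d <- binDepths(trk2)
  expect_equal(mean(d[41:80]), 0)                    # copy 0: no reads
  expect_lt(abs(mean(d[161:360]) - 75), 2)           # copy 3: 50 * 3/2

  bad <- GRanges("chr1", IRanges(c(1, 500), c(1000, 1500)),
                 copyNumber = c(1L, 3L))
  expect_error(simulateCoverage(bad, 1e5), "overlap")
})

test_that("probe log2 ratios follow dosage with the configured noise", {
  ev <- GRanges("chr1", IRanges(c(10001, 40001), c(20000, 50000)),
                copyNumber = c(1L, 4L))
  pr <- simulateProbes(ev, 1e5, meanSpacing = 500, noiseSd = 0, seed = 4)
  v <- probeLog2Ratios(pr); p <- probePositions(pr)
  inside1 <- p >= 10001 & p <= 20000
  inside4 <- p >= 40001 & p <= 50000
  expect_true(all(v[inside1] == -1))
  expect_true(all(v[inside4] == 1))
  expect_true(all(v[!inside1 & !inside4] == 0))

  pr2 <- simulateProbes(plantCnvTruth(0, 2e6), 2e6, meanSpacing = 2000,
                        noiseSd = 0.2, seed = 5)
  expect_gt(length(probePositions(pr2)), 900L)
  expect_lt(abs(sd(probeLog2Ratios(pr2)) - 0.2), 0.02)
  expect_error(simulateProbes(ev, 1e5, noiseSd = -1), ">= 0")
})

test_that("transgene pileup gives dosage-correct allele fractions", {
  t5 <- readConstitutionalTable(system.file("extdata", "table5_variants.tsv",
                                            package = "mutacolony"))
  expect_equal(nrow(t5), 18L)

  cfg <- transgeneArrayConfig(constitutionalVariants = t5, nCopies = 29,
                              depth = 1000, privateVariantRate = 0.5,
                              seed = 11)
  sim <- simulateTransgenePileup(cfg)
  expect_equal(nrow(sim$constitutionalTruth), 18L)
  ac <- altCounts(sim$pileup); d <- pileupDepth(sim$pileup)
  ## constitutional sites: combined alternate fraction near 1
  for (pos in t5$pos) {
    frac <- sum(ac$count[ac$pos == pos]) / d[pos]
    expect_gt(frac, 0.97)
  }
  ## single-copy variants: mean fraction near 1/29 (binomial mean)
  pv <- sim$privateTruth
  fr <- vapply(seq_len(nrow(pv)), function(i)
    sum(ac$count[ac$pos == pv$pos[i] & ac$alt == pv$alt[i]]) / d[pv$pos[i]],
    numeric(1))
  expect_lt(abs(mean(fr) - 1 / 29), 0.01)

  ## single-copy array: everything is constitutional by construction
  cfg1 <- transgeneArrayConfig(monomerLength = 5000, nCopies = 1,
                               privateVariantRate = 2, depth = 400, seed = 3)
  sim1 <- simulateTransgenePileup(cfg1)
  expect_equal(nrow(sim1$privateTruth), 0L)
  expect_gt(nrow(sim1$constitutionalTruth), 0L)

  expect_error(transgeneArrayConfig(
    monomerLength = 100,
    constitutionalVariants = data.frame(pos = 200, ref = "A", alt = "G")),
    "outside")
})

test_that("integration reads are exact locus substrings with the configured junctions", {
  cfg <- junctionConfig(hostWindow = c(1L, 60000L), deletion = c(20001L, 40001L),
                        inversion = c(39801L, 40000L), nInsertedBases = 4L,
                        microhomologyLenDownstream = 2L,
                        upstreamMonomerRange = c(3001L, 8000L),
                        downstreamMonomerRange = c(1L, 6000L),
                        monomerLength = 8000L, oriRange = c(1000L, 1200L),
                        readLengthMean = 6000, readErrorRate = 0,
                        nSpanningReads = 2L, seed = 21)
  refs <- simulateIntegrationReferences(cfg)
  sim <- simulateIntegrationReads(refs$config, refs$host, refs$monomer)

  ## construction identity: the locus around the upstream junction is the
  ## concatenation host flank + inverted segment + insert + monomer, built
  ## here independently from the references
  expected <- paste0(substr(refs$host, 19001, 20000),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(substr(refs$host, 39801, 40000)))),
                     refs$config$insertedBases,
                     substr(refs$monomer, 3001, 4000))
  expect_true(grepl(expected, sim$locus, fixed = TRUE))

  ## error-free reads are exact substrings of the truth locus
  for (r in as.character(sim$reads))
    expect_true(grepl(r, sim$locus, fixed = TRUE))

  ## truth model carries the configured geometry
  expect_equal(deletionSpan(sim$truth), c(20001, 40001))
  expect_equal(junctionMicrohomology(sim$truth)$downstream$length, 2L)
  expect_equal(nchar(insertedBases(sim$truth)), 4L)

  ## zero-microhomology configuration yields flanks sharing no terminal bases
  cfg0 <- junctionConfig(hostWindow = c(1L, 60000L), deletion = c(20001L, 40001L),
                         inversion = c(39801L, 40000L),
                         microhomologyLenDownstream = 0L,
                         upstreamMonomerRange = c(3001L, 8000L),
                         downstreamMonomerRange = c(1L, 6000L),
                         monomerLength = 8000L, readLengthMean = 6000,
                         nSpanningReads = 1L, seed = 8)
  refs0 <- simulateIntegrationReferences(cfg0)
  sim0 <- simulateIntegrationReads(refs0$config, refs0$host, refs0$monomer)
  expect_equal(junctionMicrohomology(sim0$truth)$downstream$length, 0L)

  expect_error(junctionConfig(hostWindow = c(1L, 1000L),
                              deletion = c(500L, 2000L)), "inside")
})
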