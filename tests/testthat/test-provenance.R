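test_that("provenance classes partition any input", {
  set.seed(42)
  for (rep in 1:25) {
    keys <- sprintf("chr%d:%d:A:G", sample(1:2, 40, TRUE),
                    sample.int(9000, 40))
    a <- sample(keys, 15); b <- sample(keys, 15)
    k <- union(union(a, b), sample(keys, 10))
    cats <- ParentalCatalogs(a, b, k, genomeLength = 20000, nChromosomes = 2L)
    cls <- classifyOrigin(keys, cats)
    expect_false(anyNA(cls))                        # exhaustive
    naive <- vapply(keys, naiveClassify, character(1), a = a, b = b, k = k)
    expect_equal(as.character(cls), unname(naive))  # mutually exclusive rule
  }
})

test_that("provenance summary equals naive per-variant counting", {
  cat0 <- simulateParentalCatalogs(400, 0.5, 0.3, seed = 6)
  cfg <- pedigreeConfig(nGenerations = 3, nBreedingFemales = 6,
                        deNovoRate = 0.3, seed = 7)
  tb <- simulateColony(cat0, cfg, 4, founderKnownExtra = 30,
                       founderPrivate = 30)
  sm <- summarizeProvenance(tb, cat0)
  expect_equal(sum(sm$cohort$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(sm$cohort$count), nrow(tb))

  a <- catalogA(cat0); b <- catalogB(cat0); k <- knownSet(cat0)
  naive <- table(factor(vapply(variantKeys(tb), naiveClassify, character(1),
                               a = a, b = b, k = k),
                        levels = sm$cohort$class))
  expect_equal(unname(sm$cohort$count), as.integer(naive))

  ## pairwise overlap: self = 1, disjoint variant sets = 0
  expect_true(all(diag(sm$pairwiseOverlap) == 1))
  gtD <- matrix(c(1L, 0L, 0L, 2L), nrow = 2L)
  smD <- summarizeProvenance(makeTable(gtD), cat0)
  expect_equal(smD$pairwiseOverlap[1L, 2L], 0)
})

test_that("density track tiles chromosomes and conserves counts", {
  cl <- c(chr1 = 5e6, chr2 = 3e6)
  keys <- c(sprintf("chr1:%d:A:G", c(10, 500, 999999)),
            sprintf("chr2:%d:T:C", c(1500000, 2999999)))
  tr <- densityTrack(keys, cl, window = 1e6)
  expect_equal(sum(mcols(tr)$count), length(keys))
  expect_equal(mcols(tr)$count[1L], 3L)             # all chr1 in window 1
  expect_equal(length(tr), 5L + 3L)
  ## empty input: all-zero track
  tr0 <- densityTrack(character(), cl, window = 1e6)
  expect_true(all(mcols(tr0)$count == 0L))
  ## randomized uniform input lands Poisson-like per window
  set.seed(1)
  keysU <- sprintf("chr1:%d:A:G", sample.int(5e6, 1000))
  trU <- densityTrack(keysU, c(chr1 = 5e6), window = 5e5)
  expect_equal(sum(mcols(trU)$count), 1000L)
  expect_true(all(abs(mcols(trU)$count - 100) < 50))
})

test_that("region classification follows the documented precedence", {
  tx <- data.frame(gene = "g1", chrom = "chr1", start = 10000, end = 20000,
                   strand = "+")
  ex <- data.frame(gene = "g1", chrom = "chr1",
                   start = c(10000, 15000), end = c(10500, 15500))
  u5 <- data.frame(gene = "g1", chrom = "chr1", start = 10000, end = 10100)
  gm <- geneModels(tx, ex, utr5 = u5)

  keyAt <- function(pos) sprintf("chr1:%d:A:G", pos)
  cls <- function(pos) as.character(classifyRegion(keyAt(pos), gm))
  expect_equal(cls(10300), "exon")
  expect_equal(cls(10050), "utr5")          # UTR beats plain exon there
  expect_equal(cls(10501), "splice_site")   # within 2 bp of exon edge
  expect_equal(cls(10502), "splice_site")
  expect_equal(cls(12000), "intron")
  expect_equal(cls(7000), "upstream")       # 3 kb 5' of a + transcript
  expect_equal(cls(23000), "downstream")
  expect_equal(cls(30001), "intergenic")    # beyond the 5 kb flank
  expect_warning(out <- classifyRegion("chr9:5:A:G", gm), "absent")
  expect_equal(as.character(out), "intergenic")

  ## two genes in range: nearest wins
  tx2 <- rbind(tx, data.frame(gene = "g2", chrom = "chr1", start = 28000,
                              end = 30000, strand = "+"))
  ex2 <- rbind(ex, data.frame(gene = "g2", chrom = "chr1", start = 28000,
                              end = 30000))
  gm2 <- geneModels(tx2, ex2, utr5 = u5)
  expect_equal(as.character(classifyRegion(keyAt(24000), gm2)), "upstream")
  expect_equal(as.character(classifyRegion(keyAt(20500), gm2)), "downstream")
})
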