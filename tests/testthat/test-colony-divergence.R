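test_that("homozygous partitioning matches set logic on constructed genotypes", {
  cats <- ParentalCatalogs(c("chr1:100:A:G"), c("chr1:100:A:G"),
                           c("chr1:100:A:G", "chr1:200:T:C"),
                           genomeLength = 1000)
  ## 4 variants: parental-shared-hom, nonparental hom in colony1 only,
  ## nonparental hom in colony2 only, nonparental hom in both
  keys <- c("chr1:100:A:G", "chr1:200:T:C", "chr1:300:G:A", "chr1:400:C:T")
  gt <- rbind(c(2L, 2L, 2L, 2L),
              c(2L, 1L, 0L, 0L),
              c(0L, 0L, 2L, 1L),
              c(1L, 2L, 2L, 2L))
  tb <- GenotypeTable(gt, keys, c("c1", "c1", "c2", "c2"))
  p <- partitionHomozygous(tb, cats)
  expect_equal(unname(p["parental", ]), c(1L, 0L, 0L))
  expect_equal(unname(p["non_parental", ]), c(1L, 1L, 1L))
  expect_equal(sum(p), 4L)                            # cells are disjoint
  expect_error(partitionHomozygous(makeTable(gt), cats), "two colonies")
})

test_that("discordance is the fraction of differing non-missing sites", {
  gt <- cbind(a = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L),
              b = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 0L, 2L))
  d <- discordanceMatrix(makeTable(gt))
  expect_equal(d$discordance["a", "b"], 0.2)          # 2 of 10 differ
  expect_equal(diag(d$discordance), c(a = 0, b = 0))
  allDiff <- cbind(a = rep(0L, 10), b = rep(2L, 10))
  expect_equal(discordanceMatrix(makeTable(allDiff))$discordance[1, 2], 1)
  ## missing genotypes drop out of the denominator
  gtM <- cbind(a = c(0L, NA, 2L, 1L), b = c(2L, 1L, NA, 1L))
  dM <- discordanceMatrix(makeTable(gtM))
  expect_equal(dM$nSites[1, 2], 2L)
  expect_equal(dM$discordance[1, 2], 0.5)
  gtE <- cbind(a = c(0L, NA), b = c(NA, 1L))
  expect_warning(dE <- discordanceMatrix(makeTable(gtE)), "no comparable")
  expect_true(is.na(dE$discordance[1, 2]))
})

test_that("discordance is a pseudometric on complete data", {
  set.seed(23)
  for (rep in 1:20) {
    gt <- matrix(sample(0:2, 40 * 4, TRUE), ncol = 4L)
    D <- discordanceMatrix(makeTable(gt))$discordance
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("ROH detection finds homozygous tracts and rejects alternating sites", {
  ## all-homozygous chromosome: one segment spanning first to last site
  pos <- sort(sample.int(5e6, 400))
  seg <- detectRoh(pos, rep(2L, 400), windowSites = 50, minLength = 1e5)
  expect_length(seg, 1L)
  expect_equal(start(seg), pos[1])
  expect_equal(end(seg), pos[400])

  ## strictly alternating het/hom: nothing passes the allowance
  gtAlt <- rep(c(1L, 2L), 200)
  expect_length(detectRoh(pos, gtAlt, windowSites = 50, minLength = 1e5), 0L)

  ## planted 2 Mb homozygous tract inside a heterozygous-rich background
  set.seed(29)
  pos2 <- sort(sample.int(1e7, 2000))
  gt2 <- sample(c(1L, 2L), 2000, TRUE)
  tract <- pos2 >= 4e6 & pos2 <= 6e6
  gt2[tract] <- 2L
  seg2 <- detectRoh(pos2, gt2, windowSites = 50, maxHetPerWindow = 1,
                    minLength = 1e6)
  expect_length(seg2, 1L)
  window <- 50 * mean(diff(pos2))                     # about one window of sites
  expect_lt(abs(start(seg2) - 4e6), window * 2)
  expect_lt(abs(end(seg2) - 6e6), window * 2)
  expect_error(detectRoh(c(5, 3), c(2L, 2L)), "sorted")
})

test_that("neighbor joining reproduces closed forms and additive matrices", {
  ## three taxa: unique closed-form branch lengths
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- buildNjTree(D)
  co <- ape::cophenetic.phylo(nj$tree)
  expect_equal(co[rownames(D), colnames(D)], D, tolerance = 1e-9)
  bl <- setNames(nj$tree$edge.length,
                 nj$tree$tip.label[nj$tree$edge[, 2L]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  ## additive matrices: path lengths reproduce the input, topology matches
  ## the independent implementation
  set.seed(31)
  for (rep in 1:25) {
    ra <- randomAdditiveMatrix(sample(4:8, 1L))
    mine <- buildNjTree(ra$D)
    co <- ape::cophenetic.phylo(mine$tree)[rownames(ra$D), colnames(ra$D)]
    expect_equal(co, ra$D, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(mine$tree),
                                ape::unroot(ra$tree))[1L], 0)
  }

  ## two tight clusters far apart: each colony is monophyletic
  Dm <- matrix(10, 6, 6); Dm[1:3, 1:3] <- 0.5; Dm[4:6, 4:6] <- 0.5
  diag(Dm) <- 0
  dimnames(Dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  colonies <- setNames(rep(c("x", "y"), each = 3L), paste0("s", 1:6))
  njm <- buildNjTree(Dm, colonies = colonies)
  expect_true(all(njm$monophyletic))

  bad <- D; bad[1, 2] <- 9
  expect_error(buildNjTree(bad), "symmetric")
})
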