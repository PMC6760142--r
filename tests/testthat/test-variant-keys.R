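test_that("variant keys normalize and round-trip", {
  expect_equal(makeVariantKey("chr1", 100, "A", "G"), "chr1:100:A:G")
  ## left-normalization: shared suffix then prefix stripped, anchor kept
  expect_equal(makeVariantKey("chr1", 100, "ATT", "AT"), "chr1:100:AT:A")
  expect_equal(makeVariantKey("chr2", 50, "CAG", "CTG"), "chr2:51:A:T")
  f <- parseVariantKey(c("chr1:100:A:G", "chrX:5:AT:A"))
  expect_equal(f$chrom, c("chr1", "chrX"))
  expect_equal(f$pos, c(100L, 5L))
  expect_equal(f$ref, c("A", "AT"))
  expect_error(makeVariantKey("chr1", 100, "A", "A"), "differ")
  expect_error(makeVariantKey("chr1", 0, "A", "G"), ">= 1")
  expect_error(parseVariantKey("chr1:100:A"), "malformed")
})

test_that("interval length honors the stated convention", {
  expect_equal(intervalLength(10, 20, "difference"), 10)
  expect_equal(intervalLength(10, 20, "inclusive"), 11)
  expect_equal(intervalLength(5, 5, "inclusive"), 1)
  expect_error(intervalLength(10, 5, "difference"), ">= start")
})
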