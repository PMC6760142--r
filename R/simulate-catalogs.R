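## Synthetic parental-strain catalogs ---------------------------------------

## RNG hygiene: simulators take explicit seeds and restore the caller's RNG
## state on exit, so interleaving simulations does not perturb user code.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

## n distinct (chrom, pos, ref, alt) SNV keys over the genome, avoiding
## positions already in `exclude` ("chrom:pos" strings).
randomSnvKeys <- function(n, chromLengths, exclude = character()) {
  used <- new.env(hash = TRUE, parent = emptyenv())
  for (e in exclude) assign(e, TRUE, envir = used)
  total <- sum(chromLengths)
  cum <- cumsum(chromLengths)
  chrom <- character(n); pos <- integer(n)
  i <- 1L
  while (i <= n) {
    p <- ceiling(runif(1L) * total)
    ci <- findInterval(p - 0.5, c(0, cum)) # 1..nChrom
    cp <- as.integer(p - c(0, cum)[ci])
    id <- paste0(names(chromLengths)[ci], ":", cp)
    if (!exists(id, envir = used, inherits = FALSE)) {
      assign(id, TRUE, envir = used)
      chrom[i] <- names(chromLengths)[ci]; pos[i] <- cp
      i <- i + 1L
    }
  }
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Simulate parental-strain variant catalogs
#'
#' Generates two parental catalogs whose union has \code{nVariants} keys, a
#' fraction \code{sharedFraction} of which is shared between the strains
#' (ancestral variants present in both), plus a known-variant set that adds
#' \code{knownExtraFraction * nVariants} keys not present in either parent
#' (a dbSNP-style stand-in). The non-shared remainder is split evenly
#' between the two strains.
#'
#' @param nVariants size of the union of the two catalogs.
#' @param sharedFraction fraction of the union present in both strains.
#' @param knownExtraFraction extra non-parental known keys, as a fraction of
#'   \code{nVariants}.
#' @param seed RNG seed.
#' @param genomeLength,nChromosomes synthetic genome dimensions.
#' @return A [ParentalCatalogs] object.
#' @export
simulateParentalCatalogs <- function(nVariants, sharedFraction = 0.55,
                                     knownExtraFraction = 0.2, seed = 1L,
                                     genomeLength = 3e7, nChromosomes = 3L) {
  if (nVariants <= 0) stop("nVariants must be positive")
  if (sharedFraction < 0 || sharedFraction > 1 ||
      knownExtraFraction < 0 || knownExtraFraction > 1)
    stop("fractions must lie in [0, 1]")
  withSeed(seed, {
    cl <- rep(genomeLength / nChromosomes, nChromosomes)
    names(cl) <- paste0("chr", seq_len(nChromosomes))
    nShared <- round(sharedFraction * nVariants)
    nAonly <- floor((nVariants - nShared) / 2)
    nBonly <- nVariants - nShared - nAonly
    nExtra <- round(knownExtraFraction * nVariants)
    keys <- randomSnvKeys(nVariants + nExtra, cl)
    shared <- keys[seq_len(nShared)]
    aOnly <- keys[nShared + seq_len(nAonly)]
    bOnly <- keys[nShared + nAonly + seq_len(nBonly)]
    extra <- keys[nVariants + seq_len(nExtra)]
    ParentalCatalogs(catalogA = c(shared, aOnly), catalogB = c(shared, bOnly),
                     knownSet = c(shared, aOnly, bOnly, extra),
                     genomeLength = genomeLength, nChromosomes = nChromosomes)
  })
}
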