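## Forward-time diploid pedigree simulator ----------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pedigree configuration for the colony simulator
#'
#' The defaults describe the MutaMouse-style husbandry the package models:
#' a closed colony founded from a single F1 x F1 cross and bred for 78
#' generations, each generation the offspring of 40 breeding females (the
#' colony records give 20-60), with random pairing that avoids full-sibling
#' matings where possible, and an optional single-generation bottleneck in
#' which only a few breeding pairs re-found the colony.
#'
#' @param nGenerations number of bred generations after the founders.
#' @param nBreedingFemales breeding females per generation (population size
#'   is twice this).
#' @param bottleneckGeneration generation whose offspring come from only
#'   \code{bottleneckPairs} pairs (NULL for none); must be less than
#'   \code{nGenerations}.
#' @param bottleneckPairs breeding pairs during the bottleneck.
#' @param deNovoRate expected new (heterozygous) variants per genome per
#'   generation (Poisson).
#' @param recombinationRate expected crossovers per chromosome per meiosis.
#' @param seed RNG seed.
#' @return A validated configuration list of class \code{PedigreeConfig}.
#' @export
pedigreeConfig <- function(nGenerations = 78L, nBreedingFemales = 40L,
                           bottleneckGeneration = NULL, bottleneckPairs = 3L,
                           deNovoRate = 0.5, recombinationRate = 1,
                           seed = 1L) {
  if (nGenerations < 1L) stop("nGenerations must be >= 1")
  if (nBreedingFemales < 1L) stop("nBreedingFemales must be >= 1")
  if (!is.null(bottleneckGeneration) && bottleneckGeneration >= nGenerations)
    stop("bottleneckGeneration must be < nGenerations")
  if (deNovoRate < 0) stop("deNovoRate must be >= 0")
  structure(list(nGenerations = as.integer(nGenerations),
                 nBreedingFemales = as.integer(nBreedingFemales),
                 bottleneckGeneration = bottleneckGeneration,
                 bottleneckPairs = as.integer(bottleneckPairs),
                 deNovoRate = deNovoRate,
                 recombinationRate = recombinationRate,
                 seed = as.integer(seed)),
            class = "PedigreeConfig")
}

deNovoCap <- function(config, nColonies = 1L) {
  mu <- config$deNovoRate * 2 * config$nBreedingFemales *
    config$nGenerations * nColonies
  as.integer(ceiling(mu + 6 * sqrt(mu + 1) + 20))
}

## Locus registry: fixed-capacity vectors plus an environment of occupied
## "chrom:pos" strings (reference semantics keep de novo draws cheap).
newRegistry <- function(keys, truth, chromLengths, capacity) {
  nBase <- length(keys)
  f <- parseVariantKey(keys)
  usedEnv <- new.env(hash = TRUE, parent = emptyenv())
  for (id in paste0(f$chrom, ":", f$pos)) assign(id, TRUE, envir = usedEnv)
  list(nUsed = nBase,
       keys = c(keys, rep(NA_character_, capacity)),
       truth = c(truth, rep("private", capacity)),
       chromName = c(f$chrom, rep(names(chromLengths)[1L], capacity)),
       pos = c(f$pos, rep(1L, capacity)),
       chromLengths = chromLengths, usedEnv = usedEnv,
       chromIdx = NULL)
}

registerUsed <- function(reg, moreIds) {
  for (id in moreIds) assign(id, TRUE, envir = reg$usedEnv)
  reg
}

## draw one fresh SNV locus not colliding with any occupied position
drawDeNovoLocus <- function(reg) {
  cl <- reg$chromLengths
  cum <- cumsum(cl); total <- sum(cl)
  repeat {
    p <- ceiling(runif(1L) * total)
    ci <- findInterval(p - 0.5, c(0, cum))
    cp <- as.integer(p - c(0, cum)[ci])
    id <- paste0(names(cl)[ci], ":", cp)
    if (!exists(id, envir = reg$usedEnv, inherits = FALSE)) {
      assign(id, TRUE, envir = reg$usedEnv)
      ref <- sample(BASES, 1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      return(list(chrom = names(cl)[ci], pos = cp,
                  key = paste(names(cl)[ci], cp, ref, alt, sep = ":")))
    }
  }
}

refreshChromIdx <- function(reg) {
  nm <- names(reg$chromLengths)
  reg$chromIdx <- lapply(nm, function(cn)
    which(reg$chromName[seq_len(reg$nUsed)] == cn))
  reg
}

## Founder state: two F1 hybrids, each carrying one strain-A and one
## strain-B haplotype. Optional extra variants (catalog false negatives and
## truly private founder variation) are planted heterozygous on single
## founder haplotypes.
buildFounders <- function(catalogs, founderKnownExtra = 0L,
                          founderPrivate = 0L, capacity = 0L) {
  a <- catalogA(catalogs); b <- catalogB(catalogs)
  unionAB <- union(a, b)
  avail <- setdiff(knownSet(catalogs), unionAB)
  if (founderKnownExtra > length(avail))
    stop("not enough non-parental known keys to plant as founder extras")
  extraKnown <- if (founderKnownExtra > 0L)
    sample(avail, founderKnownExtra) else character()
  cl <- chromLengths(catalogs)
  knownIds <- sub("^([^:]+:[0-9]+):.*$", "\\1", knownSet(catalogs))
  extraPriv <- if (founderPrivate > 0L)
    randomSnvKeys(founderPrivate, cl, exclude = knownIds) else character()

  keys <- c(unionAB, extraKnown, extraPriv)
  truth <- c(ifelse(unionAB %in% a & unionAB %in% b, "both_parents",
                    ifelse(unionAB %in% a, "a_only", "b_only")),
             rep("known_nonparental", length(extraKnown)),
             rep("private", length(extraPriv)))
  reg <- newRegistry(keys, truth, cl, capacity)
  reg <- registerUsed(reg, setdiff(knownIds,
                                   ls(envir = reg$usedEnv)))

  nMax <- length(reg$keys)
  ## founder haplotypes: columns 1-2 founder 1 (A-hap, B-hap), 3-4 founder 2
  H <- matrix(FALSE, nrow = nMax, ncol = 4L)
  base <- seq_len(reg$nUsed)
  H[base, c(1L, 3L)] <- keys %in% a
  H[base, c(2L, 4L)] <- keys %in% b
  extras <- which(keys %in% c(extraKnown, extraPriv))
  for (k in extras) {
    H[k, ] <- FALSE
    H[k, sample(4L, 1L)] <- TRUE
  }
  list(H = H, registry = reg)
}

## Meiosis masks for one batch of gametes: TRUE selects the second parental
## haplotype. Poisson(recRate) crossovers per chromosome, random phase.
meiosisMasks <- function(reg, nGametes, recRate) {
  n <- reg$nUsed
  K <- matrix(FALSE, n, nGametes)
  for (ci in seq_along(reg$chromLengths)) {
    idx <- reg$chromIdx[[ci]]
    idx <- idx[idx <= n]
    if (!length(idx)) next
    posC <- reg$pos[idx]
    len <- reg$chromLengths[ci]
    ks <- rpois(nGametes, recRate)
    phases <- sample(0:1, nGametes, replace = TRUE)
    for (j in seq_len(nGametes)) {
      if (ks[j] == 0L) {
        if (phases[j] == 1L) K[idx, j] <- TRUE
      } else {
        xp <- sort(runif(ks[j], 0, len))
        K[idx, j] <- ((phases[j] + findInterval(posC, xp)) %% 2L) == 1L
      }
    }
  }
  K
}

## One generation of gametes from parents `par` (index per child): an
## n x nChildren matrix mixing each parent's two haplotype columns.
gameteBatch <- function(H, par, reg, recRate) {
  n <- reg$nUsed
  M1 <- H[seq_len(n), 2L * par - 1L, drop = FALSE]
  M2 <- H[seq_len(n), 2L * par, drop = FALSE]
  K <- meiosisMasks(reg, length(par), recRate)
  M1[K] <- M2[K]
  M1
}

## Breed nGenerations from the founder pair. Returns final-generation
## haplotype matrix (n columns per 2 haplotypes) and the updated registry.
runPedigree <- function(H0, reg, config, bottleneck = FALSE) {
  nF <- config$nBreedingFemales
  N <- 2L * nF                               # nF females then nF males
  nMax <- nrow(H0)
  H <- H0
  parentPair <- rep(0L, ncol(H) / 2L)
  curN <- ncol(H) / 2L

  for (gen in seq_len(config$nGenerations)) {
    reg <- refreshChromIdx(reg)
    atBottleneck <- bottleneck && !is.null(config$bottleneckGeneration) &&
      gen == config$bottleneckGeneration
    if (curN == 2L) {
      pairs <- matrix(c(1L, 2L), ncol = 2L)  # founder cross
    } else {
      nPairs <- if (atBottleneck) min(config$bottleneckPairs, nF) else
        min(nF, curN - nF)
      females <- sample(seq_len(nF), nPairs)
      males <- nF + sample(seq_len(curN - nF), nPairs)
      for (p in seq_len(nPairs)) {          # avoid full-sib matings if possible
        if (parentPair[females[p]] == parentPair[males[p]]) {
          alt <- setdiff(which(parentPair[(nF + 1L):curN] !=
                                 parentPair[females[p]]) + nF, males)
          if (length(alt)) males[p] <- alt[sample.int(length(alt), 1L)]
        }
      }
      pairs <- cbind(females, males)
    }

    pIdx <- ((seq_len(N) - 1L) %% nrow(pairs)) + 1L
    G1 <- gameteBatch(H, pairs[pIdx, 1L], reg, config$recombinationRate)
    G2 <- gameteBatch(H, pairs[pIdx, 2L], reg, config$recombinationRate)
    Hn <- matrix(FALSE, nrow = nMax, ncol = 2L * N)
    nRow <- nrow(G1)
    Hn[seq_len(nRow), seq(1L, 2L * N, by = 2L)] <- G1
    Hn[seq_len(nRow), seq(2L, 2L * N, by = 2L)] <- G2
    if (config$deNovoRate > 0) {
      nNew <- rpois(N, config$deNovoRate)
      for (child in which(nNew > 0L)) {
        for (j in seq_len(min(nNew[child], nMax - reg$nUsed))) {
          reg$nUsed <- reg$nUsed + 1L         # generous capacity guard above
          loc <- drawDeNovoLocus(reg)
          reg$keys[reg$nUsed] <- loc$key
          reg$chromName[reg$nUsed] <- loc$chrom
          reg$pos[reg$nUsed] <- loc$pos
          Hn[reg$nUsed, 2L * child - sample(0:1, 1L)] <- TRUE
        }
      }
    }
    H <- Hn
    parentPair <- pIdx + gen * 10000L
    curN <- N
  }
  list(H = H, n = curN, registry = reg)
}

sampleGenotypes <- function(res, nSampled, nLoci) {
  if (nSampled > res$n)
    stop("cannot sample ", nSampled, " animals from a colony of ", res$n)
  pick <- sample(seq_len(res$n), nSampled)
  g <- vapply(pick, function(a)
    as.integer(res$H[seq_len(nLoci), 2L * a - 1L]) +
      as.integer(res$H[seq_len(nLoci), 2L * a]),
    integer(nLoci))
  matrix(g, nrow = nLoci)
}

#' Simulate a closed breeding colony
#'
#' Forward-time diploid simulation: the colony is founded by two identical
#' F1 hybrids of the parental strains (one strain-A plus one strain-B
#' haplotype each), then bred under \code{config} with random non-sibling
#' pairing, per-chromosome Poisson recombination, Poisson de novo mutation,
#' and an optional single-generation bottleneck. At the end,
#' \code{nSampledAnimals} animals are drawn from the final generation and
#' their diploid genotypes at every locus segregating among them are
#' returned.
#'
#' Every emitted variant carries a truth provenance class in
#' \code{both_parents}, \code{a_only}, \code{b_only},
#' \code{known_nonparental}, \code{private}; de novo variants are
#' \code{private}. Identical seeds give identical output.
#'
#' @param catalogs a [ParentalCatalogs] object.
#' @param config a [pedigreeConfig()].
#' @param nSampledAnimals animals sampled from the final generation.
#' @param founderKnownExtra non-parental known-set variants planted
#'   heterozygous on founder haplotypes (models catalog false negatives).
#' @param founderPrivate novel variants planted heterozygous on founder
#'   haplotypes.
#' @param colonyLabel colony label attached to every sample.
#' @return A [GenotypeTable] with per-variant \code{truthClass} in rowData.
#' @export
simulateColony <- function(catalogs, config, nSampledAnimals = 5L,
                           founderKnownExtra = 0L, founderPrivate = 0L,
                           colonyLabel = "colony1") {
  stopifnot(is(catalogs, "ParentalCatalogs"), inherits(config, "PedigreeConfig"))
  if (!length(catalogA(catalogs)) && !length(catalogB(catalogs)))
    stop("catalogs are empty")
  withSeed(config$seed, {
    f <- buildFounders(catalogs, founderKnownExtra, founderPrivate,
                       deNovoCap(config))
    res <- runPedigree(f$H, f$registry, config,
                       bottleneck = !is.null(config$bottleneckGeneration))
    reg <- res$registry
    gt <- sampleGenotypes(res, nSampledAnimals, reg$nUsed)
    seg <- rowSums(gt) > 0L
    GenotypeTable(gt[seg, , drop = FALSE], reg$keys[seq_len(reg$nUsed)][seg],
                  rep(colonyLabel, nSampledAnimals),
                  truthClass = reg$truth[seq_len(reg$nUsed)][seg])
  })
}

#' Simulate two colonies split from the same founders
#'
#' Both colonies descend from the same pair of F1 founders (and share any
#' planted founder variation) but breed independently for
#' \code{config$nGenerations}; the second colony experiences the bottleneck
#' configured in \code{config} (if any), the first never does. This is the
#' two-lineage design used to study divergence and founder-effect direction.
#'
#' @inheritParams simulateColony
#' @param nSampledPerColony integer vector of length 2.
#' @param colonyLabels labels for the two colonies.
#' @return A [GenotypeTable] combining samples from both colonies.
#' @export
simulateColonyPair <- function(catalogs, config, nSampledPerColony = c(5L, 2L),
                               founderKnownExtra = 0L, founderPrivate = 0L,
                               colonyLabels = c("colony1", "colony2")) {
  stopifnot(is(catalogs, "ParentalCatalogs"), inherits(config, "PedigreeConfig"))
  withSeed(config$seed, {
    f <- buildFounders(catalogs, founderKnownExtra, founderPrivate,
                       deNovoCap(config, nColonies = 2L))
    res1 <- runPedigree(f$H, f$registry, config, bottleneck = FALSE)
    ## colony 2 restarts from the same founders; its registry continues from
    ## colony 1's so every de novo locus is globally unique
    res2 <- runPedigree(f$H, res1$registry, config,
                        bottleneck = !is.null(config$bottleneckGeneration))
    reg <- res2$registry
    g1 <- sampleGenotypes(res1, nSampledPerColony[1L], reg$nUsed)
    g2 <- sampleGenotypes(res2, nSampledPerColony[2L], reg$nUsed)
    gt <- cbind(g1, g2)
    colnames(gt) <- c(sprintf("%s_animal%d", colonyLabels[1L],
                              seq_len(nSampledPerColony[1L])),
                      sprintf("%s_animal%d", colonyLabels[2L],
                              seq_len(nSampledPerColony[2L])))
    seg <- rowSums(gt) > 0L
    GenotypeTable(gt[seg, , drop = FALSE], reg$keys[seq_len(reg$nUsed)][seg],
                  rep(colonyLabels, nSampledPerColony),
                  truthClass = reg$truth[seq_len(reg$nUsed)][seg])
  })
}
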