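## Multi-copy tandem transgene array: pooled pileup simulator ---------------

#' Configuration of a tandem transgene array
#'
#' Describes a head-to-tail tandem array of \code{nCopies} identical
#' monomers (defaults follow the MutaMouse lambda-gt10/lacZ array: a
#' 47,588 bp monomer present in about 29 copies). \emph{Constitutional}
#' variants are present on every copy and therefore appear at pooled allele
#' fraction near 1; \emph{private} variants sit on exactly one copy and
#' appear near \code{1/nCopies}. A multi-allelic constitutional entry (alt
#' \code{"C,A,G"}) distributes its alternates across copies.
#'
#' @param monomerLength monomer length in bp.
#' @param nCopies array copy number.
#' @param constitutionalVariants data.frame with columns \code{pos},
#'   \code{ref}, \code{alt} (alt may be comma-separated for multi-allelic
#'   sites); planted on every copy.
#' @param privateVariantRate expected private variants per copy (Poisson).
#' @param depth mean pooled read depth per position.
#' @param errorRate per-base sequencing error rate (uniform substitution).
#' @param seed RNG seed.
#' @return Configuration list of class \code{TransgeneArrayConfig}.
#' @export
transgeneArrayConfig <- function(monomerLength = 47588L, nCopies = 29L,
                                 constitutionalVariants = NULL,
                                 privateVariantRate = 0.5, depth = 1000,
                                 errorRate = 0.002, seed = 1L) {
  if (nCopies < 1L) stop("nCopies must be >= 1")
  cv <- constitutionalVariants
  if (is.null(cv)) cv <- data.frame(pos = integer(), ref = character(),
                                    alt = character())
  if (any(cv$pos > monomerLength) || any(cv$pos < 1L))
    stop("constitutional variant position outside the monomer")
  structure(list(monomerLength = as.integer(monomerLength),
                 nCopies = as.integer(nCopies),
                 constitutionalVariants = cv,
                 privateVariantRate = privateVariantRate,
                 depth = depth, errorRate = errorRate,
                 seed = as.integer(seed)),
            class = "TransgeneArrayConfig")
}

#' Simulate a pooled pileup over a transgene array
#'
#' All copies of the array are collapsed onto monomer coordinates, as in
#' pooled short-read alignment against a single monomer reference. Depth
#' per position is Poisson(\code{depth}); each read reports its source
#' copy's allele with probability \code{1 - errorRate}, otherwise a random
#' other base. Constitutional variants sit on every copy; private variants
#' (Poisson(\code{privateVariantRate * nCopies}) of them, at positions
#' distinct from each other and from constitutional sites) each sit on one
#' copy. With \code{nCopies = 1} every planted variant is constitutional by
#' construction and the truth lists reflect that.
#'
#' @param config a [transgeneArrayConfig()].
#' @return List with \code{pileup} (a [TransgenePileup]),
#'   \code{constitutionalTruth} and \code{privateTruth} (data.frames with
#'   \code{pos}, \code{ref}, \code{alt}; private also \code{copy}).
#' @export
simulateTransgenePileup <- function(config) {
  stopifnot(inherits(config, "TransgeneArrayConfig"))
  L <- config$monomerLength; nc <- config$nCopies
  err <- config$errorRate
  withSeed(config$seed, {
    cv <- config$constitutionalVariants
    nPriv <- rpois(1L, config$privateVariantRate * nc)
    free <- setdiff(seq_len(L), cv$pos)
    privPos <- sort(sample(free, min(nPriv, length(free))))
    privRef <- sample(BASES, length(privPos), replace = TRUE)
    privAlt <- vapply(privRef, function(r) sample(setdiff(BASES, r), 1L),
                      character(1))
    privCopy <- sample.int(nc, length(privPos), replace = TRUE)
    priv <- data.frame(pos = privPos, ref = privRef, alt = privAlt,
                       copy = privCopy)

    depth <- rpois(L, config$depth)
    rows <- list()
    emit <- function(pos, ref, alleles, copies) {
      ## `alleles` per copy (length nCopies): observed allele of each copy
      d <- depth[pos]
      if (d == 0L) return()
      src <- sample.int(nc, d, replace = TRUE)
      obs <- alleles[src]
      isErr <- runif(d) < err
      if (any(isErr))
        obs[isErr] <- vapply(obs[isErr], function(a)
          sample(setdiff(BASES, substr(a, 1L, 1L)), 1L), character(1))
      tab <- table(obs)
      for (al in names(tab)) if (al != ref)
        rows[[length(rows) + 1L]] <<- data.frame(
          pos = pos, ref = ref, alt = al, count = as.integer(tab[[al]]))
    }

    for (i in seq_len(nrow(cv))) {
      alts <- strsplit(cv$alt[i], ",", fixed = TRUE)[[1L]]
      perCopy <- rep(alts, length.out = nc)      # alternates across copies
      emit(cv$pos[i], cv$ref[i], perCopy, seq_len(nc))
    }
    for (i in seq_along(privPos)) {
      perCopy <- rep(priv$ref[i], nc)
      perCopy[priv$copy[i]] <- priv$alt[i]
      emit(priv$pos[i], priv$ref[i], perCopy, priv$copy[i])
    }

    ## background sequencing error at all remaining positions (sparse)
    bg <- setdiff(seq_len(L), c(cv$pos, privPos))
    errN <- rbinom(length(bg), depth[bg], err)
    hasErr <- errN > 0L
    if (any(hasErr)) {
      bgRef <- sample(BASES, sum(hasErr), replace = TRUE)
      bgAlt <- vapply(bgRef, function(r) sample(setdiff(BASES, r), 1L),
                      character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        pos = bg[hasErr], ref = bgRef, alt = bgAlt, count = errN[hasErr])
    }

    ac <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pos = integer(), ref = character(), alt = character(),
                 count = integer())
    ac <- ac[order(ac$pos, ac$alt), , drop = FALSE]
    rownames(ac) <- NULL
    pileup <- TransgenePileup(L, nc, depth, ac)

    constTruth <- cv
    privTruth <- priv
    if (nc == 1L && nrow(priv)) {          # single copy: everything is on it
      constTruth <- rbind(cv, priv[, c("pos", "ref", "alt")])
      privTruth <- priv[0L, ]
    }
    list(pileup = pileup, constitutionalTruth = constTruth,
         privateTruth = privTruth)
  })
}

#' Read a constitutional-variant table
#'
#' Reads a TSV with columns \code{pos}, \code{ref}, \code{alt} (alt may be
#' comma-separated for multi-allelic sites), such as the bundled
#' \code{extdata/table5_variants.tsv} fixture listing the 18 constitutional
#' variant sites of the MutaMouse transgene monomer.
#'
#' @param path file path.
#' @return data.frame with \code{pos}, \code{ref}, \code{alt}.
#' @export
readConstitutionalTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("integer", "character", "character"))
  stopifnot(all(c("pos", "ref", "alt") %in% names(df)))
  df
}
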