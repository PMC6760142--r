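## Planted CNV truth sets and their two observation layers ------------------
## (noisy aCGH probe log2 ratios, Poisson binned read depth)

#' Plant a CNV truth set
#'
#' Generates non-overlapping copy-number events on one chromosome. A
#' fraction of events are \emph{complex clusters}: the recorded event is
#' the union span of 2-4 dosage-bearing sub-events separated by normal-copy
#' gaps, emulating array calls that read-depth data reveal to be composed
#' of many small deletions and gains. The rest are \emph{simple} events
#' whose single sub-event equals the event span.
#'
#' @param nEvents number of top-level events.
#' @param genomeLength chromosome length in bp.
#' @param chrom chromosome name.
#' @param sizeRange sub-event length range in bp.
#' @param copyNumbers copy numbers sampled for sub-events (diploid baseline 2).
#' @param complexFraction fraction of events that are complex clusters.
#' @param minGap minimum gap between events (and between sub-events, bp).
#' @param seed RNG seed.
#' @return A \code{CnvTruthSet}: list with \code{events} (GRanges; mcols
#'   \code{complexity}, \code{nSubEvents}, \code{copyNumber} — NA for
#'   clusters) and \code{subEvents} (GRanges; mcols \code{copyNumber},
#'   \code{eventId}).
#' @export
plantCnvTruth <- function(nEvents, genomeLength, chrom = "chr1",
                          sizeRange = c(1000, 5000),
                          copyNumbers = c(0L, 1L, 3L, 4L),
                          complexFraction = 0, minGap = 2000, seed = 1L) {
  stopifnot(nEvents >= 0)
  withSeed(seed, {
    evs <- list(); subs <- list()
    cursor <- 1
    ## lay events left to right with random spacing, then check we fit
    for (i in seq_len(nEvents)) {
      complex <- runif(1L) < complexFraction
      nSub <- if (complex) sample(2:4, 1L) else 1L
      lens <- round(runif(nSub, sizeRange[1L], sizeRange[2L]))
      gaps <- if (nSub > 1L) round(runif(nSub - 1L, minGap, 2 * minGap)) else integer()
      span <- sum(lens) + sum(gaps)
      lead <- round(runif(1L, minGap, 4 * minGap))
      evStart <- cursor + lead
      s <- evStart
      for (j in seq_len(nSub)) {
        cn <- sample(copyNumbers, 1L)
        subs[[length(subs) + 1L]] <- data.frame(
          start = s, end = s + lens[j] - 1L, copyNumber = cn, eventId = i)
        s <- s + lens[j] + if (j < nSub) gaps[j] else 0L
      }
      evs[[length(evs) + 1L]] <- data.frame(
        start = evStart, end = evStart + span - 1L,
        complexity = if (complex) "complex_cluster" else "simple",
        nSubEvents = nSub)
      cursor <- evStart + span
    }
    if (nEvents > 0 && cursor > genomeLength)
      stop("genomeLength too small for the requested events")
    ev <- do.call(rbind, evs %||% list(data.frame()))
    sb <- do.call(rbind, subs %||% list(data.frame()))
    events <- if (nEvents > 0)
      GRanges(chrom, IRanges(ev$start, ev$end), complexity = ev$complexity,
              nSubEvents = ev$nSubEvents,
              copyNumber = ifelse(ev$nSubEvents == 1L,
                                  sb$copyNumber[match(seq_len(nEvents),
                                                      sb$eventId)], NA))
      else GRanges()
    subEvents <- if (nEvents > 0)
      GRanges(chrom, IRanges(sb$start, sb$end), copyNumber = sb$copyNumber,
              eventId = sb$eventId)
      else GRanges()
    structure(list(events = events, subEvents = subEvents,
                   genomeLength = genomeLength, chrom = chrom),
              class = "CnvTruthSet")
  })
}

truthSubEvents <- function(truth) {
  if (inherits(truth, "CnvTruthSet")) truth$subEvents
  else if (is(truth, "GRanges")) truth
  else stop("truth must be a CnvTruthSet or a GRanges with copyNumber")
}

#' Simulate a binned coverage track over a CNV truth set
#'
#' Per-bin read depth is Poisson with mean \code{baseDepth} scaled by
#' \code{copyNumber/2} over the portion of the bin covered by a dosage
#' event (bins partially covered by an event get the overlap-weighted
#' expectation).
#'
#' @param truth a \code{CnvTruthSet} (its sub-events carry the dosage) or a
#'   GRanges with a \code{copyNumber} column; events must not overlap.
#' @param genomeLength chromosome length in bp.
#' @param binSize bin width in bp.
#' @param baseDepth expected diploid depth per bin position.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return A [CoverageTrack].
#' @export
simulateCoverage <- function(truth, genomeLength, binSize = 250L,
                             baseDepth = 50, seed = 1L, chrom = "chr1") {
  if (binSize < 1) stop("binSize must be >= 1")
  ev <- truthSubEvents(truth)
  if (length(ev) > 1L && sum(width(reduce(ev))) != sum(width(ev)))
    stop("truth events overlap")
  withSeed(seed, {
    nBins <- ceiling(genomeLength / binSize)
    mult <- rep(1, nBins)
    for (i in seq_along(ev)) {
      cn <- mcols(ev)$copyNumber[i]
      b1 <- (start(ev)[i] - 1L) %/% binSize + 1L
      b2 <- (end(ev)[i] - 1L) %/% binSize + 1L
      for (b in b1:b2) {
        binS <- (b - 1L) * binSize + 1L; binE <- b * binSize
        ov <- (min(binE, end(ev)[i]) - max(binS, start(ev)[i]) + 1) / binSize
        mult[b] <- mult[b] + ov * (cn / 2 - 1)
      }
    }
    CoverageTrack(chrom, binSize, rpois(nBins, baseDepth * pmax(mult, 0)))
  })
}

#' Simulate aCGH probes over a CNV truth set
#'
#' Probes are laid at jittered spacing along the chromosome; each probe's
#' expected log2 ratio is \code{log2(copyNumber/2)} inside a dosage event
#' (floored at \code{log2(0.05)} for copy 0) and 0 outside, with Gaussian
#' noise of sd \code{noiseSd}.
#'
#' @inheritParams simulateCoverage
#' @param meanSpacing mean probe spacing in bp.
#' @param spacingJitter fractional jitter on the spacing.
#' @param noiseSd Gaussian noise sd in log2 units.
#' @return A [ProbeSet].
#' @export
simulateProbes <- function(truth, genomeLength, meanSpacing = 2000,
                           spacingJitter = 0.3, noiseSd = 0.15, seed = 1L,
                           chrom = "chr1") {
  if (meanSpacing <= 0) stop("meanSpacing must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  ev <- truthSubEvents(truth)
  withSeed(seed, {
    n <- ceiling(genomeLength / meanSpacing) + 10L
    steps <- meanSpacing * (1 + runif(n, -spacingJitter, spacingJitter))
    pos <- round(cumsum(steps))
    pos <- unique(pos[pos >= 1 & pos <= genomeLength])
    mu <- rep(0, length(pos))
    if (length(ev)) {
      hits <- findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)), ev)
      cn <- mcols(ev)$copyNumber[subjectHits(hits)]
      mu[queryHits(hits)] <- ifelse(cn == 0, log2(0.05), log2(cn / 2))
    }
    ProbeSet(chrom, pos, mu + rnorm(length(pos), 0, noiseSd))
  })
}
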