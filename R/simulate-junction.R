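## Transgene integration locus: reference + chimeric long-read simulator ----

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcompStr <- function(x)
  as.character(reverseComplement(DNAString(x)))

complementBase <- function(b) chartr("ACGT", "TGCA", b)

#' Configuration of a transgene integration locus
#'
#' Describes the architecture of a tandem-array integration site of the
#' kind seen at the MutaMouse locus on chromosome 3: a large host deletion
#' whose upstream breakpoint carries an inverted copy of host sequence from
#' near the downstream breakpoint, a few inserted nucleotides, and a
#' truncated transgene monomer entering the array; at the downstream
#' breakpoint the array exits through another truncated monomer joined to
#' the host with a short microhomology.
#'
#' The \code{deletion} is given as (first deleted base, first retained base
#' after the deletion), so its printed length follows the difference
#' convention; the \code{inversion} is a 1-based inclusive source span.
#'
#' @param hostChrom host chromosome name.
#' @param hostWindow c(start, end): simulated host window (1-based incl.).
#' @param deletion c(start, end) as described above; must lie in the window.
#' @param inversion c(start, end) source span of the inverted segment; must
#'   lie inside or adjacent to the deletion.
#' @param nInsertedBases random nucleotides inserted at the upstream
#'   junction (ignored when \code{insertedBases} is given).
#' @param insertedBases explicit inserted sequence, or NULL to draw.
#' @param microhomologyLenDownstream exact shared-terminal-base count at the
#'   downstream junction.
#' @param upstreamMonomerRange,downstreamMonomerRange monomer coordinate
#'   ranges of the truncated copies at the two breakpoints.
#' @param monomerLength transgene monomer length in bp.
#' @param nFullCopies full monomer copies simulated between the truncated
#'   ones (the real array has ~27 more; reads only ever span junctions).
#' @param oriRange monomer coordinates of the replication origin.
#' @param cosLength length of each cohesive-end segment at the monomer ends.
#' @param readLengthMean,readErrorRate,nSpanningReads long-read parameters;
#'   errors are uniform substitutions.
#' @param seed RNG seed.
#' @return Configuration list of class \code{JunctionConfig}.
#' @export
junctionConfig <- function(hostChrom = "chr1",
                           hostWindow = c(1L, 120000L),
                           deletion = c(30001L, 80001L),
                           inversion = c(79631L, 80000L),
                           nInsertedBases = 4L, insertedBases = NULL,
                           microhomologyLenDownstream = 2L,
                           upstreamMonomerRange = c(30001L, 47588L),
                           downstreamMonomerRange = c(1L, 40000L),
                           monomerLength = 47588L, nFullCopies = 1L,
                           oriRange = c(20001L, 20600L), cosLength = 12L,
                           readLengthMean = 15000, readErrorRate = 0,
                           nSpanningReads = 3L, seed = 1L) {
  if (deletion[1L] <= hostWindow[1L] || deletion[2L] >= hostWindow[2L])
    stop("deletion must lie strictly inside the host window")
  if (inversion[1L] < deletion[1L] || inversion[2L] > deletion[2L])
    stop("inversion must lie inside or adjacent to the deletion")
  if (readErrorRate < 0 || readErrorRate >= 1)
    stop("readErrorRate must lie in [0, 1)")
  if (upstreamMonomerRange[2L] > monomerLength ||
      downstreamMonomerRange[2L] > monomerLength)
    stop("monomer ranges exceed the monomer length")
  structure(list(hostChrom = hostChrom, hostWindow = as.integer(hostWindow),
                 deletion = as.integer(deletion),
                 inversion = as.integer(inversion),
                 nInsertedBases = as.integer(nInsertedBases),
                 insertedBases = insertedBases,
                 microhomologyLenDownstream = as.integer(microhomologyLenDownstream),
                 upstreamMonomerRange = as.integer(upstreamMonomerRange),
                 downstreamMonomerRange = as.integer(downstreamMonomerRange),
                 monomerLength = as.integer(monomerLength),
                 nFullCopies = as.integer(nFullCopies),
                 oriRange = as.integer(oriRange),
                 cosLength = as.integer(cosLength),
                 readLengthMean = readLengthMean,
                 readErrorRate = readErrorRate,
                 nSpanningReads = as.integer(nSpanningReads),
                 seed = as.integer(seed)),
            class = "JunctionConfig")
}

#' The published MutaMouse integration architecture
#'
#' Preset encoding the reported chromosome 3 integration locus: a deletion
#' spanning chr3:37,971,249-38,436,675 (465,426 bp under the difference
#' convention), an inverted copy of chr3:38,436,306-38,436,675 (370 bp,
#' inclusive) joined to the upstream breakpoint, four inserted nucleotides,
#' and a 2 bp microhomology at the downstream junction. Host and monomer
#' base content is synthetic; only the structure (coordinates, lengths,
#' order, strands) follows the published locus.
#'
#' @param flank retained host flank simulated on each side of the deletion.
#' @param ... overrides passed to [junctionConfig()].
#' @return A \code{JunctionConfig}.
#' @export
publishedArchitecture <- function(flank = 25000L, ...) {
  junctionConfig(hostChrom = "chr3",
                 hostWindow = c(37971249L - flank, 38436675L + flank),
                 deletion = c(37971249L, 38436675L),
                 inversion = c(38436306L, 38436675L),
                 nInsertedBases = 4L, microhomologyLenDownstream = 2L,
                 ...)
}

## Host-window and monomer sequences honoring the configured junction
## geometry. Synthetic bases are drawn at random, then a handful of bases at
## the junction edges are constrained so that (a) the downstream junction
## shares exactly the configured number of terminal bases and (b) no
## accidental single-base homology extends an anchor chain across a
## junction. The k-mers flanking each junction are checked for uniqueness
## and the draw is rejected and repeated if they collide.
#' Generate host and monomer references for an integration locus
#'
#' @param config a [junctionConfig()].
#' @param k anchor k-mer size whose junction-edge uniqueness is enforced.
#' @return List with \code{host} (character, the window sequence),
#'   \code{monomer} (character) and \code{config} (the input with
#'   \code{insertedBases} filled in).
#' @export
simulateIntegrationReferences <- function(config, k = 15L) {
  stopifnot(inherits(config, "JunctionConfig"))
  withSeed(config$seed, {
    ws <- config$hostWindow[1L]
    wlen <- config$hostWindow[2L] - ws + 1L
    m <- config$microhomologyLenDownstream
    delStart <- config$deletion[1L]; resume <- config$deletion[2L]
    invS <- config$inversion[1L]; invE <- config$inversion[2L]
    dEnd <- config$downstreamMonomerRange[2L]
    uStart <- config$upstreamMonomerRange[1L]
    loc <- function(x) x - ws + 1L           # window-local coordinate

    for (try in seq_len(20L)) {
      host <- strsplit(randSeq(wlen), "")[[1L]]
      monomer <- strsplit(randSeq(config$monomerLength), "")[[1L]]

      ## (a) downstream microhomology: host bases at the resume point copy
      ## the monomer tail for exactly m bases
      if (m > 0L)
        host[loc(resume) + 0:(m - 1L)] <- monomer[dEnd - m + 1L + 0:(m - 1L)]
      ## first non-shared host base breaks both the microhomology extension
      ## and any monomer-anchor overrun
      excl <- c(monomer[dEnd],
                if (dEnd < config$monomerLength) monomer[dEnd + 1L])
      if (m == 1L) excl <- c(excl, complementBase(host[loc(delStart) - 1L]))
      host[loc(resume) + m] <- sample(setdiff(BASES, excl), 1L)
      ## deleted base before the resume point must not extend the retained
      ## host anchor chain leftward across the junction
      host[loc(resume) - 1L] <- sample(setdiff(BASES, monomer[dEnd - m]), 1L)
      ## deleted base after the upstream breakpoint must not mimic the
      ## first base of the inverted segment
      host[loc(delStart)] <- sample(
        setdiff(BASES, complementBase(host[loc(invE)])), 1L)
      ## inverted-segment anchors must not extend past the inversion source
      if (m != 1L) {
        bad <- complementBase(host[loc(delStart) - 1L])
        if (m >= 2L) {                        # host[resume+1] is pinned
          if (host[loc(invE) + 1L] == bad)
            host[loc(delStart) - 1L] <- sample(
              setdiff(BASES, complementBase(host[loc(invE) + 1L])), 1L)
        } else {                              # m == 0: resume+1 is free
          host[loc(resume) + 1L] <- sample(setdiff(BASES, bad), 1L)
        }
      }

      ## inserted bases: random, but not extending a flanking anchor chain
      ins <- config$insertedBases
      nIns <- if (is.null(ins)) config$nInsertedBases else nchar(ins)
      if (is.null(ins) && nIns > 0L) {
        insV <- sample(BASES, nIns, replace = TRUE)
        insV[1L] <- sample(setdiff(BASES,
                                   complementBase(host[loc(invS) - 1L])), 1L)
        if (uStart > 1L)
          insV[nIns] <- sample(setdiff(BASES, monomer[uStart - 1L]), 1L)
        ins <- paste(insV, collapse = "")
      } else if (is.null(ins)) ins <- ""

      hostStr <- paste(host, collapse = "")
      monomerStr <- paste(monomer, collapse = "")

      ## (b) junction-edge k-mers must be unique within their reference
      edges <- c(substr(hostStr, loc(delStart) - k, loc(delStart) - 1L),
                 substr(hostStr, loc(resume), loc(resume) + k - 1L),
                 substr(hostStr, loc(invS), loc(invS) + k - 1L),
                 substr(hostStr, loc(invE) - k + 1L, loc(invE)),
                 substr(monomerStr, uStart, uStart + k - 1L),
                 substr(monomerStr, dEnd - k + 1L, dEnd))
      uniqueIn <- function(pat, s) {
        lengths(gregexpr(pat, s, fixed = TRUE)) == 1L
      }
      ok <- all(vapply(edges[1:4], uniqueIn, logical(1), s = hostStr)) &&
        all(vapply(edges[5:6], uniqueIn, logical(1), s = monomerStr))
      if (ok) {
        cfg <- config; cfg$insertedBases <- ins
        return(list(host = hostStr, monomer = monomerStr, config = cfg))
      }
    }
    stop("could not generate junction references satisfying the constraints")
  })
}

## Assemble the post-integration locus sequence and its truth blocks.
buildIntegrationLocus <- function(config, host, monomer) {
  ws <- config$hostWindow[1L]
  loc <- function(x) x - ws + 1L
  m <- config$microhomologyLenDownstream
  delStart <- config$deletion[1L]; resume <- config$deletion[2L]
  invS <- config$inversion[1L]; invE <- config$inversion[2L]
  uR <- config$upstreamMonomerRange; dR <- config$downstreamMonomerRange
  L <- config$monomerLength
  ins <- config$insertedBases %||% ""

  pieces <- list(
    list(seq = substr(host, 1L, loc(delStart) - 1L), label = "host",
         refStart = ws, refEnd = delStart - 1L, strand = "+"),
    list(seq = revcompStr(substr(host, loc(invS), loc(invE))),
         label = "host_inverted", refStart = invS, refEnd = invE,
         strand = "-"),
    if (nzchar(ins)) list(seq = ins, label = "insert", refStart = NA,
                          refEnd = NA, strand = "+"),
    list(seq = substr(monomer, uR[1L], uR[2L]), label = "transgene",
         refStart = uR[1L], refEnd = uR[2L], strand = "+"))
  for (i in seq_len(config$nFullCopies))
    pieces[[length(pieces) + 1L]] <- list(seq = monomer, label = "transgene",
                                          refStart = 1L, refEnd = L,
                                          strand = "+")
  pieces[[length(pieces) + 1L]] <-
    list(seq = substr(monomer, dR[1L], dR[2L]), label = "transgene",
         refStart = dR[1L], refEnd = dR[2L], strand = "+")
  ## the shared microhomology bases appear once: host resumes m bases in
  pieces[[length(pieces) + 1L]] <-
    list(seq = substr(host, loc(resume) + m, nchar(host)), label = "host",
         refStart = resume + m, refEnd = config$hostWindow[2L], strand = "+")
  pieces <- Filter(Negate(is.null), pieces)

  seqs <- vapply(pieces, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  blocks <- data.frame(
    label = vapply(pieces, `[[`, character(1), "label"),
    locusStart = offs + 1L, locusEnd = offs + lens,
    refStart = vapply(pieces, function(p) as.numeric(p$refStart), numeric(1)),
    refEnd = vapply(pieces, function(p) as.numeric(p$refEnd), numeric(1)),
    strand = vapply(pieces, `[[`, character(1), "strand"))
  list(locus = paste(seqs, collapse = ""), blocks = blocks)
}

#' Simulate chimeric long reads across a transgene integration locus
#'
#' Builds the post-integration locus sequence implied by \code{config} and
#' the supplied references, then draws \code{nSpanningReads} long reads
#' across each breakpoint junction (plus optional background reads),
#' applying uniform substitution errors. Returns the reads together with
#' the truth [JunctionModel].
#'
#' @param config a [junctionConfig()] whose \code{insertedBases} is set
#'   (use [simulateIntegrationReferences()] to generate matching inputs).
#' @param host host window sequence (character or DNAString).
#' @param monomer transgene monomer sequence (character or DNAString).
#' @param nBackgroundReads host-only reads added for realism.
#' @return List with \code{reads} (a [Biostrings::DNAStringSet]),
#'   \code{truth} (a [JunctionModel]), \code{locus} (character) and
#'   \code{locusBlocks} (data.frame).
#' @export
simulateIntegrationReads <- function(config, host, monomer,
                                     nBackgroundReads = 0L) {
  stopifnot(inherits(config, "JunctionConfig"))
  host <- as.character(host); monomer <- as.character(monomer)
  if (nchar(host) != config$hostWindow[2L] - config$hostWindow[1L] + 1L)
    stop("host sequence length does not match the configured window")
  if (nchar(monomer) != config$monomerLength)
    stop("monomer sequence length does not match the configuration")
  withSeed(config$seed + 101L, {
    bl <- buildIntegrationLocus(config, host, monomer)
    locus <- bl$locus; blocks <- bl$blocks
    locusLen <- nchar(locus)
    jUp <- blocks$locusEnd[blocks$label == "host"][1L]        # upstream bp
    jDown <- blocks$locusStart[blocks$label == "host"][2L]    # downstream bp

    margin <- min(2000L, floor(config$readLengthMean / 4))
    drawRead <- function(center) {
      len <- max(4L * margin,
                 round(rnorm(1L, config$readLengthMean,
                             0.1 * config$readLengthMean)))
      lo <- max(1L, center + margin - len + 1L)
      hi <- min(center - margin, locusLen - len + 1L)
      st <- if (hi <= lo) lo else lo + floor(runif(1L) * (hi - lo + 1L))
      substr(locus, st, st + len - 1L)
    }
    reads <- character()
    for (j in c(jUp, jDown))
      for (i in seq_len(config$nSpanningReads))
        reads <- c(reads, drawRead(j))
    for (i in seq_len(nBackgroundReads)) {
      len <- round(config$readLengthMean)
      st <- 1L + floor(runif(1L) * max(1L, nchar(host) - len))
      reads <- c(reads, substr(host, st, st + len - 1L))
    }
    if (config$readErrorRate > 0) {
      reads <- vapply(reads, function(r) {
        n <- nchar(r)
        nErr <- rbinom(1L, n, config$readErrorRate)
        if (nErr == 0L) return(r)
        v <- strsplit(r, "")[[1L]]
        at <- sample.int(n, nErr)
        v[at] <- vapply(v[at], function(b) sample(setdiff(BASES, b), 1L),
                        character(1))
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    names(reads) <- sprintf("read%02d", seq_along(reads))

    truth <- junctionTruth(config, host, monomer)
    list(reads = DNAStringSet(reads), truth = truth, locus = locus,
         locusBlocks = blocks)
  })
}

## Truth model with microhomology computed from the actual sequences.
junctionTruth <- function(config, host, monomer) {
  ws <- config$hostWindow[1L]
  loc <- function(x) x - ws + 1L
  delStart <- config$deletion[1L]; resume <- config$deletion[2L]
  dEnd <- config$downstreamMonomerRange[2L]
  uR <- config$upstreamMonomerRange; dR <- config$downstreamMonomerRange
  invSeq <- revcompStr(substr(host, loc(config$inversion[1L]),
                              loc(config$inversion[2L])))
  mhUp <- microhomology(substr(host, 1L, loc(delStart) - 1L),
                        paste0(invSeq, config$insertedBases %||% ""))
  mhDown <- microhomology(substr(monomer, 1L, dEnd),
                          substr(host, loc(resume), nchar(host)))
  blocks <- buildIntegrationLocus(config, host, monomer)$blocks
  ori <- config$oriRange; cs <- config$cosLength; L <- config$monomerLength
  trunc <- list(
    upstream = list(range = uR,
                    oriFunctional = ori[1L] >= uR[1L] && ori[2L] <= uR[2L],
                    cohesiveEndPresent = uR[1L] <= cs && uR[2L] >= L - cs + 1L),
    downstream = list(range = dR,
                      oriFunctional = ori[1L] >= dR[1L] && ori[2L] <= dR[2L],
                      cohesiveEndPresent = dR[1L] <= cs && dR[2L] >= L - cs + 1L))
  JunctionModel(found = TRUE,
                blocks = blocks[, c("label", "refStart", "refEnd", "strand")],
                deletionSpan = c(delStart, resume),
                inversionSpan = config$inversion,
                insertedBases = config$insertedBases %||% "",
                microhomology = list(upstream = mhUp, downstream = mhDown),
                monomerTruncations = trunc)
}
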