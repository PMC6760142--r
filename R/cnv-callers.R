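## CNV calling from binned depth and from aCGH probes -----------------------

#' Call copy-number variants from a binned coverage track
#'
#' Scans a binned read-depth track for maximal runs of bins whose depth ratio
#' to the diploid baseline falls outside \code{[delRatio, dupRatio]}, merges
#' runs separated by at most \code{maxGapBins} discordant-free bins, and
#' retains runs whose summed depth departs from expectation under a Poisson
#' model. Significance is tested with a Poisson-approximate two-sided z-test
#' on the run's total read count; \code{alpha} is interpreted family-wise
#' over the genome scan and Bonferroni-corrected by the number of bins
#' scanned. Correcting only over the runs actually tested would not control
#' the scan-wide error rate, because candidate runs are pre-selected for
#' extreme bins.
#'
#' Copy number is estimated as \code{round(2 * mean depth ratio)}.
#'
#' @param track a [CoverageTrack].
#' @param baseDepth expected diploid depth (reads per bin position).
#' @param alpha family-wise significance level for the run test.
#' @param minBins minimum number of bins in a reported call.
#' @param delRatio,dupRatio per-bin depth-ratio thresholds flagging candidate
#'   loss/gain bins.
#' @param maxGapBins candidate runs separated by at most this many
#'   non-candidate bins are merged before testing (prevents one noisy bin
#'   from splitting a real event).
#' @return GRanges call set (see [intervalCalls()]) with \code{score} the
#'   absolute z statistic.
#' @export
callDepthCnvs <- function(track, baseDepth, alpha = 0.05, minBins = 2L,
                          delRatio = 0.75, dupRatio = 1.25, maxGapBins = 2L) {
  stopifnot(is(track, "CoverageTrack"))
  if (baseDepth <= 0) stop("baseDepth must be > 0")
  d <- binDepths(track)
  if (!length(d)) stop("empty coverage track")
  ratio <- d / baseDepth
  state <- integer(length(d))            # -1 loss candidate, +1 gain candidate
  state[ratio < delRatio] <- -1L
  state[ratio > dupRatio] <- 1L

  runs <- candidateRuns(state, maxGapBins)
  runs <- runs[(runs$end - runs$start + 1L) >= minBins, , drop = FALSE]
  if (!nrow(runs)) return(emptyCalls())

  nTests <- nrow(runs)
  nScan <- length(d)                     # scan-wide Bonferroni family
  keep <- logical(nTests); z <- numeric(nTests); cn <- integer(nTests)
  for (i in seq_len(nTests)) {
    idx <- runs$start[i]:runs$end[i]
    total <- sum(d[idx]); expect <- baseDepth * length(idx)
    z[i] <- (total - expect) / sqrt(expect)
    p <- 2 * pnorm(-abs(z[i]))
    keep[i] <- (p * nScan) < alpha
    cn[i] <- as.integer(round(2 * mean(ratio[idx])))
  }
  runs <- runs[keep, , drop = FALSE]; z <- z[keep]; cn <- cn[keep]
  if (!nrow(runs)) return(emptyCalls())

  bs <- binSize(track)
  intervalCalls(track@chrom,
                start = (runs$start - 1L) * bs + 1L,
                end = runs$end * bs,
                svtype = ifelse(runs$sign < 0L, "DEL", "DUP"),
                copyNumber = cn, source = "depth", score = abs(z),
                nSupport = 1L)
}

## Maximal same-sign candidate runs, merging across gaps of <= maxGap zeros.
candidateRuns <- function(state, maxGap) {
  idx <- which(state != 0L)
  if (!length(idx)) return(data.frame(start = integer(), end = integer(),
                                      sign = integer()))
  brk <- c(TRUE, diff(idx) > (maxGap + 1L) | state[idx[-1L]] != state[idx[-length(idx)]])
  grp <- cumsum(brk)
  data.frame(start = tapply(idx, grp, min), end = tapply(idx, grp, max),
             sign = tapply(state[idx], grp, function(s) s[1L]),
             row.names = NULL)
}

emptyCalls <- function()
  intervalCalls(character(), integer(), integer(), character())

#' Segment aCGH probes into copy-number calls
#'
#' A threshold-run segmenter: maximal runs of at least \code{minProbes}
#' consecutive probes whose log2 ratios all lie beyond \code{threshold} on
#' the same side of zero are emitted as calls spanning the first to last
#' probe of the run. This is a deliberately simple stand-in for a full
#' genome-alteration-detection segmentation; its calls exist to feed the
#' consensus and complexity-classification logic downstream.
#'
#' Copy number is \code{round(2 * 2^mean(log2 ratio))}.
#'
#' @param probes a [ProbeSet] (positions strictly increasing).
#' @param threshold absolute log2-ratio threshold.
#' @param minProbes minimum run length.
#' @return GRanges call set with \code{score} the mean |log2 ratio| and
#'   \code{nSupport} the probe count.
#' @export
segmentProbes <- function(probes, threshold = 0.3, minProbes = 3L) {
  stopifnot(is(probes, "ProbeSet"))
  pos <- probePositions(probes); lr <- probeLog2Ratios(probes)
  if (length(pos) < minProbes) stop("need at least minProbes probes")
  state <- integer(length(lr))
  state[lr < -threshold] <- -1L
  state[lr > threshold] <- 1L
  runs <- candidateRuns(state, maxGap = 0L)
  runs <- runs[(runs$end - runs$start + 1L) >= minProbes, , drop = FALSE]
  if (!nrow(runs)) return(emptyCalls())
  m <- vapply(seq_len(nrow(runs)),
              function(i) mean(lr[runs$start[i]:runs$end[i]]), numeric(1))
  intervalCalls(probes@chrom, start = pos[runs$start], end = pos[runs$end],
                svtype = ifelse(runs$sign < 0L, "DEL", "DUP"),
                copyNumber = as.integer(round(2 * 2^m)), source = "acgh",
                score = abs(m),
                nSupport = runs$end - runs$start + 1L)
}
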