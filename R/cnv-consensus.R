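## Cross-sample and cross-method CNV/SV integration -------------------------

#' Consensus calls across samples
#'
#' Retains a call if and only if a call of the same svtype with at least
#' \code{minReciprocalOverlap} reciprocal overlap exists in every sample
#' (\code{requireAll = TRUE}) or in at least \code{minSamples} samples.
#' The retained span is the intersection of the matched spans across
#' samples, with \code{nSupport} the number of supporting samples. The
#' result is independent of sample order and deduplicated.
#'
#' @param callsets list of per-sample call-set GRanges (see [intervalCalls()]).
#' @param minReciprocalOverlap reciprocal-overlap fraction for matching.
#' @param requireAll require support in every sample.
#' @param minSamples minimum supporting samples when \code{requireAll=FALSE}.
#' @return GRanges of consensus calls.
#' @export
consensusAcrossSamples <- function(callsets, minReciprocalOverlap = 0.5,
                                   requireAll = TRUE, minSamples = 2L) {
  if (!length(callsets)) stop("empty callset list")
  if (length(callsets) < 2L) stop("need at least 2 callsets")
  lapply(callsets, assertCalls)
  nS <- length(callsets)
  need <- if (requireAll) nS else as.integer(minSamples)

  out <- list()
  for (s in seq_len(nS)) {
    calls <- callsets[[s]]
    for (i in seq_along(calls)) {
      spans <- matchAcross(calls[i], callsets, minReciprocalOverlap)
      if (sum(!is.na(spans$start)) >= need) {
        use <- !is.na(spans$start)
        out[[length(out) + 1L]] <- data.frame(
          chrom = as.character(seqnames(calls[i])),
          start = max(spans$start[use]), end = min(spans$end[use]),
          svtype = mcols(calls[i])$svtype, nSupport = sum(use))
      }
    }
  }
  if (!length(out)) return(emptyCalls())
  df <- unique(do.call(rbind, out))
  df <- df[order(df$chrom, df$start, df$end, df$svtype), , drop = FALSE]
  intervalCalls(df$chrom, df$start, df$end, df$svtype,
                source = "consensus", nSupport = df$nSupport)
}

## Best same-svtype match of one call in each sample; NA spans when no match.
matchAcross <- function(call, callsets, minRo) {
  st <- en <- rep(NA_real_, length(callsets))
  for (s in seq_along(callsets)) {
    cs <- callsets[[s]]
    same <- cs[mcols(cs)$svtype == mcols(call)$svtype &
               as.character(seqnames(cs)) == as.character(seqnames(call))]
    if (!length(same)) next
    ro <- reciprocalOverlap(start(call), end(call), start(same), end(same))
    j <- which.max(ro)
    if (length(j) && ro[j] >= minRo) { st[s] <- start(same)[j]; en[s] <- end(same)[j] }
  }
  list(start = st, end = en)
}

#' Three-way method overlap (Venn regions)
#'
#' Clusters calls from three calling methods (aCGH segmentation, read-depth,
#' paired-end) into distinct merged events by single-linkage over
#' same-svtype reciprocal overlap, and counts events in each of the seven
#' Venn regions. Every merged event lands in exactly one region, so region
#' counts sum to the number of distinct events.
#'
#' @param acgh,depth,pairedend deduplicated call-set GRanges per method.
#' @param minReciprocalOverlap reciprocal-overlap fraction for matching.
#' @return Named integer vector with elements \code{acgh_only},
#'   \code{depth_only}, \code{pairedend_only}, \code{acgh_depth},
#'   \code{acgh_pairedend}, \code{depth_pairedend}, \code{all_three}.
#' @export
threewayOverlap <- function(acgh, depth, pairedend,
                            minReciprocalOverlap = 0.5) {
  sets <- list(acgh = acgh, depth = depth, pairedend = pairedend)
  lapply(sets, assertCalls)
  df <- do.call(rbind, lapply(names(sets), function(m) {
    g <- sets[[m]]
    if (!length(g)) return(NULL)
    data.frame(method = m, chrom = as.character(seqnames(g)),
               start = start(g), end = end(g), svtype = mcols(g)$svtype)
  }))
  regions <- c("acgh_only", "depth_only", "pairedend_only", "acgh_depth",
               "acgh_pairedend", "depth_pairedend", "all_three")
  counts <- setNames(integer(7), regions)
  if (is.null(df) || !nrow(df)) return(counts)

  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (df$method[i] == df$method[j]) next
    if (df$chrom[i] != df$chrom[j] || df$svtype[i] != df$svtype[j]) next
    ro <- reciprocalOverlap(df$start[i], df$end[i], df$start[j], df$end[j])
    if (ro >= minReciprocalOverlap) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  for (cp in unique(comp)) {
    methods <- sort(unique(df$method[comp == cp]))
    key <- paste(methods, collapse = "+")
    region <- switch(key,
      "acgh" = "acgh_only", "depth" = "depth_only",
      "pairedend" = "pairedend_only", "acgh+depth" = "acgh_depth",
      "acgh+pairedend" = "acgh_pairedend",
      "depth+pairedend" = "depth_pairedend",
      "acgh+depth+pairedend" = "all_three")
    counts[region] <- counts[region] + 1L
  }
  counts
}

#' Classify an aCGH call as a simple or complex event
#'
#' An array call is \code{complex} when more than one read-depth call
#' overlaps its span (any overlap, not strict containment, because depth
#' calls routinely cross array-call edges), and \code{simple} otherwise.
#' An array call overlapped by no depth call at all is simple but flagged
#' unsupported.
#'
#' @param acghCall a single-element call-set GRanges.
#' @param depthCalls call-set GRanges of read-depth calls.
#' @return List with \code{class} ("simple"/"complex"),
#'   \code{containedCalls} (overlapping depth-call count) and
#'   \code{unsupported} (TRUE when no depth call overlaps).
#' @export
classifyAcghComplexity <- function(acghCall, depthCalls) {
  assertCalls(acghCall); assertCalls(depthCalls)
  if (length(acghCall) != 1L) stop("classify one aCGH call at a time")
  hits <- findOverlaps(acghCall, depthCalls)
  nIn <- length(hits)
  list(class = if (nIn > 1L) "complex" else "simple",
       containedCalls = nIn, unsupported = nIn == 0L)
}
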