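## CNV/SV calls are plain GRanges with a documented set of metadata columns,
## the idiom used by the structural-variant packages this module follows.

CALL_MCOLS <- c("svtype", "copyNumber", "source", "score", "nSupport")

#' Construct a CNV/SV call set
#'
#' Calls are held as a [GenomicRanges::GRanges] with metadata columns
#' \code{svtype} (DEL/DUP/INS/INV/BND), \code{copyNumber} (NA when unknown),
#' \code{source} (\code{depth}, \code{acgh} or \code{pairedend}),
#' \code{score} and \code{nSupport}. Starts/ends are 1-based inclusive in
#' the GRanges (internal arithmetic converts to 0-based half-open where
#' needed; BED output is 0-based half-open).
#'
#' @param chrom,start,end call coordinates (1-based inclusive).
#' @param svtype one of DEL, DUP, INS, INV, BND (recycled).
#' @param copyNumber integer copy number or NA.
#' @param source calling method label.
#' @param score numeric call score.
#' @param nSupport supporting sample/method count.
#' @return GRanges of calls.
#' @export
intervalCalls <- function(chrom, start, end, svtype, copyNumber = NA_integer_,
                          source = "depth", score = NA_real_, nSupport = 1L) {
  n <- length(start)
  svtype <- rep_len(as.character(svtype), n)
  ok <- svtype %in% c("DEL", "DUP", "INS", "INV", "BND")
  if (!all(ok)) stop("unknown svtype: ", svtype[!ok][1L])
  if (any(end < start & svtype != "INS")) stop("start must be <= end for non-INS calls")
  cn <- rep_len(as.integer(copyNumber), n)
  if (any(!is.na(cn) & cn < 0L)) stop("copyNumber must be >= 0")
  gr <- GRanges(rep_len(chrom, n), IRanges(start, end))
  mcols(gr) <- DataFrame(svtype = svtype, copyNumber = cn,
                         source = rep_len(source, n),
                         score = rep_len(as.numeric(score), n),
                         nSupport = rep_len(as.integer(nSupport), n))
  gr
}

assertCalls <- function(x) {
  if (!is(x, "GRanges") || !all(CALL_MCOLS %in% names(mcols(x))))
    stop("expected a call-set GRanges with columns ",
         paste(CALL_MCOLS, collapse = ", "))
  invisible(x)
}

#' Reciprocal overlap between two intervals
#'
#' Fraction by which each interval covers the other; the standard
#' structural-variant matching criterion. Returns the minimum of the two
#' coverage fractions (0 when disjoint).
#'
#' @param start1,end1,start2,end2 1-based inclusive interval coordinates
#'   (vectorized).
#' @return Numeric vector of reciprocal-overlap fractions in [0, 1].
#' @export
reciprocalOverlap <- function(start1, end1, start2, end2) {
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  pmin(ov / (end1 - start1 + 1), ov / (end2 - start2 + 1))
}
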