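## Parental-origin attribution of colony variants ---------------------------

PROVENANCE_CLASSES <- c("both_parents", "a_only", "b_only",
                        "known_nonparental", "private")

#' Classify variant origin against the parental catalogs
#'
#' Assigns each variant key exactly one provenance class by set membership:
#' \code{both_parents} when present in both parental catalogs,
#' \code{a_only}/\code{b_only} when in exactly one, \code{known_nonparental}
#' when absent from both parents but present in the known-variant set, and
#' \code{private} otherwise. The five classes partition any input.
#'
#' @param keys character vector of variant keys (see [makeVariantKey()]).
#' @param catalogs a [ParentalCatalogs].
#' @return Factor with levels both_parents, a_only, b_only,
#'   known_nonparental, private.
#' @export
classifyOrigin <- function(keys, catalogs) {
  stopifnot(is(catalogs, "ParentalCatalogs"))
  parseVariantKey(keys)                      # validates key shape
  inA <- keys %in% catalogA(catalogs)
  inB <- keys %in% catalogB(catalogs)
  inK <- keys %in% knownSet(catalogs)
  cls <- ifelse(inA & inB, "both_parents",
         ifelse(inA, "a_only",
         ifelse(inB, "b_only",
         ifelse(inK, "known_nonparental", "private"))))
  factor(cls, levels = PROVENANCE_CLASSES)
}

#' Summarize provenance across a genotype table
#'
#' Counts and fractions of the five provenance classes for the cohort and
#' for each sample (a sample carries a variant when its genotype is
#' heterozygous or homozygous alternate), plus the pairwise variant-set
#' overlap (Jaccard: shared / union) between samples.
#'
#' @param table a [GenotypeTable].
#' @param catalogs a [ParentalCatalogs].
#' @return List with \code{cohort} (data.frame class/count/fraction),
#'   \code{perSample} (data.frame sample x class counts),
#'   \code{pairwiseOverlap} (samples x samples matrix).
#' @export
summarizeProvenance <- function(table, catalogs) {
  stopifnot(is(table, "GenotypeTable"))
  if (!nrow(table)) stop("empty genotype table")
  keys <- variantKeys(table)
  cls <- classifyOrigin(keys, catalogs)
  gt <- genotypeCodes(table)
  carried <- !is.na(gt) & gt > 0L

  cohortCounts <- tabulate(cls[rowSums(carried) > 0L],
                           nbins = length(PROVENANCE_CLASSES))
  names(cohortCounts) <- PROVENANCE_CLASSES
  tot <- sum(cohortCounts)
  cohort <- data.frame(class = PROVENANCE_CLASSES, count = cohortCounts,
                       fraction = if (tot > 0) cohortCounts / tot else
                         rep(0, length(cohortCounts)),
                       row.names = NULL)

  perSample <- t(vapply(seq_len(ncol(gt)), function(s)
    tabulate(cls[carried[, s]], nbins = length(PROVENANCE_CLASSES)),
    integer(length(PROVENANCE_CLASSES))))
  dimnames(perSample) <- list(colnames(gt), PROVENANCE_CLASSES)

  nS <- ncol(gt)
  ov <- matrix(NA_real_, nS, nS, dimnames = list(colnames(gt), colnames(gt)))
  for (i in seq_len(nS)) for (j in seq_len(nS)) {
    un <- sum(carried[, i] | carried[, j])
    ov[i, j] <- if (un == 0L) NA_real_ else
      sum(carried[, i] & carried[, j]) / un
  }
  list(cohort = cohort, perSample = as.data.frame(perSample),
       pairwiseOverlap = ov)
}

#' Per-window variant density track
#'
#' Tiles each chromosome into fixed windows and counts variants per window
#' (optionally split by a class factor, e.g. provenance). Window counts sum
#' to the number of input variants.
#'
#' @param keys character vector of variant keys.
#' @param chromLengths named vector of chromosome lengths (windows tile
#'   each chromosome fully).
#' @param window window size in bp (default 1 Mb).
#' @param classes optional factor (same length as keys) to split counts by.
#' @return GRanges of windows with a \code{count} column (and one column
#'   per class level when \code{classes} is given).
#' @export
densityTrack <- function(keys, chromLengths, window = 1e6, classes = NULL) {
  if (window < 1) stop("window must be >= 1")
  tdf <- do.call(rbind, lapply(names(chromLengths), function(cn) {
    n <- ceiling(chromLengths[[cn]] / window)
    st <- (seq_len(n) - 1) * window + 1
    data.frame(chrom = cn, start = st,
               end = pmin(st + window - 1, chromLengths[[cn]]))
  }))
  tiles <- GRanges(tdf$chrom, IRanges(tdf$start, tdf$end))
  if (!length(keys)) { mcols(tiles)$count <- 0L; return(tiles) }
  v <- variantKeyRanges(keys)
  hits <- findOverlaps(GRanges(seqnames(v), IRanges(start(v), width = 1L)),
                       tiles)
  mcols(tiles)$count <- tabulate(subjectHits(hits), nbins = length(tiles))
  if (!is.null(classes)) {
    for (lv in levels(classes)) {
      sel <- which(classes[queryHits(hits)] == lv)
      mcols(tiles)[[lv]] <- tabulate(subjectHits(hits)[sel],
                                     nbins = length(tiles))
    }
  }
  tiles
}
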