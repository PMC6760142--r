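## Divergence between two colonies ------------------------------------------

#' Partition homozygous variants between two colonies
#'
#' Counts variants that are homozygous-alternate in at least one sample of
#' a colony, split by parental origin (present in either parental catalog)
#' versus non-parental, and by sharing (both colonies / colony-1 only /
#' colony-2 only). The six cells are disjoint; a variant homozygous in
#' both colonies is counted only in the shared cell.
#'
#' @param table a [GenotypeTable] whose samples carry exactly two colony
#'   labels.
#' @param catalogs a [ParentalCatalogs].
#' @param allSamples when TRUE a variant counts for a colony only if
#'   homozygous-alternate in all of its samples (default: at least one).
#' @return 2x3 integer matrix, rows parental/non_parental, columns
#'   shared/colony-1-only/colony-2-only (column names carry the labels).
#' @export
partitionHomozygous <- function(table, catalogs, allSamples = FALSE) {
  stopifnot(is(table, "GenotypeTable"))
  cols <- colonyLabels(table)
  colonies <- unique(cols)
  if (length(colonies) != 2L)
    stop("genotype table must contain exactly two colonies")
  gt <- genotypeCodes(table)
  keys <- variantKeys(table)
  homIn <- function(colony) {
    sub <- gt[, cols == colony, drop = FALSE]
    hom <- !is.na(sub) & sub == 2L
    if (allSamples) rowSums(hom) == ncol(sub) else rowSums(hom) > 0L
  }
  h1 <- homIn(colonies[1L]); h2 <- homIn(colonies[2L])
  parental <- keys %in% catalogA(catalogs) | keys %in% catalogB(catalogs)
  cells <- function(p) c(
    shared = sum(p & h1 & h2),
    only1 = sum(p & h1 & !h2),
    only2 = sum(p & !h1 & h2))
  out <- rbind(parental = cells(parental), non_parental = cells(!parental))
  colnames(out) <- c("both_colonies", paste0(colonies[1L], "_only"),
                     paste0(colonies[2L], "_only"))
  out
}

#' Pairwise genotype discordance matrix
#'
#' For every sample pair, the fraction of sites with differing genotype
#' codes among sites non-missing in both:
#' discordance = (number of different sites) / (total compared sites).
#' This is a pseudometric on complete data (zero diagonal, symmetric,
#' triangle inequality).
#'
#' @param table a [GenotypeTable].
#' @return List with \code{discordance} (symmetric matrix, values in
#'   [0,1]) and \code{nSites} (compared-site counts per pair). A pair with
#'   zero comparable sites gets NA with a warning.
#' @export
discordanceMatrix <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  gt <- genotypeCodes(table)
  if (ncol(gt) < 2L) stop("need at least 2 samples")
  nS <- ncol(gt)
  D <- matrix(0, nS, nS, dimnames = list(colnames(gt), colnames(gt)))
  N <- matrix(0L, nS, nS, dimnames = dimnames(D))
  anyEmpty <- FALSE
  for (i in seq_len(nS)) {
    N[i, i] <- sum(!is.na(gt[, i]))
    for (j in seq_len(nS)) {
      if (j <= i) next
      ok <- !is.na(gt[, i]) & !is.na(gt[, j])
      n <- sum(ok)
      N[i, j] <- N[j, i] <- n
      if (n == 0L) { D[i, j] <- D[j, i] <- NA_real_; anyEmpty <- TRUE; next }
      d <- sum(gt[ok, i] != gt[ok, j]) / n
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyEmpty) warning("some sample pairs share no comparable sites")
  list(discordance = D, nSites = N)
}

#' Detect runs of homozygosity
#'
#' Sliding-window rule over one sample's genotypes ordered by position:
#' every window of \code{windowSites} consecutive called sites containing
#' at most \code{maxHetPerWindow} heterozygous calls is accepted; accepted
#' overlapping windows are merged and the merged segments are filtered by
#' \code{minLength}. Segments end at the first/last homozygous site of the
#' merged run.
#'
#' @param positions sorted 1-based positions of the sample's called sites
#'   on one chromosome.
#' @param genotypes genotype codes (0/1/2) matching \code{positions};
#'   missing codes must be removed beforehand.
#' @param chrom chromosome name for the output.
#' @param windowSites sites per window.
#' @param maxHetPerWindow heterozygote allowance per window.
#' @param minLength minimum segment length in bp.
#' @return GRanges of segments with \code{nSites} and \code{hetCount}.
#' @export
detectRoh <- function(positions, genotypes, chrom = "chr1",
                      windowSites = 50L, maxHetPerWindow = 1L,
                      minLength = 1e6) {
  stopifnot(length(positions) == length(genotypes))
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(positions)
  if (n < windowSites) return(GRanges())
  het <- as.integer(genotypes == 1L)
  cs <- cumsum(c(0L, het))
  winHet <- cs[(windowSites + 1L):(n + 1L)] - cs[1L:(n - windowSites + 1L)]
  pass <- winHet <= maxHetPerWindow         # window i covers sites i..i+w-1
  if (!any(pass)) return(GRanges())
  idx <- which(pass)
  brk <- c(TRUE, diff(idx) > 1L)
  grp <- cumsum(brk)
  segs <- lapply(split(idx, grp), function(ii) {
    lo <- min(ii); hi <- max(ii) + windowSites - 1L
    sites <- lo:hi
    homSites <- sites[het[sites] == 0L]     # trim to homozygous ends
    if (!length(homSites)) return(NULL)
    c(start = positions[min(homSites)], end = positions[max(homSites)],
      nSites = length(sites), hetCount = sum(het[sites]))
  })
  segs <- do.call(rbind, Filter(Negate(is.null), segs))
  if (is.null(segs)) return(GRanges())
  keep <- (segs[, "end"] - segs[, "start"] + 1L) >= minLength
  segs <- segs[keep, , drop = FALSE]
  if (!nrow(segs)) return(GRanges())
  GRanges(chrom, IRanges(segs[, "start"], segs[, "end"]),
          nSites = as.integer(segs[, "nSites"]),
          hetCount = as.integer(segs[, "hetCount"]))
}
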