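## Genic-region classification of variants ----------------------------------

REGION_CLASSES <- c("exon", "utr5", "utr3", "splice_site", "intron",
                    "upstream", "downstream", "intergenic")

#' Build a gene-model set
#'
#' A light container for transcript models: per-transcript span and strand,
#' exon intervals, and optional UTR intervals. Exons must lie within their
#' transcript span.
#'
#' @param transcripts data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (1-based inclusive).
#' @param exons data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param utr5,utr3 optional data.frames in the same shape as \code{exons}.
#' @return List of GRanges of class \code{GeneModelSet}.
#' @export
geneModels <- function(transcripts, exons, utr5 = NULL, utr3 = NULL) {
  stopifnot(all(transcripts$strand %in% c("+", "-")))
  asGr <- function(df) if (is.null(df) || !nrow(df)) GRanges() else
    GRanges(df$chrom, IRanges(df$start, df$end), gene = df$gene)
  tx <- GRanges(transcripts$chrom,
                IRanges(transcripts$start, transcripts$end),
                strand = transcripts$strand, gene = transcripts$gene)
  ex <- asGr(exons)
  hits <- findOverlaps(ex, tx, type = "within")
  ok <- mcols(ex)$gene[queryHits(hits)] == mcols(tx)$gene[subjectHits(hits)]
  if (length(ex) && !all(seq_along(ex) %in% queryHits(hits)[ok]))
    stop("every exon must lie within its transcript span")
  structure(list(transcripts = tx, exons = ex,
                 utr5 = asGr(utr5), utr3 = asGr(utr3)),
            class = "GeneModelSet")
}

#' Read gene models from a BED12 file
#'
#' Interprets blocks as exons; thickStart/thickEnd as the coding span, from
#' which UTR intervals are derived strand-aware.
#'
#' @param path BED12 file path (0-based half-open, as BED requires).
#' @return A \code{GeneModelSet}.
#' @export
readBed12 <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 BED columns")
  names(df)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                       "thickStart", "thickEnd", "rgb", "blockCount",
                       "blockSizes", "blockStarts")
  tx <- data.frame(gene = df$name, chrom = df$chrom, start = df$start + 1L,
                   end = df$end, strand = df$strand)
  exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    sizes <- as.integer(strsplit(df$blockSizes[i], ",")[[1L]])
    offs <- as.integer(strsplit(df$blockStarts[i], ",")[[1L]])
    data.frame(gene = df$name[i], chrom = df$chrom[i],
               start = df$start[i] + offs + 1L,
               end = df$start[i] + offs + sizes)
  }))
  utr5 <- list(); utr3 <- list()
  for (i in seq_len(nrow(df))) {
    cdsS <- df$thickStart[i] + 1L; cdsE <- df$thickEnd[i]
    if (cdsE < cdsS) next                    # non-coding: no UTR annotation
    left <- data.frame(gene = df$name[i], chrom = df$chrom[i],
                       start = df$start[i] + 1L, end = cdsS - 1L)
    right <- data.frame(gene = df$name[i], chrom = df$chrom[i],
                        start = cdsE + 1L, end = df$end[i])
    if (left$end >= left$start)
      if (df$strand[i] == "+") utr5[[length(utr5) + 1L]] <- left
      else utr3[[length(utr3) + 1L]] <- left
    if (right$end >= right$start)
      if (df$strand[i] == "+") utr3[[length(utr3) + 1L]] <- right
      else utr5[[length(utr5) + 1L]] <- right
  }
  geneModels(tx, exons,
             utr5 = if (length(utr5)) do.call(rbind, utr5) else NULL,
             utr3 = if (length(utr3)) do.call(rbind, utr3) else NULL)
}

#' Classify variants by genic region
#'
#' Assigns each variant one region class with deterministic precedence:
#' coding exon > UTR > splice site > intron > upstream/downstream >
#' intergenic. \code{exon} means exonic sequence outside the annotated
#' UTRs (when UTRs are provided); \code{splice_site} is within 2 bp of an
#' exon-intron boundary on the intronic side; \code{upstream}/
#' \code{downstream} are strand-aware within \code{flank} bp of the
#' transcript; a variant within \code{flank} of two genes on opposite
#' sides goes to the nearer one (tie: upstream). Unknown chromosomes fall
#' to \code{intergenic} with a warning.
#'
#' @param keys character vector of variant keys.
#' @param models a [geneModels()] set.
#' @param flank upstream/downstream window in bp.
#' @param spliceWindow bp of intron adjacent to each exon boundary called
#'   splice site.
#' @return Factor with levels exon, utr5, utr3, splice_site, intron,
#'   upstream, downstream, intergenic.
#' @export
classifyRegion <- function(keys, models, flank = 5000L, spliceWindow = 2L) {
  stopifnot(inherits(models, "GeneModelSet"))
  f <- parseVariantKey(keys)
  pos <- GRanges(f$chrom, IRanges(f$pos, width = 1L))
  known <- as.character(seqnames(pos)) %in%
    unique(as.character(seqnames(models$transcripts)))
  if (!all(known))
    warning(sum(!known), " variant(s) on chromosomes absent from the gene models")

  res <- rep("intergenic", length(keys))
  overlapsAny <- function(gr) {
    if (!length(gr)) return(logical(length(keys)))
    ## unknown chromosomes are legitimate here (classified intergenic), so
    ## the disjoint-seqlevels notice is expected
    countOv <- suppressWarnings(
      GenomicRanges::countOverlaps(pos, gr, ignore.strand = TRUE))
    countOv > 0L
  }

  tx <- models$transcripts
  inTx <- overlapsAny(tx)
  inEx <- overlapsAny(models$exons)
  inU5 <- overlapsAny(models$utr5)
  inU3 <- overlapsAny(models$utr3)

  ## splice sites: within spliceWindow bp of an exon edge, intronic side
  spl <- logical(length(keys))
  if (length(models$exons) && spliceWindow > 0L) {
    ex <- models$exons
    edges <- GRanges(rep(as.character(seqnames(ex)), 2L),
                     IRanges(c(start(ex) - spliceWindow, end(ex) + 1L),
                             c(start(ex) - 1L, end(ex) + spliceWindow)))
    spl <- overlapsAny(edges) & inTx & !inEx
  }

  ## strand-aware flanks, nearest gene wins, tie -> upstream
  upDist <- downDist <- rep(Inf, length(keys))
  if (length(tx) && flank > 0L) {
    plus <- as.character(strand(tx)) == "+"
    chr <- as.character(seqnames(tx))
    upReg <- GRanges(c(chr[plus], chr[!plus]),
                     IRanges(c(pmax(1L, start(tx)[plus] - flank),
                               end(tx)[!plus] + 1L),
                             c(start(tx)[plus] - 1L,
                               end(tx)[!plus] + flank)))
    downReg <- GRanges(c(chr[plus], chr[!plus]),
                       IRanges(c(end(tx)[plus] + 1L,
                                 pmax(1L, start(tx)[!plus] - flank)),
                               c(end(tx)[plus] + flank,
                                 start(tx)[!plus] - 1L)))
    txStarts <- c(start(tx)[plus] , end(tx)[!plus])   # 5' anchor per region
    txEnds <- c(end(tx)[plus], start(tx)[!plus])      # 3' anchor per region
    hu <- suppressWarnings(findOverlaps(pos, upReg))
    for (h in seq_along(hu)) {
      q <- queryHits(hu)[h]; s <- subjectHits(hu)[h]
      dist <- abs(f$pos[q] - txStarts[s])
      if (dist < upDist[q]) upDist[q] <- dist
    }
    hd <- suppressWarnings(findOverlaps(pos, downReg))
    for (h in seq_along(hd)) {
      q <- queryHits(hd)[h]; s <- subjectHits(hd)[h]
      dist <- abs(f$pos[q] - txEnds[s])
      if (dist < downDist[q]) downDist[q] <- dist
    }
  }

  res[is.finite(downDist) & downDist < upDist] <- "downstream"
  res[is.finite(upDist) & upDist <= downDist] <- "upstream"
  res[inTx] <- "intron"
  res[spl] <- "splice_site"
  res[inU3] <- "utr3"
  res[inU5] <- "utr5"
  res[inEx & !inU5 & !inU3] <- "exon"
  res[!known] <- "intergenic"
  factor(res, levels = REGION_CLASSES)
}
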