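## Readers/writers for the package's text formats ---------------------------
## Every writer records the tool version and (when given) the RNG seed and
## parameter string in its header; every writer round-trips through the
## matching reader.

toolHeader <- function(prefix = "##", seed = NULL, params = NULL) {
  h <- sprintf("%ssource=mutacolony %s", prefix,
               as.character(packageVersion("mutacolony")))
  if (!is.null(seed)) h <- c(h, sprintf("%sseed=%d", prefix, as.integer(seed)))
  if (!is.null(params))
    h <- c(h, sprintf("%sparams=%s", prefix,
                      paste(names(params), unlist(params), sep = "=",
                            collapse = ";")))
  h
}

gtToString <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a genotype table as minimal multi-sample VCF
#'
#' Emits VCF v4.2 with CHROM/POS/REF/ALT and a GT-only FORMAT column, one
#' record per (already decomposed) variant key, sorted by chromosome,
#' position and alternate allele. Output is deterministic, so identical
#' tables give byte-identical files.
#'
#' @param table a [GenotypeTable].
#' @param path output path.
#' @param seed,params optional provenance recorded in the header.
#' @return Invisibly, the path.
#' @export
writeVcfMinimal <- function(table, path, seed = NULL, params = NULL) {
  stopifnot(is(table, "GenotypeTable"))
  rd <- rowData(table)
  o <- order(rd$chrom, rd$pos, rd$alt)
  gt <- genotypeCodes(table)[o, , drop = FALSE]
  rd <- rd[o, ]
  lines <- c("##fileformat=VCFv4.2",
             toolHeader(seed = seed, params = params),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(table)), collapse = "\t"))
  if (nrow(rd)) {
    gts <- apply(gt, 1L, function(r) paste(gtToString(r), collapse = "\t"))
    lines <- c(lines, paste(rd$chrom, rd$pos, ".", rd$ref, rd$alt, ".",
                            "PASS", ".", "GT", gts, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal multi-sample VCF into a genotype table
#'
#' Honors CHROM, POS, REF, ALT and the GT genotype field only (the
#' analyses use genotype identity, nothing else). Multi-allelic records are
#' decomposed into one row per alternate allele, counting each sample's
#' copies of that allele (other alternates count as reference for the
#' decomposed row); missing genotypes are preserved.
#'
#' @param path VCF path.
#' @param colony colony label per sample (recycled; default "colony1").
#' @return A [GenotypeTable].
#' @export
readVcfMinimal <- function(path, colony = "colony1") {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  gtStr <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtStr)) stop("VCF has no GT genotypes")
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  chroms <- as.character(seqnames(rr))
  poss <- start(rr)

  keys <- character(); rows <- list()
  nAlt <- lengths(altList)
  for (r in seq_along(nAlt)) {
    alleles <- strsplit(gtStr[r, ], "[/|]")
    for (a in seq_len(nAlt[r])) {
      code <- vapply(alleles, function(al) {
        if (any(al == ".")) return(NA_integer_)
        sum(as.integer(al) == a)
      }, integer(1))
      keys <- c(keys, makeVariantKey(chroms[r], poss[r], refs[r],
                                     as.character(altList[[r]][a])))
      rows[[length(rows) + 1L]] <- code
    }
  }
  gt <- do.call(rbind, rows)
  colnames(gt) <- colnames(gtStr)
  GenotypeTable(gt, keys, rep_len(colony, ncol(gt)))
}

#' Write a call set as extended BED
#'
#' Standard 0-based half-open BED coordinates plus the call columns
#' (svtype, copyNumber, source, score, nSupport). Round-trips losslessly
#' through [readCallsBed()].
#'
#' @param calls call-set GRanges (see [intervalCalls()]).
#' @param path output path.
#' @param seed,params optional provenance recorded in the header.
#' @return Invisibly, the path.
#' @export
writeCallsBed <- function(calls, path, seed = NULL, params = NULL) {
  assertCalls(calls)
  lines <- c(toolHeader(prefix = "#", seed = seed, params = params),
             paste("#chrom", "start", "end", "svtype", "copyNumber",
                   "source", "score", "nSupport", sep = "\t"))
  if (length(calls)) {
    m <- mcols(calls)
    lines <- c(lines, paste(as.character(seqnames(calls)), start(calls) - 1L,
                            end(calls), m$svtype, m$copyNumber, m$source,
                            m$score, m$nSupport, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a call set written by [writeCallsBed()]
#'
#' @param path input path.
#' @return Call-set GRanges.
#' @export
readCallsBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(emptyCalls())
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "svtype",
                                 "copyNumber", "source", "score", "nSupport"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "numeric", "integer"),
                   na.strings = "NA")
  intervalCalls(df$chrom, df$start + 1L, df$end, df$svtype, df$copyNumber,
                df$source, df$score, df$nSupport)
}

#' @rdname writeCallsBed
#' @param probes a [ProbeSet].
#' @export
writeProbesTsv <- function(probes, path, seed = NULL, params = NULL) {
  stopifnot(is(probes, "ProbeSet"))
  lines <- c(toolHeader(prefix = "#", seed = seed, params = params),
             paste("#chrom", "pos", "log2ratio", sep = "\t"),
             paste(probes@chrom, probePositions(probes),
                   sprintf("%.8g", probeLog2Ratios(probes)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname readCallsBed
#' @export
readProbesTsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "pos", "log2ratio"),
                   colClasses = c("character", "numeric", "numeric"))
  ProbeSet(df$chrom[1L], df$pos, df$log2ratio)
}

#' Write/read a coverage track as bedGraph-style TSV
#'
#' @param track a [CoverageTrack].
#' @param path file path.
#' @param seed,params optional provenance recorded in the header.
#' @return Invisibly the path (writer); a [CoverageTrack] (reader).
#' @export
writeCoverageBedgraph <- function(track, path, seed = NULL, params = NULL) {
  stopifnot(is(track, "CoverageTrack"))
  n <- length(binDepths(track))
  bs <- binSize(track)
  lines <- c(toolHeader(prefix = "#", seed = seed, params = params),
             paste(track@chrom, (seq_len(n) - 1L) * bs, seq_len(n) * bs,
                   binDepths(track), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCoverageBedgraph
#' @export
readCoverageBedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "depth"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  CoverageTrack(df$chrom[1L], df$end[1L] - df$start[1L], df$depth)
}

#' Serialize a junction model to JSON (and back)
#'
#' @param model a [JunctionModel].
#' @param path file path.
#' @return Invisibly the path (writer); a [JunctionModel] (reader).
#' @export
writeJunctionJson <- function(model, path) {
  stopifnot(is(model, "JunctionModel"))
  x <- list(found = model@found, blocks = model@blocks,
            deletionSpan = model@deletionSpan,
            inversionSpan = model@inversionSpan,
            insertedBases = model@insertedBases,
            microhomology = model@microhomology,
            monomerTruncations = model@monomerTruncations,
            tool = sprintf("mutacolony %s",
                           as.character(packageVersion("mutacolony"))))
  write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
             pretty = TRUE)
  invisible(path)
}

#' @rdname writeJunctionJson
#' @export
readJunctionJson <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  JunctionModel(found = x$found,
                blocks = as.data.frame(x$blocks),
                deletionSpan = unlist(x$deletionSpan) %||% numeric(),
                inversionSpan = unlist(x$inversionSpan) %||% numeric(),
                insertedBases = x$insertedBases %||% "",
                microhomology = x$microhomology %||% list(),
                monomerTruncations = x$monomerTruncations %||% list())
}
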