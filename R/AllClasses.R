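## Central S4 containers ----------------------------------------------------

#' Parental strain variant catalogs
#'
#' Holds the two parental-strain variant catalogs (for the MutaMouse system,
#' BALB/cJ and DBA/2J) plus a known-variant set standing in for a dbSNP-style
#' catalog, over a synthetic or real genome. Catalogs may overlap (shared
#' ancestral variants); the known set must contain every parental variant.
#'
#' @slot catalogA,catalogB character vectors of variant keys
#'   (see [makeVariantKey()]) for the two parental strains.
#' @slot knownSet character vector of variant keys; superset of both catalogs.
#' @slot genomeLength total genome length in bp.
#' @slot nChromosomes number of (equal-sized) chromosomes.
#' @slot chromLengths named numeric vector of per-chromosome lengths.
#' @export
setClass("ParentalCatalogs",
  representation(catalogA = "character", catalogB = "character",
                 knownSet = "character", genomeLength = "numeric",
                 nChromosomes = "integer", chromLengths = "numeric"))

setValidity("ParentalCatalogs", function(object) {
  msg <- character()
  un <- union(object@catalogA, object@catalogB)
  if (!all(un %in% object@knownSet))
    msg <- c(msg, "knownSet must contain the union of both parental catalogs")
  if (length(object@chromLengths) &&
      abs(sum(object@chromLengths) - object@genomeLength) > 0.5)
    msg <- c(msg, "chromLengths must sum to genomeLength")
  all_keys <- unique(c(un, object@knownSet))
  if (length(all_keys)) {
    f <- parseVariantKey(all_keys)
    cl <- object@chromLengths[f$chrom]
    if (anyNA(cl) || any(f$pos < 1) || any(f$pos > cl))
      msg <- c(msg, "all catalog positions must lie within [1, chromosome length]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ParentalCatalogs constructor.
#' @param catalogA,catalogB,knownSet,genomeLength,nChromosomes see slots.
#' @export
ParentalCatalogs <- function(catalogA, catalogB, knownSet,
                             genomeLength, nChromosomes = 1L) {
  nChromosomes <- as.integer(nChromosomes)
  cl <- rep(genomeLength / nChromosomes, nChromosomes)
  names(cl) <- paste0("chr", seq_len(nChromosomes))
  new("ParentalCatalogs", catalogA = unique(catalogA),
      catalogB = unique(catalogB),
      knownSet = unique(knownSet), genomeLength = genomeLength,
      nChromosomes = nChromosomes, chromLengths = cl)
}

#' @describeIn ParentalCatalogs variant keys of parental strain A.
#' @param x a \code{ParentalCatalogs} object.
#' @export
catalogA <- function(x) x@catalogA
#' @describeIn ParentalCatalogs variant keys of parental strain B.
#' @export
catalogB <- function(x) x@catalogB
#' @describeIn ParentalCatalogs the known-variant (dbSNP stand-in) key set.
#' @export
knownSet <- function(x) x@knownSet
#' @describeIn ParentalCatalogs named per-chromosome lengths.
#' @export
chromLengths <- function(x) x@chromLengths

setMethod("show", "ParentalCatalogs", function(object) {
  cat("ParentalCatalogs:",
      length(object@catalogA), "strain-A,",
      length(object@catalogB), "strain-B,",
      length(object@knownSet), "known keys;",
      length(intersect(object@catalogA, object@catalogB)), "shared;",
      "genome", object@genomeLength, "bp /",
      object@nChromosomes, "chromosome(s)\n")
})

#' Samples-by-variants genotype table
#'
#' A \linkS4class{SummarizedExperiment} holding one diploid genotype code per
#' variant (row) and sample (column) in the \code{"GT"} assay, with codes
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate and
#' \code{NA} = missing. \code{rowData} carries \code{chrom}, \code{pos},
#' \code{ref}, \code{alt} (and, for simulated tables, \code{truthClass});
#' \code{colData} carries the \code{colony} label of each animal.
#'
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!"GT" %in% names(assays(object)))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- assay(object, "GT")
    if (!all(gt %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  if (!"colony" %in% names(colData(object)))
    msg <- c(msg, "colData column 'colony' is required")
  else if (any(!nzchar(colData(object)$colony)))
    msg <- c(msg, "colony labels must be nonempty")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(rowData(object))))
    msg <- c(msg, "rowData must contain chrom, pos, ref, alt")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeTable constructor.
#' @param gt integer matrix (variants x samples) of genotype codes.
#' @param variants character vector of variant keys (one per row of \code{gt}).
#' @param colony character vector of colony labels (one per column).
#' @param truthClass optional per-variant truth provenance class (simulated
#'   tables only).
#' @export
GenotypeTable <- function(gt, variants, colony, truthClass = NULL) {
  stopifnot(nrow(gt) == length(variants), ncol(gt) == length(colony))
  rd <- parseVariantKey(variants)
  rd$key <- variants
  if (!is.null(truthClass)) rd$truthClass <- truthClass
  if (is.null(colnames(gt))) colnames(gt) <- paste0("animal", seq_len(ncol(gt)))
  se <- SummarizedExperiment(
    assays = list(GT = gt), rowData = rd,
    colData = DataFrame(colony = colony, row.names = colnames(gt)))
  rownames(se) <- variants
  new("GenotypeTable", se)
}

#' @describeIn GenotypeTable genotype code matrix (variants x samples).
#' @param x a \code{GenotypeTable}.
#' @export
genotypeCodes <- function(x) assay(x, "GT")
#' @describeIn GenotypeTable variant keys (row identities).
#' @export
variantKeys <- function(x) rowData(x)$key
#' @describeIn GenotypeTable per-sample colony labels.
#' @export
colonyLabels <- function(x) setNames(colData(x)$colony, colnames(x))
#' @describeIn GenotypeTable per-variant simulated truth classes (or NULL).
#' @export
truthClasses <- function(x) rowData(x)$truthClass

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object), "variants x", ncol(object), "samples;",
      "colonies:", paste(unique(colData(object)$colony), collapse = ", "), "\n")
})

#' Binned read-depth track for one chromosome
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot depths per-bin mean read depth, ordered along the chromosome;
#'   bin \code{i} covers 0-based half-open \code{[(i-1)*binSize, i*binSize)}.
#' @export
setClass("CoverageTrack",
  representation(chrom = "character", binSize = "integer", depths = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (object@binSize < 1L) return("binSize must be >= 1")
  if (any(object@depths < 0)) return("depths must be non-negative")
  TRUE
})

#' @describeIn CoverageTrack constructor.
#' @param chrom,binSize,depths see slots.
#' @export
CoverageTrack <- function(chrom, binSize, depths)
  new("CoverageTrack", chrom = chrom, binSize = as.integer(binSize),
      depths = as.numeric(depths))

#' @describeIn CoverageTrack per-bin depths.
#' @param x a \code{CoverageTrack}.
#' @export
binDepths <- function(x) x@depths
#' @describeIn CoverageTrack bin width in bp.
#' @export
binSize <- function(x) x@binSize

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", object@chrom, "-", length(object@depths), "bins x",
      object@binSize, "bp; mean depth",
      round(mean(object@depths), 2), "\n")
})

#' aCGH probe set for one chromosome
#'
#' @slot chrom chromosome name.
#' @slot positions strictly increasing 1-based probe positions.
#' @slot log2Ratios per-probe log2(sample/reference) copy ratios.
#' @export
setClass("ProbeSet",
  representation(chrom = "character", positions = "numeric",
                 log2Ratios = "numeric"))

setValidity("ProbeSet", function(object) {
  if (length(object@positions) != length(object@log2Ratios))
    return("positions and log2Ratios must have equal length")
  if (is.unsorted(object@positions, strictly = TRUE))
    return("probe positions must be strictly increasing")
  TRUE
})

#' @describeIn ProbeSet constructor.
#' @param chrom,positions,log2Ratios see slots.
#' @export
ProbeSet <- function(chrom, positions, log2Ratios)
  new("ProbeSet", chrom = chrom, positions = as.numeric(positions),
      log2Ratios = as.numeric(log2Ratios))

#' @describeIn ProbeSet probe positions.
#' @param x a \code{ProbeSet}.
#' @export
probePositions <- function(x) x@positions
#' @describeIn ProbeSet probe log2 ratios.
#' @export
probeLog2Ratios <- function(x) x@log2Ratios

setMethod("show", "ProbeSet", function(object) {
  cat("ProbeSet:", object@chrom, "-", length(object@positions), "probes;",
      "log2 ratio sd", round(stats::sd(object@log2Ratios), 3), "\n")
})

#' Pooled pileup over one transgene monomer
#'
#' Per-position read support over a single monomer of a head-to-tail tandem
#' transgene array of \code{copyNumber} copies, with all copies collapsed
#' onto monomer coordinates. Non-reference support is stored sparsely.
#'
#' @slot monomerLength monomer length in bp.
#' @slot copyNumber array copy number (about 29 for the MutaMouse array).
#' @slot depth integer vector of total depth per monomer position.
#' @slot altCounts data.frame with columns \code{pos}, \code{ref}, \code{alt},
#'   \code{count}: reads supporting each non-reference allele.
#' @export
setClass("TransgenePileup",
  representation(monomerLength = "integer", copyNumber = "integer",
                 depth = "integer", altCounts = "data.frame"))

setValidity("TransgenePileup", function(object) {
  msg <- character()
  if (object@copyNumber < 1L) msg <- c(msg, "copyNumber must be >= 1")
  if (length(object@depth) != object@monomerLength)
    msg <- c(msg, "depth must have one entry per monomer position")
  ac <- object@altCounts
  if (nrow(ac)) {
    if (any(ac$pos < 1L | ac$pos > object@monomerLength))
      msg <- c(msg, "altCounts positions must lie within the monomer")
    tot <- tapply(ac$count, ac$pos, sum)
    if (any(tot > object@depth[as.integer(names(tot))]))
      msg <- c(msg, "allele counts cannot exceed depth at a position")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TransgenePileup constructor.
#' @param monomerLength,copyNumber,depth,altCounts see slots.
#' @export
TransgenePileup <- function(monomerLength, copyNumber, depth, altCounts) {
  new("TransgenePileup", monomerLength = as.integer(monomerLength),
      copyNumber = as.integer(copyNumber), depth = as.integer(depth),
      altCounts = altCounts)
}

#' @describeIn TransgenePileup array copy number.
#' @param x a \code{TransgenePileup}.
#' @export
copyNumber <- function(x) x@copyNumber
#' @describeIn TransgenePileup sparse non-reference allele counts.
#' @export
altCounts <- function(x) x@altCounts
#' @describeIn TransgenePileup per-position total depth.
#' @export
pileupDepth <- function(x) x@depth

setMethod("show", "TransgenePileup", function(object) {
  cat("TransgenePileup:", object@monomerLength, "bp monomer x",
      object@copyNumber, "copies;",
      length(unique(object@altCounts$pos)), "non-reference positions;",
      "mean depth", round(mean(object@depth), 1), "\n")
})

#' Integration-junction model
#'
#' Ordered, labeled blocks describing a transgene integration locus: the
#' retained host flanks, an inverted host segment, inserted bases, and the
#' (truncated) transgene monomers at each breakpoint, together with the
#' deletion span, inversion span, per-junction microhomology and
#' monomer-truncation annotations. All coordinates are 1-based inclusive
#' host-genome coordinates.
#'
#' @slot found FALSE when no chimeric evidence was available.
#' @slot blocks data.frame with columns \code{label} (host/host_inverted/
#'   insert/transgene), \code{refStart}, \code{refEnd}, \code{strand},
#'   \code{nReads}, ordered along the reconstructed locus.
#' @slot deletionSpan numeric c(start, end): first deleted base and first
#'   retained base after the deletion (printed-coordinate convention; the
#'   deleted length is \code{end - start}).
#' @slot inversionSpan numeric c(start, end), 1-based inclusive source span
#'   of the inverted segment (length \code{end - start + 1}).
#' @slot insertedBases consensus inserted nucleotides at the upstream
#'   junction ("" when none).
#' @slot microhomology named list per junction: list(length=, sequence=).
#' @slot monomerTruncations named list per breakpoint-adjacent monomer:
#'   list(range=c(from, to), oriFunctional=, cohesiveEndPresent=).
#' @export
setClass("JunctionModel",
  representation(found = "logical", blocks = "data.frame",
                 deletionSpan = "numeric", inversionSpan = "numeric",
                 insertedBases = "character", microhomology = "list",
                 monomerTruncations = "list"))

setValidity("JunctionModel", function(object) {
  if (!object@found) return(TRUE)
  msg <- character()
  if (length(object@deletionSpan) == 2L && !anyNA(object@deletionSpan) &&
      diff(object@deletionSpan) < 0)
    msg <- c(msg, "deletionSpan must be increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn JunctionModel constructor.
#' @param found,blocks,deletionSpan,inversionSpan,insertedBases see slots.
#' @param microhomology,monomerTruncations see slots.
#' @export
JunctionModel <- function(found = TRUE, blocks = data.frame(),
                          deletionSpan = numeric(), inversionSpan = numeric(),
                          insertedBases = "", microhomology = list(),
                          monomerTruncations = list()) {
  new("JunctionModel", found = found, blocks = blocks,
      deletionSpan = as.numeric(deletionSpan),
      inversionSpan = as.numeric(inversionSpan),
      insertedBases = insertedBases, microhomology = microhomology,
      monomerTruncations = monomerTruncations)
}

#' @describeIn JunctionModel TRUE when chimeric evidence supported a model.
#' @param x a \code{JunctionModel}.
#' @export
junctionFound <- function(x) x@found
#' @describeIn JunctionModel deletion span c(start, end).
#' @export
deletionSpan <- function(x) x@deletionSpan
#' @describeIn JunctionModel inversion span c(start, end).
#' @export
inversionSpan <- function(x) x@inversionSpan
#' @describeIn JunctionModel inserted bases at the upstream junction.
#' @export
insertedBases <- function(x) x@insertedBases
#' @describeIn JunctionModel ordered locus blocks.
#' @export
junctionBlocks <- function(x) x@blocks
#' @describeIn JunctionModel per-junction microhomology annotations.
#' @export
junctionMicrohomology <- function(x) x@microhomology

setMethod("show", "JunctionModel", function(object) {
  if (!object@found) { cat("JunctionModel: no junction found\n"); return(invisible(NULL)) }
  cat("JunctionModel:\n")
  if (length(object@deletionSpan) == 2L)
    cat(sprintf("  deletion  %s-%s (%d bp, difference convention)\n",
                format(object@deletionSpan[1], big.mark = ","),
                format(object@deletionSpan[2], big.mark = ","),
                as.integer(diff(object@deletionSpan))))
  if (length(object@inversionSpan) == 2L)
    cat(sprintf("  inversion %s-%s (%d bp, inclusive)\n",
                format(object@inversionSpan[1], big.mark = ","),
                format(object@inversionSpan[2], big.mark = ","),
                as.integer(diff(object@inversionSpan)) + 1L))
  cat(sprintf("  inserted bases: %s (%d nt)\n",
              ifelse(nzchar(object@insertedBases), object@insertedBases, "-"),
              nchar(object@insertedBases)))
  for (nm in names(object@microhomology))
    cat(sprintf("  microhomology %s: %d bp %s\n", nm,
                object@microhomology[[nm]]$length,
                object@microhomology[[nm]]$sequence))
  cat(" ", nrow(object@blocks), "locus blocks\n")
})
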