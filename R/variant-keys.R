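## Variant identity ---------------------------------------------------------
##
## All set algebra in the package runs over normalized variant keys:
## "chrom:pos:ref:alt" with pos 1-based. Multi-allelic records decompose into
## one key per alternate allele before keys are formed.

#' Build normalized variant keys
#'
#' A variant key is the string \code{"chrom:pos:ref:alt"} with a 1-based
#' position and left-normalized alleles; it is the identity used for all
#' variant set algebra (parental attribution, colony partitioning, overlap
#' fractions). Indel alleles are left-normalized by stripping the common
#' suffix and then the common prefix (keeping one anchor base), so
#' representation differences between callers do not break exact matching.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return Character vector of keys.
#' @examples
#' makeVariantKey("chr1", 100, "A", "G")
#' makeVariantKey("chr1", 100, "ATT", "AT")  # normalizes to chr1:100:AT:A
#' @export
makeVariantKey <- function(chrom, pos, ref, alt) {
  if (any(pos < 1)) stop("positions must be >= 1")
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  n <- normalizeAlleles(pos, ref, alt)
  paste(chrom, n$pos, n$ref, n$alt, sep = ":")
}

## Strip shared suffix then shared prefix (keep >=1 base each side); adjust
## pos by the number of prefix bases removed. Vectorized.
normalizeAlleles <- function(pos, ref, alt) {
  needs <- nchar(ref) > 1L | nchar(alt) > 1L
  if (any(needs)) {
    for (i in which(needs)) {
      r <- strsplit(ref[i], "")[[1]]
      a <- strsplit(alt[i], "")[[1]]
      while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]; a <- a[-length(a)]
      }
      off <- 0L
      while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
        r <- r[-1L]; a <- a[-1L]; off <- off + 1L
      }
      ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
      pos[i] <- pos[i] + off
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Parse variant keys back into their fields
#'
#' @param keys character vector of keys produced by [makeVariantKey()].
#' @return A [S4Vectors::DataFrame] with columns \code{chrom}, \code{pos}
#'   (integer, 1-based), \code{ref}, \code{alt}.
#' @export
parseVariantKey <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed variant key: ", keys[which(bad)[1L]])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos) && length(keys)) stop("malformed variant key: non-numeric position")
  DataFrame(chrom = m[, 1L], pos = pos, ref = m[, 3L], alt = m[, 4L])
}

## GRanges view of a key set (width = nchar(ref)), for window/overlap ops.
variantKeyRanges <- function(keys) {
  f <- parseVariantKey(keys)
  GRanges(f$chrom, IRanges(f$pos, width = nchar(f$ref)), key = keys)
}

#' Event length under an explicit coordinate convention
#'
#' Published breakpoint coordinates are 1-based inclusive, but event lengths
#' are quoted under two different conventions in practice: plain difference
#' (\code{end - start}) and inclusive span (\code{end - start + 1}).
#' This helper makes the convention explicit instead of guessing one rule.
#'
#' @param start,end 1-based coordinates, \code{end >= start}.
#' @param convention \code{"difference"} or \code{"inclusive"}.
#' @return Numeric length in bp.
#' @examples
#' intervalLength(37971249, 38436675, "difference")  # 465426
#' intervalLength(38436306, 38436675, "inclusive")   # 370
#' @export
intervalLength <- function(start, end, convention = c("difference", "inclusive")) {
  convention <- match.arg(convention)
  if (any(end < start)) stop("end must be >= start")
  if (convention == "difference") end - start else end - start + 1
}
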