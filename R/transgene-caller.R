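## Constitutional vs copy-private variant calling over a tandem array -------

#' Call constitutional and partial variants on a transgene-array pileup
#'
#' Classifies each non-reference position of a pooled tandem-array pileup.
#' A position whose combined alternate fraction is at least
#' \code{constitutionalLower} is \emph{constitutional} (present on every
#' copy; the 0.9 default rather than exactly 1 tolerates sequencing error).
#' A position whose fraction is below that but at least
#' \code{1/(copyNumber + 2)} — the single-copy detection floor, the same
#' margin as calling a 29-copy array at ploidy 31 — and significantly above
#' the sequencing error rate by a one-sided binomial test at \code{alpha}
#' is \emph{partial} (present on a subset of copies). Alleles at one
#' position are aggregated, so a multi-allelic constitutional site counts
#' once.
#'
#' @param pileup a [TransgenePileup].
#' @param minDepth positions below this depth are skipped with a warning.
#' @param constitutionalLower alternate-fraction threshold for
#'   constitutional calls.
#' @param errorRate assumed per-base sequencing error rate (null
#'   hypothesis of the partial-variant test).
#' @param alpha significance level of the binomial test.
#' @return List of two data.frames, \code{constitutional} and
#'   \code{partial}, each with columns \code{pos}, \code{ref}, \code{alt}
#'   (comma-joined when multi-allelic), \code{fraction}, \code{depth}.
#' @export
callConstitutionalVariants <- function(pileup, minDepth = 30L,
                                       constitutionalLower = 0.9,
                                       errorRate = 0.005, alpha = 0.01) {
  stopifnot(is(pileup, "TransgenePileup"))
  nc <- copyNumber(pileup)
  ac <- altCounts(pileup)
  d <- pileupDepth(pileup)
  empty <- data.frame(pos = integer(), ref = character(), alt = character(),
                      fraction = numeric(), depth = integer())
  if (!nrow(ac)) return(list(constitutional = empty, partial = empty))

  floorFrac <- 1 / (nc + 2)
  agg <- rowsum(ac$count, ac$pos)
  pos <- as.integer(rownames(agg))
  altTot <- as.integer(agg[, 1L])
  depth <- d[pos]
  frac <- ifelse(depth > 0L, altTot / depth, 0)
  shallow <- depth < minDepth
  if (any(shallow))
    warning(sum(shallow), " position(s) below minDepth skipped")
  ## positions below the single-copy detection floor can never be called
  cand <- which(!shallow & frac >= floorFrac)
  cons <- list(); part <- list()
  for (i in cand) {
    grp <- ac[ac$pos == pos[i], , drop = FALSE]
    row <- data.frame(pos = pos[i], ref = grp$ref[1L],
                      alt = paste(grp$alt[order(-grp$count)], collapse = ","),
                      fraction = frac[i], depth = depth[i])
    if (frac[i] >= constitutionalLower) {
      cons[[length(cons) + 1L]] <- row
    } else if (binom.test(altTot[i], depth[i], errorRate,
                          alternative = "greater")$p.value < alpha) {
      part[[length(part) + 1L]] <- row
    }
  }
  list(constitutional = if (length(cons)) do.call(rbind, cons) else empty,
       partial = if (length(part)) do.call(rbind, part) else empty)
}
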