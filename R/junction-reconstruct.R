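## Chimeric-read segmentation and junction-model reconstruction -------------

#' Microhomology between two junction flanks
#'
#' Length (and sequence) of the longest exact match between the terminal
#' suffix of the left flank and the terminal prefix of the right flank,
#' capped at \code{maxLen}. Microhomology at a rearrangement junction is
#' the classic signature of microhomology-mediated repair.
#'
#' @param leftFlank,rightFlank junction flank sequences (character or
#'   DNAString); nonempty.
#' @param maxLen cap on the reported length.
#' @return List with \code{length} and \code{sequence} ("" when none).
#' @examples
#' microhomology("AAACGT", "GTCCC")  # length 2, "GT"
#' @export
microhomology <- function(leftFlank, rightFlank, maxLen = 25L) {
  leftFlank <- as.character(leftFlank); rightFlank <- as.character(rightFlank)
  if (!nzchar(leftFlank) || !nzchar(rightFlank)) stop("flanks must be nonempty")
  nl <- nchar(leftFlank)
  top <- min(maxLen, nl, nchar(rightFlank))
  for (len in rev(seq_len(top))) {
    if (substr(leftFlank, nl - len + 1L, nl) == substr(rightFlank, 1L, len))
      return(list(length = len,
                  sequence = substr(rightFlank, 1L, len)))
  }
  list(length = 0L, sequence = "")
}

## k-mer lookup table of a reference: only k-mers occurring exactly once are
## kept (unique-anchor filtering); duplicated entries are blanked.
kmerTable <- function(refStr, k) {
  n <- nchar(refStr)
  if (n < k) return(character())
  km <- substring(refStr, 1:(n - k + 1L), k:n)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  km[dup] <- NA_character_
  km
}

## anchors of one read frame against one reference table:
## data.frame(qPos, refPos) of exact unique-k-mer matches
frameAnchors <- function(readStr, tbl, k) {
  n <- nchar(readStr)
  if (n < k || !length(tbl))
    return(data.frame(qPos = integer(), refPos = integer()))
  qk <- substring(readStr, 1:(n - k + 1L), k:n)
  hit <- match(qk, tbl)
  keep <- !is.na(hit)
  data.frame(qPos = which(keep), refPos = hit[keep])
}

## chain anchors: same-diagonal groups (substitution-only error model keeps
## diagonals exact), split at query gaps > maxGap, kept at >= minAnchors
chainAnchors <- function(anch, k, minAnchors, maxGap) {
  if (!nrow(anch)) return(list())
  anch$diag <- anch$refPos - anch$qPos
  anch <- anch[order(anch$diag, anch$qPos), ]
  newDiag <- c(TRUE, diff(anch$diag) != 0L)
  gap <- c(TRUE, diff(anch$qPos) > maxGap)
  grp <- cumsum(newDiag | (gap & !newDiag))
  out <- list()
  for (g in unique(grp)) {
    a <- anch[grp == g, ]
    if (nrow(a) < minAnchors) next
    out[[length(out) + 1L]] <- list(
      qStart = min(a$qPos), qEnd = max(a$qPos) + k - 1L,
      refStart = min(a$refPos), refEnd = max(a$refPos) + k - 1L,
      anchors = nrow(a))
  }
  out
}

#' Segment reads into host/transgene blocks by k-mer anchoring
#'
#' Finds exact matches of unique reference k-mers in each read (and its
#' reverse complement), chains collinear anchors per reference and strand,
#' and reports the resulting blocks ordered by read offset. Unanchored read
#' segments (for example inserted bases at a junction) are left unlabeled.
#' The error model this targets is substitution-only long reads, for which
#' anchor chains stay on exact diagonals.
#'
#' @param reads a [Biostrings::DNAStringSet] (or named character vector).
#' @param hostRef,transgeneRef reference sequences (character or DNAString).
#' @param k anchor k-mer size (>= 11).
#' @param minChainAnchors minimum anchors per reported block.
#' @param maxGap maximum within-block anchor gap in read bp.
#' @return A list (one element per read) of data.frames with columns
#'   \code{label} (host/transgene), \code{strand}, \code{readStart},
#'   \code{readEnd}, \code{refStart}, \code{refEnd}, \code{anchors},
#'   sorted by \code{readStart}. Reads shorter than \code{k} yield an
#'   empty data.frame.
#' @export
segmentChimericReads <- function(reads, hostRef, transgeneRef, k = 15L,
                                 minChainAnchors = 4L, maxGap = 2000L) {
  if (k < 11L) stop("k must be >= 11")
  reads <- as.character(reads)
  refs <- list(host = as.character(hostRef),
               transgene = as.character(transgeneRef))
  tbls <- lapply(refs, kmerTable, k = k)

  lapply(reads, function(r) {
    n <- nchar(r)
    rows <- list()
    if (n >= k) {
      rc <- revcompStr(r)
      for (lab in names(tbls)) {
        for (strand in c("+", "-")) {
          frame <- if (strand == "+") r else rc
          chains <- chainAnchors(frameAnchors(frame, tbls[[lab]], k),
                                 k, minChainAnchors, maxGap)
          for (ch in chains) {
            if (strand == "+") {
              rs <- ch$qStart; re <- ch$qEnd
            } else {            # map rc-frame offsets back onto the read
              rs <- n - ch$qEnd + 1L; re <- n - ch$qStart + 1L
            }
            rows[[length(rows) + 1L]] <- data.frame(
              label = lab, strand = strand, readStart = rs, readEnd = re,
              refStart = ch$refStart, refEnd = ch$refEnd,
              anchors = ch$anchors)
          }
        }
      }
    }
    if (!length(rows))
      return(data.frame(label = character(), strand = character(),
                        readStart = integer(), readEnd = integer(),
                        refStart = integer(), refEnd = integer(),
                        anchors = integer()))
    df <- do.call(rbind, rows)
    df[order(df$readStart, df$readEnd), , drop = FALSE]
  })
}

#' @rdname segmentChimericReads
#' @param read a single read (character or DNAString).
#' @export
segmentChimericRead <- function(read, hostRef, transgeneRef, k = 15L,
                                minChainAnchors = 4L, maxGap = 2000L) {
  segmentChimericReads(setNames(as.character(read), "read"),
                       hostRef, transgeneRef, k = k,
                       minChainAnchors = minChainAnchors,
                       maxGap = maxGap)[[1L]]
}

#' Reconstruct an integration-junction model from segmented reads
#'
#' Combines per-read host/transgene blocks into a single [JunctionModel]:
#' breakpoints are medians over supporting reads; the deletion span is the
#' gap between the outermost retained host blocks; an inversion is detected
#' as a minus-strand host block; inserted bases are the consensus of the
#' unlabeled read sequence between the upstream host-side block and the
#' first transgene block; per-junction microhomology is recomputed from the
#' reference sequences at the reconstructed breakpoints. Returns a
#' \code{found = FALSE} model (not an error) when no read carries both host
#' and transgene blocks.
#'
#' @param blocksPerRead output of [segmentChimericReads()].
#' @param reads the reads that were segmented (DNAStringSet or character).
#' @param hostRef,transgeneRef reference sequences used for segmentation.
#' @param hostWindow list or vector with the 1-based host-genome coordinate
#'   of the first base of \code{hostRef} as its first element (and the last
#'   base as its second); block coordinates are reported in host-genome
#'   space.
#' @param oriRange,cosLength monomer annotation used to flag whether the
#'   breakpoint-adjacent truncated monomers retain a functional replication
#'   origin and their cohesive ends (NULL to skip).
#' @return A [JunctionModel].
#' @export
reconstructJunction <- function(blocksPerRead, reads, hostRef, transgeneRef,
                                hostWindow, oriRange = NULL, cosLength = 12L) {
  reads <- as.character(reads)
  hostRef <- as.character(hostRef); transgeneRef <- as.character(transgeneRef)
  ws <- as.integer(hostWindow[[1L]])
  chimeric <- vapply(blocksPerRead, function(b)
    nrow(b) > 0L && any(b$label == "host") && any(b$label == "transgene"),
    logical(1))
  if (!any(chimeric)) return(JunctionModel(found = FALSE))

  leftEnds <- rightStarts <- numeric()
  invS <- invE <- numeric()
  tgUpStart <- tgUpEnd <- tgDownStart <- tgDownEnd <- numeric()
  inserts <- character()

  for (i in which(chimeric)) {
    b <- blocksPerRead[[i]]
    tg <- which(b$label == "transgene")
    hostPlus <- which(b$label == "host" & b$strand == "+")
    hostMinus <- which(b$label == "host" & b$strand == "-")

    before <- hostPlus[hostPlus < min(tg)]
    if (length(before)) {
      lf <- max(before)
      leftEnds <- c(leftEnds, b$refEnd[lf] + ws - 1L)
      firstTg <- min(tg)
      tgUpStart <- c(tgUpStart, b$refStart[firstTg])
      tgUpEnd <- c(tgUpEnd, b$refEnd[firstTg])
      ## inversion evidence: minus-strand host blocks sitting between the
      ## upstream host flank and the first transgene block (minus-strand
      ## blocks elsewhere are chance inverted-repeat matches, not junction
      ## structure)
      invJ <- hostMinus[hostMinus > lf & hostMinus < firstTg]
      if (length(invJ)) {
        invS <- c(invS, b$refStart[invJ] + ws - 1L)
        invE <- c(invE, b$refEnd[invJ] + ws - 1L)
      }
      ## unlabeled gap between the junction-side block (inversion if
      ## present, else the host flank) and the first transgene block
      pre <- if (length(invJ)) max(invJ) else lf
      gap <- b$readStart[firstTg] - b$readEnd[pre] - 1L
      inserts <- c(inserts,
                   if (gap > 0L) substr(reads[i], b$readEnd[pre] + 1L,
                                        b$readStart[firstTg] - 1L) else "")
    }
    after <- hostPlus[hostPlus > max(tg)]
    if (length(after)) {
      rt <- min(after)
      rightStarts <- c(rightStarts, b$refStart[rt] + ws - 1L)
      lastTg <- max(tg)
      tgDownStart <- c(tgDownStart, b$refStart[lastTg])
      tgDownEnd <- c(tgDownEnd, b$refEnd[lastTg])
    }
  }

  med <- function(x) if (length(x)) round(median(x)) else NA_real_
  delStart <- med(leftEnds) + 1
  resume <- med(rightStarts)
  inversion <- if (length(invS)) c(med(invS), med(invE)) else numeric()

  ## consensus inserted bases: modal length, then per-position majority
  insCons <- ""
  if (length(inserts)) {
    lenMode <- as.integer(names(sort(table(nchar(inserts)),
                                     decreasing = TRUE))[1L])
    cand <- inserts[nchar(inserts) == lenMode]
    if (lenMode > 0L) {
      mat <- do.call(rbind, strsplit(cand, ""))
      insCons <- paste(apply(mat, 2L, function(col)
        names(sort(table(col), decreasing = TRUE))[1L]), collapse = "")
    }
  }

  mh <- list()
  flankMax <- 200L
  if (!is.na(delStart) && (length(inversion) || !is.na(resume))) {
    leftFlank <- substr(hostRef, max(1L, delStart - ws + 1L - flankMax),
                        delStart - ws)            # host up to last retained
    rightSeq <- if (length(inversion))
      paste0(revcompStr(substr(hostRef, inversion[1L] - ws + 1L,
                               inversion[2L] - ws + 1L)), insCons)
    else substr(transgeneRef, med(tgUpStart),
                min(nchar(transgeneRef), med(tgUpStart) + flankMax))
    if (nzchar(leftFlank) && nzchar(rightSeq))
      mh$upstream <- microhomology(leftFlank, rightSeq)
  }
  if (!is.na(resume) && length(tgDownEnd)) {
    dEnd <- med(tgDownEnd)
    leftFlank <- substr(transgeneRef, max(1L, dEnd - flankMax), dEnd)
    rightFlank <- substr(hostRef, resume - ws + 1L,
                         min(nchar(hostRef), resume - ws + 1L + flankMax))
    if (nzchar(leftFlank) && nzchar(rightFlank))
      mh$downstream <- microhomology(leftFlank, rightFlank)
  }

  blocks <- data.frame(label = character(), refStart = numeric(),
                       refEnd = numeric(), strand = character(),
                       nReads = integer())
  addBlock <- function(label, rs, re, strand, n) {
    if (is.na(rs) || is.na(re)) return()
    blocks <<- rbind(blocks, data.frame(label = label, refStart = rs,
                                        refEnd = re, strand = strand,
                                        nReads = n))
  }
  addBlock("host", ws, med(leftEnds), "+", length(leftEnds))
  if (length(inversion))
    addBlock("host_inverted", inversion[1L], inversion[2L], "-", length(invS))
  if (nzchar(insCons)) addBlock("insert", NA_real_, NA_real_, "+",
                                sum(nchar(inserts) > 0L))
  addBlock("transgene", med(tgUpStart), med(tgUpEnd), "+", length(tgUpStart))
  addBlock("transgene", med(tgDownStart), med(tgDownEnd), "+",
           length(tgDownStart))
  addBlock("host", resume, as.integer(hostWindow[[2L]] %||% NA), "+",
           length(rightStarts))

  trunc <- list()
  if (!is.null(oriRange)) {
    L <- nchar(transgeneRef)
    flag <- function(rg) list(
      range = rg,
      oriFunctional = !anyNA(rg) && oriRange[1L] >= rg[1L] && oriRange[2L] <= rg[2L],
      cohesiveEndPresent = !anyNA(rg) && rg[1L] <= cosLength && rg[2L] >= L - cosLength + 1L)
    trunc <- list(upstream = flag(c(med(tgUpStart), med(tgUpEnd))),
                  downstream = flag(c(med(tgDownStart), med(tgDownEnd))))
  }

  JunctionModel(found = TRUE, blocks = blocks,
                deletionSpan = c(delStart, resume),
                inversionSpan = inversion, insertedBases = insCons,
                microhomology = mh, monomerTruncations = trunc)
}
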