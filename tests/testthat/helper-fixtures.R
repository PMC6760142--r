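## Shared fixtures and independent brute-force oracles ----------------------

## tiny genotype table from an explicit code matrix
makeTable <- function(gt, keys = NULL, colony = NULL) {
  if (is.null(keys))
    keys <- sprintf("chr1:%d:A:G", seq_len(nrow(gt)) * 100L)
  if (is.null(colony)) colony <- rep("colony1", ncol(gt))
  GenotypeTable(gt, keys, colony)
}

## independent re-derivation of the provenance rule
naiveClassify <- function(key, a, b, k) {
  if (key %in% a && key %in% b) "both_parents"
  else if (key %in% a) "a_only"
  else if (key %in% b) "b_only"
  else if (key %in% k) "known_nonparental"
  else "private"
}

## independent reciprocal-overlap formula
naiveRO <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

## brute-force consensus: keep a call iff every sample has a same-type
## match at >= minRo; span = intersection of best matches
naiveConsensus <- function(sets, minRo) {
  out <- list()
  for (s in seq_along(sets)) {
    for (i in seq_len(nrow(sets[[s]]))) {
      call <- sets[[s]][i, ]
      spans <- matrix(NA_real_, length(sets), 2L)
      for (t in seq_along(sets)) {
        best <- 0; bi <- NA
        for (j in seq_len(nrow(sets[[t]]))) {
          cand <- sets[[t]][j, ]
          if (cand$svtype != call$svtype) next
          ro <- naiveRO(call$start, call$end, cand$start, cand$end)
          if (ro > best) { best <- ro; bi <- j }
        }
        if (!is.na(bi) && best >= minRo)
          spans[t, ] <- c(sets[[t]]$start[bi], sets[[t]]$end[bi])
      }
      if (all(!is.na(spans[, 1L])))
        out[[length(out) + 1L]] <- data.frame(
          start = max(spans[, 1L]), end = min(spans[, 2L]),
          svtype = call$svtype)
    }
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric(),
                                      svtype = character()))
  unique(do.call(rbind, out))
}

## brute-force microhomology: try every suffix/prefix length
naiveMicrohomology <- function(left, right, maxLen = 25L) {
  best <- 0L
  for (len in seq_len(min(maxLen, nchar(left), nchar(right)))) {
    suf <- substr(left, nchar(left) - len + 1L, nchar(left))
    pre <- substr(right, 1L, len)
    if (suf == pre) best <- len
  }
  best
}

## random additive distance matrix from a random tree (ape is the
## independent source here, not the implementation under test)
randomAdditiveMatrix <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(D = ape::cophenetic.phylo(tr), tree = tr)
}

randomCallsetDf <- function(nCalls, span = 10000L) {
  st <- sort(sample.int(span, nCalls))
  data.frame(start = st,
             end = st + sample(50:800, nCalls, replace = TRUE),
             svtype = sample(c("DEL", "DUP"), nCalls, replace = TRUE))
}

dfToCalls <- function(df, source = "depth") {
  intervalCalls(rep("chr1", nrow(df)), df$start, df$end, df$svtype,
                source = source)
}
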