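## Neighbor-joining tree from a discordance matrix --------------------------
## The agglomeration is implemented here (Saitou-Nei joins under the
## Studier-Keppler Q criterion); ape's "phylo" is used only as the output
## container, so established tree tooling (plotting, newick I/O, rooting)
## applies directly.

#' Build a neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix (for example
#' [discordanceMatrix()]'s \code{discordance}): at each step the pair
#' minimizing \eqn{Q(i,j) = (m-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' is joined with the standard branch-length update, and the last three
#' clusters close the unrooted tree with three-point branch lengths. On
#' additive matrices the path-length distances of the result reproduce the
#' input exactly.
#'
#' When \code{colonies} is supplied, the tree is midpoint-rooted and each
#' colony is tested for monophyly, summarizing whether the colonies
#' separate into distinct branches.
#'
#' @param dist symmetric numeric matrix with zero diagonal and sample
#'   names, or the list returned by [discordanceMatrix()].
#' @param colonies optional named vector (sample -> colony label).
#' @return List with \code{tree} (an unrooted [ape::phylo]),
#'   \code{newick} (character) and, when \code{colonies} is given,
#'   \code{monophyletic} (named logical per colony).
#' @export
buildNjTree <- function(dist, colonies = NULL) {
  if (is.list(dist) && !is.null(dist$discordance)) dist <- dist$discordance
  if (!isSymmetric(unname(dist), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have zero diagonal")
  if (anyNA(dist)) stop("distance matrix contains missing values")
  n <- nrow(dist)
  if (n < 3L) stop("need at least 3 samples")
  labels <- rownames(dist) %||% paste0("t", seq_len(n))

  D <- unname(dist)
  sub <- labels                             # newick subtree per cluster
  active <- seq_len(n)

  fmt <- function(x) sprintf("%.10g", x)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- ij[1L]; j <- ij[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- dij - li
    ai <- active[i]; aj <- active[j]
    dNew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    sub[ai] <- sprintf("(%s:%s,%s:%s)", sub[ai], fmt(li), sub[aj], fmt(lj))
    D[ai, active] <- dNew
    D[active, ai] <- dNew
    D[ai, ai] <- 0
    active <- active[-j]
  }
  a <- active
  dab <- D[a[1L], a[2L]]; dac <- D[a[1L], a[3L]]; dbc <- D[a[2L], a[3L]]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[a[1L]], fmt(la),
                    sub[a[2L]], fmt(lb), sub[a[3L]], fmt(lc))
  tree <- ape::read.tree(text = newick)

  out <- list(tree = tree, newick = newick)
  if (!is.null(colonies)) {
    rooted <- phangorn::midpoint(tree)
    out$monophyletic <- vapply(unique(colonies[labels]), function(cl)
      ape::is.monophyletic(rooted, labels[colonies[labels] == cl]),
      logical(1))
  }
  out
}
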