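# Phylogenetic comparative layer: Brownian-motion covariance, multivariate
# phylogenetic signal, and GLS-transformed (phylogenetic) ANOVA and PLS.

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion the expected covariance of a trait between two tips
#' equals the shared root-to-ancestor path length; the diagonal holds
#' root-to-tip depths.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param speciesOrder character vector giving the row/column order; all
#'   species must be tips of the tree.
#' @return the N x N covariance matrix (symmetric positive semi-definite).
#' @export
bmCovariance <- function(tree, speciesOrder = tree$tip.label) {
  missing <- setdiff(speciesOrder, tree$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  C <- ape::vcv.phylo(tree)
  C[speciesOrder, speciesOrder]
}

# C, its inverse and inverse square root, with singular protection: zero
# branch lengths are perturbed by 1e-8 x tree depth before inversion.
.phyloPrep <- function(tree, speciesOrder) {
  if (any(tree$edge.length == 0)) {
    warning("zero-length branches perturbed before inversion")
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- pmax(tree$edge.length, 1e-8 * depth)
  }
  C <- bmCovariance(tree, speciesOrder)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0) stop("Brownian covariance is singular")
  Cinv <- e$vectors %*% (t(e$vectors) / e$values)
  P <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  list(C = C, Cinv = Cinv, P = P)
}

# Phylogenetic (GLS) grand mean: one row vector over traits.
.phyloMean <- function(Y, Cinv) {
  one <- rep(1, nrow(Y))
  as.numeric(crossprod(one, Cinv %*% Y)) / sum(Cinv)
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Measures the similarity of multivariate trait values among species
#' relative to the expectation under Brownian motion on the tree; Kmult = 1
#' is the Brownian expectation, values above 1 indicate more similarity
#' among close relatives than expected, values below 1 less. Significance is
#' assessed by permuting species across the tips.
#'
#' @param Y \code{N x p} matrix of per-species values, rows named by species
#'   (or ordered as the tree's tips).
#' @param tree rooted \code{phylo}, N >= 4 tips.
#' @param nperm permutations (0 skips the test).
#' @param seed integer seed.
#' @return a \linkS4class{KmultResult}. The statistic is invariant to a
#'   common rescaling of all branch lengths.
#' @export
kmult <- function(Y, tree, nperm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (N < 4L) stop("at least 4 species required")
  sp <- rownames(Y)
  if (is.null(sp)) {
    if (N != length(tree$tip.label))
      stop("unnamed Y must have one row per tip")
    sp <- tree$tip.label
  }
  prep <- .phyloPrep(tree, sp)
  if (all(apply(Y, 2, stats::var) == 0))
    stop("undefined statistic: Y is constant across species")
  denom <- (sum(diag(prep$C)) - N / sum(prep$Cinv)) / (N - 1)
  stat <- function(Y) {
    E <- sweep(Y, 2, .phyloMean(Y, prep$Cinv))
    (sum(E^2) / sum(E * (prep$Cinv %*% E))) / denom
  }
  k <- stat(Y)
  p <- NA_real_
  if (nperm > 0) {
    perms <- .permIndices(N, nperm, seed)
    kp <- vapply(seq_len(nperm), function(b)
      stat(Y[perms[b, ], , drop = FALSE]), numeric(1))
    p <- .permP(k, kp)
  }
  new("KmultResult", statistic = k, pValue = p, nperm = nperm)
}

#' Procrustes ANOVA in a phylogenetic framework
#'
#' Generalized least-squares version of [procrustesAnova()]: response and
#' design are premultiplied by the inverse square root of the Brownian
#' covariance (symmetric eigendecomposition), the response centred on the
#' phylogenetic grand mean, and the RRPP machinery applied to the
#' transformed data. On a star tree with equal branch lengths this
#' coincides with the non-phylogenetic ANOVA.
#'
#' @param Y \code{N x p} per-species shape variables, rows named by species.
#' @param groups group labels per species.
#' @param tree rooted \code{phylo}.
#' @inheritParams rrppModel
#' @return an \linkS4class{AnovaResult}.
#' @export
phyloProcrustesAnova <- function(Y, groups, tree, nperm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  sp <- rownames(Y)
  if (is.null(sp)) sp <- tree$tip.label[seq_len(nrow(Y))]
  prep <- .phyloPrep(tree, sp)
  Yt <- prep$P %*% sweep(Y, 2, .phyloMean(Y, prep$Cinv))
  X <- stats::model.matrix(~ as.factor(groups))
  hats <- list(.hat(prep$P %*% matrix(1, nrow(Y), 1)),
               .hat(prep$P %*% X))
  if (hats[[2]]$rank == hats[[1]]$rank)
    stop("rank-deficient design: term 'group' is aliased")
  .rrppEngine(Yt, hats, "group", nperm = nperm, seed = seed)
}

#' Phylogenetic two-block partial least squares
#'
#' Assesses the evolutionary covariation of two trait blocks under Brownian
#' motion: both blocks are centred on their phylogenetic grand means and
#' premultiplied by the inverse square root of the Brownian covariance, then
#' analysed with [twoBlockPls()] (no further centering). Permutation
#' shuffles the transformed rows. On a star tree with equal branch lengths
#' this coincides with the ordinary PLS.
#'
#' @param Y1,Y2 \code{N x p} per-species blocks over the same species set,
#'   rows named by species.
#' @param tree rooted \code{phylo}.
#' @inheritParams twoBlockPls
#' @return a \linkS4class{PlsResult}.
#' @export
phyloPls <- function(Y1, Y2, tree, nperm = 999, seed = NULL) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (nrow(Y1) != nrow(Y2)) stop("blocks must cover the same species")
  sp <- rownames(Y1)
  if (is.null(sp)) sp <- tree$tip.label[seq_len(nrow(Y1))]
  if (!is.null(rownames(Y2)) && !identical(sp, rownames(Y2)))
    stop("block rows must be in the same species order")
  prep <- .phyloPrep(tree, sp)
  Y1t <- prep$P %*% sweep(Y1, 2, .phyloMean(Y1, prep$Cinv))
  Y2t <- prep$P %*% sweep(Y2, 2, .phyloMean(Y2, prep$Cinv))
  twoBlockPls(Y1t, Y2t, nperm = nperm, seed = seed, center = FALSE)
}
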