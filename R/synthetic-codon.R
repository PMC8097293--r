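# Simulation of codon alignments under the branch-class codon model.

#' Simulate a codon alignment along a tree
#'
#' Evolves codon sequences (61 sense codons, universal code) along a tree
#' under the substitution process of \code{\link{codonRateMatrix}}, with
#' one omega per branch class. Branch lengths are in expected
#' substitutions per codon.
#'
#' @param tree rooted or unrooted \code{phylo} with branch lengths.
#' @param omega numeric vector of dN/dS per branch class.
#' @param kappa transition/transversion ratio (> 0).
#' @param branchClass integer vector (per \code{tree$edge} row) of class
#'   indices into \code{omega}; default all class 1.
#' @param pi codon frequencies (length 61); default uniform.
#' @param nCodons number of codon sites.
#' @param seed integer seed (optional).
#' @return codon character matrix (tips x sites) with attributes
#'   \code{"params"} (the generating parameters) and \code{"dna"}
#'   (named character vector of ungapped coding sequences).
#' @export
simulateCodonAlignment <- function(tree, omega, kappa, branchClass = NULL,
                                   pi = NULL, nCodons = 500L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(omega < 0)) stop("omega must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  tab <- .codonTable()
  n <- length(tab$codons)
  pi <- pi %||% rep(1 / n, n)
  nEdge <- nrow(tree$edge)
  branchClass <- branchClass %||% rep(1L, nEdge)
  stopifnot(length(branchClass) == nEdge,
            all(branchClass %in% seq_along(omega)))
  len <- tree$edge.length
  if (is.null(len)) stop("tree must have branch lengths")
  .withSeed(seed, {
    eigs <- lapply(omega, function(w)
      .codonEigen(codonRateMatrix(w, kappa, pi), pi))
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    states <- matrix(NA_integer_, nTip + tree$Nnode, nCodons)
    states[root, ] <- sample.int(n, nCodons, replace = TRUE, prob = pi)
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    ord <- match(paste(edge[, 1], edge[, 2]),
                 paste(tree$edge[, 1], tree$edge[, 2]))
    for (k in seq_len(nEdge)) {
      e <- ord[k]
      P <- .codonP(eigs[[branchClass[e]]], len[e])
      par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      ps <- states[par, ]
      states[chd, ] <- vapply(seq_len(nCodons), function(sidx)
        sample.int(n, 1L, prob = P[ps[sidx], ]), integer(1))
    }
    m <- matrix(tab$codons[states[seq_len(nTip), , drop = FALSE]],
                nrow = nTip, dimnames = list(tree$tip.label, NULL))
    attr(m, "params") <- list(omega = omega, kappa = kappa,
                              branchClass = branchClass, pi = pi)
    attr(m, "dna") <- setNames(apply(m, 1, paste, collapse = ""),
                               tree$tip.label)
    m
  })
}
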