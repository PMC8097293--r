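# Codon substitution model: state space, rate matrix, alignment threading,
# and the pruning log-likelihood (C++ backend).

.mavkitCache <- new.env(parent = emptyenv())

# Universal genetic code over the 61 sense codons, plus the single-nucleotide
# neighbour structure used to build the Muse-Gaut/Goldman-Yang style rate
# matrix: for each ordered pair of codons differing at exactly one position,
# whether the change is a transition and whether it is nonsynonymous.
.codonTable <- function() {
  if (!is.null(.mavkitCache$codonTable)) return(.mavkitCache$codonTable)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)            # 61
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  ii <- integer(0); jj <- integer(0); ti <- integer(0); ns <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(cmat[i, ] != cmat[j, ])
      if (length(diff) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ti <- c(ti, as.integer(transitions[[cmat[i, diff]]] == cmat[j, diff]))
      ns <- c(ns, as.integer(aa[i] != aa[j]))
    }
  }
  tab <- list(codons = codons, aa = aa,
              nbr = cbind(i = ii, j = jj, ti = ti, nonsyn = ns))
  .mavkitCache$codonTable <- tab
  tab
}

#' Codon substitution rate matrix
#'
#' Builds the 61 x 61 generator of the codon substitution process with
#' transition/transversion ratio \code{kappa} and nonsynonymous/synonymous
#' ratio \code{omega}: instantaneous rates are zero for multi-nucleotide
#' changes and proportional to \code{pi[j]}, times \code{kappa} for
#' transitions and times \code{omega} for nonsynonymous changes, otherwise.
#' The matrix is scaled so that the expected number of substitutions per
#' codon per unit branch length equals 1 at stationarity.
#'
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi codon stationary frequencies (length 61, summing to 1);
#'   defaults to uniform.
#' @return a 61 x 61 matrix with rows summing to zero, codon names from the
#'   universal code (stop codons excluded).
#' @export
codonRateMatrix <- function(omega, kappa, pi = NULL) {
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("omega must be a single non-negative number")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive number")
  tab <- .codonTable()
  n <- length(tab$codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(length(pi) == n, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  nbr <- tab$nbr
  rate <- pi[nbr[, "j"]] *
    ifelse(nbr[, "ti"] == 1L, kappa, 1) *
    ifelse(nbr[, "nonsyn"] == 1L, omega, 1)
  Q[cbind(nbr[, "i"], nbr[, "j"])] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  Q
}

# Symmetric eigendecomposition of a reversible generator. Returns a list
# allowing P(t) = D^-1/2 U exp(L t) U' D^1/2 for any t.
.codonEigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, d = d)
}

.codonP <- function(eig, t) {
  U <- eig$vectors
  P <- (U %*% (exp(eig$values * t) * t(U)))
  P <- P * ((1 / eig$d) %o% eig$d)
  P[P < 0] <- 0
  P
}

#' Thread coding sequences onto a protein guide alignment
#'
#' Builds an in-frame codon alignment from unaligned CDS sequences and a
#' protein alignment of their translations, the classic translation-guided
#' (TranslatorX-style) construction: every aligned amino acid becomes its
#' source codon and every protein gap becomes a codon gap ("---"), so all
#' rows share one reading frame.
#'
#' @param cds a \code{DNAStringSet} (or named character vector) of coding
#'   sequences; lengths must be divisible by 3 and free of internal stops.
#' @param guide an \code{AAStringSet} (or named character vector) with the
#'   aligned translations, same names as \code{cds}.
#' @return a character matrix of codons (rows = sequences, columns = codon
#'   sites), with attribute \code{"dna"} holding the gapped nucleotide
#'   alignment as a character vector.
#' @export
buildCodonAlignment <- function(cds, guide) {
  cds <- setNames(as.character(cds), names(cds))
  guide <- setNames(as.character(guide), names(guide))
  if (is.null(names(cds)) || is.null(names(guide)) ||
      !setequal(names(cds), names(guide)))
    stop("cds and guide must be named and share the same sequence names")
  guide <- guide[names(cds)]
  w <- unique(nchar(guide))
  if (length(w) != 1L) stop("guide alignment is ragged")
  gc <- Biostrings::GENETIC_CODE
  rows <- lapply(names(cds), function(id) {
    dna <- cds[[id]]
    if (nchar(dna) %% 3 != 0)
      stop("CDS length of ", id, " is not divisible by 3")
    codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
    aa <- gc[codons]
    if (any(is.na(aa)))
      stop("CDS of ", id, " contains unrecognised codons")
    # trailing stop codon tolerated, internal stops are not
    if (length(aa) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*"))
      stop("CDS of ", id, " contains an internal stop codon at codon ",
           which(aa == "*")[1])
    g <- strsplit(guide[[id]], "", fixed = TRUE)[[1]]
    res <- g != "-" & g != "."
    if (sum(res) != length(aa))
      stop("guide row of ", id, " has ", sum(res),
           " residues but the CDS encodes ", length(aa))
    mism <- which(g[res] != aa & g[res] != "X")
    if (length(mism))
      stop("translation mismatch for ", id, " at guide residue ",
           which(res)[mism[1]], ": CDS encodes ", aa[mism[1]],
           " but guide has ", g[res][mism[1]])
    out <- rep("---", length(g))
    out[res] <- codons
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(cds)
  attr(m, "dna") <- setNames(apply(m, 1, paste, collapse = ""), names(cds))
  m
}

# Convert a codon character matrix to 0-based codon indices (-1 for gaps or
# anything unrecognised, which is treated as missing data).
.codonIndices <- function(codonMatrix) {
  tab <- .codonTable()
  idx <- match(codonMatrix, tab$codons) - 1L
  idx[is.na(idx)] <- -1L
  matrix(idx, nrow = nrow(codonMatrix),
         dimnames = list(rownames(codonMatrix), NULL))
}

# Collapse alignment columns into unique site patterns with weights.
.sitePatterns <- function(idx) {
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = idx[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

# Root a (possibly unrooted) binary tree representation for pruning and
# return postorder edge tables.
.pruningTables <- function(tree, tipNames) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  tree <- ape::reorder.phylo(tree, "postorder")
  tip <- match(tipNames, tree$tip.label)
  if (any(is.na(tip)))
    stop("alignment rows missing from tree: ",
         paste(tipNames[is.na(tip)], collapse = ", "))
  list(tree = tree, edge = tree$edge, tipIndex = tip,
       nTip = length(tree$tip.label), root = ape::Ntip(tree) + 1L)
}

#' Codon model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a tree under the
#' codon substitution model of \code{\link{codonRateMatrix}}, with one
#' omega per branch class. Gaps are treated as missing data (partial
#' likelihood 1). Numerical underflow is handled by per-pattern rescaling.
#'
#' @param alignment codon character matrix (rows named by tree tips), as
#'   produced by \code{\link{buildCodonAlignment}} or
#'   \code{\link{simulateCodonAlignment}}.
#' @param tree a \code{phylo} tree whose tip labels match the rows.
#' @param omega numeric vector of dN/dS values, one per branch class.
#' @param kappa transition/transversion ratio.
#' @param branchClass integer vector assigning each tree edge (in
#'   \code{tree$edge} order) to a class in \code{seq_along(omega)};
#'   default: all edges in class 1.
#' @param branchLengths optional replacement branch lengths (expected
#'   substitutions per codon); defaults to \code{tree$edge.length}.
#' @param pi codon frequencies (length 61); default uniform. See
#'   \code{\link{codonFrequencies}} for the F1x4 and empirical estimators.
#' @return the log-likelihood (scalar).
#' @export
codonLogLikelihood <- function(alignment, tree, omega, kappa,
                               branchClass = NULL, branchLengths = NULL,
                               pi = NULL) {
  tab <- .codonTable()
  if (is.character(alignment)) idx <- .codonIndices(alignment)
  else idx <- alignment
  pt <- .pruningTables(tree, rownames(idx))
  nEdge <- nrow(pt$edge)
  branchClass <- branchClass %||% rep(1L, nEdge)
  branchLengths <- branchLengths %||% pt$tree$edge.length
  if (is.null(branchLengths))
    stop("tree has no branch lengths and none were supplied")
  if (length(branchClass) != nEdge || length(branchLengths) != nEdge)
    stop("branchClass/branchLengths must have one entry per tree edge")
  if (any(branchLengths < 0)) stop("negative branch length")
  if (any(omega < 0) || kappa <= 0)
    stop("omega must be >= 0 and kappa > 0")
  n <- length(tab$codons)
  pi <- pi %||% rep(1 / n, n)
  sp <- .sitePatterns(idx[pt$tree$tip.label, , drop = FALSE])
  cpp_codon_lnL(pt$edge, nrow(sp$patterns), sp$patterns, sp$weights,
                pi, kappa, omega, as.integer(branchClass) - 1L,
                branchLengths,
                .codonTable()$nbr[, 1L] - 1L, .codonTable()$nbr[, 2L] - 1L,
                .codonTable()$nbr[, 3L], .codonTable()$nbr[, 4L])
}

#' Codon frequency estimators
#'
#' \code{codonFrequencies} returns stationarity frequencies for the codon
#' model: \code{"uniform"} (1/61 each), \code{"F1x4"} (product of the
#' position-independent empirical nucleotide frequencies, renormalised over
#' sense codons) or \code{"F61"} (empirical codon frequencies with additive
#' pseudocount 0.5).
#'
#' @param alignment codon character matrix (gaps ignored).
#' @param method one of "uniform", "F1x4", "F61".
#' @return numeric length-61 vector summing to 1.
#' @export
codonFrequencies <- function(alignment, method = c("F1x4", "F61", "uniform")) {
  method <- match.arg(method)
  tab <- .codonTable()
  n <- length(tab$codons)
  if (method == "uniform") return(setNames(rep(1 / n, n), tab$codons))
  cod <- alignment[alignment %in% tab$codons]
  if (method == "F61") {
    cnt <- table(factor(cod, levels = tab$codons)) + 0.5
    return(setNames(as.numeric(cnt / sum(cnt)), tab$codons))
  }
  ntfreq <- table(factor(strsplit(paste(cod, collapse = ""), "")[[1]],
                         levels = .DNA_BASES))
  ntfreq <- (ntfreq + 1) / sum(ntfreq + 1)
  cmat <- do.call(rbind, strsplit(tab$codons, "", fixed = TRUE))
  p <- ntfreq[cmat[, 1]] * ntfreq[cmat[, 2]] * ntfreq[cmat[, 3]]
  setNames(as.numeric(p / sum(p)), tab$codons)
}
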