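# Alignment quality statistics: gap trimming, entropy, classic distance
# corrections, and multi-criteria alignment ranking.

#' Remove gap-rich columns
#'
#' Drops every column whose gap fraction is greater than or equal to
#' \code{maxGapFraction} (boundary inclusive, matching the ">= 50% gaps"
#' and ">= 99% gaps" trimming rules). Row order is preserved.
#'
#' @param alignment \code{XStringSet}, character vector or character
#'   matrix (rectangular).
#' @param maxGapFraction removal threshold in [0, 1].
#' @return list: \code{alignment} (character matrix) and \code{removed}
#'   (indices of removed columns).
#' @export
trimGapColumns <- function(alignment, maxGapFraction) {
  m <- .alignmentMatrix(alignment)
  gapFrac <- colMeans(matrix(m %in% .GAP_CHARS, nrow(m)))
  removed <- which(gapFrac >= maxGapFraction)
  keep <- setdiff(seq_len(ncol(m)), removed)
  list(alignment = m[, keep, drop = FALSE], removed = removed)
}

#' Subset an alignment to rows with little gap content
#'
#' Retains sequences whose row gap fraction is at most
#' \code{maxRowGapFraction} (the "<= 10% gaps" scaffold-subset rule).
#'
#' @param alignment rectangular alignment.
#' @param maxRowGapFraction retention threshold.
#' @return character matrix of the retained rows (possibly 0 rows).
#' @export
subsetByRowGappiness <- function(alignment, maxRowGapFraction = 0.10) {
  m <- .alignmentMatrix(alignment)
  gapFrac <- rowMeans(matrix(m %in% .GAP_CHARS, nrow(m)))
  m[gapFrac <= maxRowGapFraction, , drop = FALSE]
}

#' Mean Shannon entropy of an alignment
#'
#' Per-column entropy H = -sum p_i log2 p_i over the observed residues
#' (gaps and missing symbols X are excluded from the frequencies),
#' averaged over columns with at least one residue.
#'
#' @param alignment rectangular alignment (protein or nucleotide).
#' @return mean entropy in bits.
#' @export
meanShannonEntropy <- function(alignment) {
  m <- .alignmentMatrix(alignment)
  if (!length(m)) stop("empty alignment")
  hs <- apply(m, 2, function(col) {
    obs <- col[!col %in% c(.GAP_CHARS, "X", "x")]
    if (!length(obs)) return(NA_real_)
    p <- table(obs) / length(obs)
    -sum(p * log2(p))
  })
  mean(hs, na.rm = TRUE)
}

#' Pairwise evolutionary distances between aligned sequences
#'
#' Computes the distance between two aligned rows under the classic
#' corrections, from the proportion p of differing sites among sites
#' ungapped in both rows:
#' observed: p; Jukes-Cantor generalised to alphabet size q:
#' -((q-1)/q) ln(1 - q p/(q-1)); Poisson: -ln(1-p); Gamma:
#' a((1-p)^(-1/a) - 1) with shape a.
#'
#' @param seqA,seqB aligned sequences (equal length, character or
#'   XString).
#' @param model "observed", "JC", "Poisson" or "Gamma".
#' @param q alphabet size for JC (20 for proteins, 4 for nucleotides).
#' @param gammaAlpha Gamma shape parameter.
#' @return the distance; \code{Inf} with attribute \code{saturated = TRUE}
#'   when p lies at or beyond the model's singularity.
#' @export
pairwiseDistance <- function(seqA, seqB,
                             model = c("observed", "JC", "Poisson",
                                       "Gamma"),
                             q = 20, gammaAlpha = 1) {
  model <- match.arg(model)
  a <- strsplit(as.character(seqA), "", fixed = TRUE)[[1]]
  b <- strsplit(as.character(seqB), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences are not aligned")
  keep <- !(a %in% .GAP_CHARS) & !(b %in% .GAP_CHARS)
  if (!sum(keep)) return(NA_real_)
  p <- mean(a[keep] != b[keep])
  sat <- function() structure(Inf, saturated = TRUE)
  switch(model,
    observed = p,
    JC = {
      arg <- 1 - q * p / (q - 1)
      if (arg <= 0) sat() else -((q - 1) / q) * log(arg)
    },
    Poisson = if (p >= 1) sat() else -log(1 - p),
    Gamma = if (p >= 1) sat() else gammaAlpha * ((1 - p)^(-1 / gammaAlpha) - 1))
}

#' Summary statistics of a protein alignment
#'
#' The alignment-choice statistics: alignment length; mean/max/min
#' ungapped sequence lengths; residue content (fraction of non-gap
#' cells); average pairwise identity (excluding pairwise-gapped sites);
#' most related and most unrelated pair and most distant sequence (by
#' observed distance); mean Shannon entropy; and mean observed, JC,
#' Poisson and Gamma distances over all pairs.
#'
#' @param alignment rectangular alignment.
#' @param q,gammaAlpha distance parameters.
#' @return a one-row data.frame (pair/sequence ids as strings).
#' @export
alignmentSummary <- function(alignment, q = 20, gammaAlpha = 1) {
  m <- .alignmentMatrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("alignment needs at least two sequences")
  ids <- rownames(m) %||% paste0("seq", seq_len(n))
  rownames(m) <- ids
  rows <- apply(m, 1, paste, collapse = "")
  isGap <- matrix(m %in% .GAP_CHARS, n)
  lens <- ncol(m) - rowSums(isGap)
  pairs <- utils::combn(n, 2)
  ident <- dObs <- dJc <- dPois <- dGam <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dObs[k] <- pairwiseDistance(rows[i], rows[j], "observed", q)
    dJc[k] <- pairwiseDistance(rows[i], rows[j], "JC", q)
    dPois[k] <- pairwiseDistance(rows[i], rows[j], "Poisson", q)
    dGam[k] <- pairwiseDistance(rows[i], rows[j], "Gamma", q, gammaAlpha)
    ident[k] <- 1 - dObs[k]
  }
  pairName <- function(k) paste(ids[pairs[1, k]], ids[pairs[2, k]],
                                sep = "|")
  meanDistPerSeq <- vapply(seq_len(n), function(i)
    mean(dObs[pairs[1, ] == i | pairs[2, ] == i]), numeric(1))
  data.frame(
    alignmentLength = ncol(m),
    meanSeqLength = mean(lens), maxSeqLength = max(lens),
    minSeqLength = min(lens),
    residueContent = 1 - mean(isGap),
    averageIdentity = mean(ident),
    mostRelatedPair = pairName(which.max(ident)),
    mostUnrelatedPair = pairName(which.min(ident)),
    mostDistantSequence = ids[which.max(meanDistPerSeq)],
    meanEntropy = meanShannonEntropy(m),
    meanObserved = mean(dObs), meanJC = mean(dJc),
    meanPoisson = mean(dPois), meanGamma = mean(dGam),
    stringsAsFactors = FALSE)
}

#' Rank candidate alignments of the same sequence set
#'
#' Orders alignments by the selection criteria: highest average identity
#' and residue content, lowest mean entropy and lowest mean pairwise
#' distances (observed, JC, Poisson, Gamma). Each criterion is ranked
#' separately; the final order is by mean rank, ties broken by higher
#' average identity, then input order.
#'
#' @param alignments list of >= 2 rectangular alignments over the same
#'   sequence names.
#' @param q,gammaAlpha distance parameters.
#' @return list: \code{order} (indices into the input, best first) and
#'   \code{summaries} (per-alignment statistics with \code{meanRank}).
#' @export
rankAlignments <- function(alignments, q = 20, gammaAlpha = 1) {
  if (length(alignments) < 2L) stop("need at least two alignments")
  mats <- lapply(alignments, .alignmentMatrix)
  nameSets <- lapply(mats, function(m) sort(rownames(m) %||% character(0)))
  if (length(unique(vapply(nameSets, paste, character(1),
                           collapse = ","))) != 1L)
    stop("alignments do not contain the same sequence set")
  sums <- do.call(rbind, lapply(mats, alignmentSummary, q = q,
                                gammaAlpha = gammaAlpha))
  higher <- c("averageIdentity", "residueContent")
  lower <- c("meanEntropy", "meanObserved", "meanJC", "meanPoisson",
             "meanGamma")
  ranks <- cbind(
    vapply(higher, function(cn) rank(-sums[[cn]], ties.method = "average"),
           numeric(nrow(sums))),
    vapply(lower, function(cn) rank(sums[[cn]], ties.method = "average"),
           numeric(nrow(sums))))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  meanRank <- rowMeans(ranks)
  ord <- order(meanRank, -sums$averageIdentity, seq_along(alignments))
  sums$meanRank <- meanRank
  list(order = ord, summaries = sums)
}
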