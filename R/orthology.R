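# Orthologous-insertion detection: flank extraction, reciprocal flank
# hits, seed-and-chain colinearity, component grouping, and lognormal age
# calibration.

#' Extract element flanks
#'
#' Returns up to \code{flank} bp of host DNA on each side of an element,
#' excluding both TSD copies and the element itself. Flanks truncated by
#' contig ends are flagged; a zero-length flank marks the locus unusable.
#'
#' @param genome \code{DNAString} or character (the contig).
#' @param elementStart,elementEnd element boundaries (1-based inclusive).
#' @param flank flank length (default 2 kb).
#' @param tsdLength TSD length excluded next to each boundary.
#' @return list: \code{left}, \code{right} (\code{DNAString}),
#'   \code{clippedLeft}, \code{clippedRight}, \code{usable}.
#' @export
extractFlanks <- function(genome, elementStart, elementEnd, flank = 2000L,
                          tsdLength = 6L) {
  s <- .asDnaString(genome)
  n <- length(s)
  leftTo <- elementStart - tsdLength - 1L
  leftFrom <- max(1L, leftTo - as.integer(flank) + 1L)
  rightFrom <- elementEnd + tsdLength + 1L
  rightTo <- min(n, rightFrom + as.integer(flank) - 1L)
  left <- if (leftTo >= leftFrom) Biostrings::subseq(s, leftFrom, leftTo)
          else Biostrings::DNAString("")
  right <- if (rightTo >= rightFrom)
    Biostrings::subseq(s, rightFrom, rightTo) else Biostrings::DNAString("")
  list(left = left, right = right,
       clippedLeft = leftFrom == 1L && leftTo - leftFrom + 1L < flank,
       clippedRight = rightTo == n && rightTo - rightFrom + 1L < flank,
       usable = length(left) > 0L && length(right) > 0L)
}

# nucleotide local alignment: returns identity over the aligned span and
# the span length
.nucLocalHit <- function(a, b, gapOpen = 5, gapExtend = 2) {
  if (!length(a) || !length(b)) return(list(identity = 0, length = 0L))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(as.character(a)),
                                      Biostrings::DNAString(as.character(b)),
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend)
  alen <- Biostrings::nchar(pa)
  if (!length(alen) || alen == 0L) return(list(identity = 0, length = 0L))
  list(identity = Biostrings::pid(pa) / 100, length = alen)
}

#' Find candidate ortholog pairs from flank similarity
#'
#' Two element loci are candidate orthologs when the left flank of one
#' hits the left flank of the other AND the right flanks hit as well
#' (local nucleotide alignment with identity >= \code{minIdentity} over
#' >= \code{minLength} aligned bp) - the reciprocal "hits to both flanks"
#' rule. Same-genome pairs are excluded unless
#' \code{allowSameGenome = TRUE} (segmental-duplication guard).
#'
#' @param loci list; each entry has \code{locusId}, \code{genomeId},
#'   \code{left}, \code{right} (flank sequences).
#' @param minIdentity,minLength flank-hit acceptance cutoffs.
#' @param allowSameGenome allow pairs within one genome.
#' @return data.frame of candidate pairs: \code{locusA}, \code{locusB},
#'   \code{leftIdentity}, \code{rightIdentity}.
#' @export
flankPairCandidates <- function(loci, minIdentity = 0.7, minLength = 200L,
                                allowSameGenome = FALSE) {
  empty <- data.frame(locusA = character(0), locusB = character(0),
                      leftIdentity = numeric(0),
                      rightIdentity = numeric(0))
  if (length(loci) < 2L) return(empty)
  out <- list()
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (j <= i) next
    x <- loci[[i]]; y <- loci[[j]]
    if (!allowSameGenome && identical(x$genomeId, y$genomeId)) next
    hl <- .nucLocalHit(x$left, y$left)
    if (hl$identity < minIdentity || hl$length < minLength) next
    hr <- .nucLocalHit(x$right, y$right)
    if (hr$identity < minIdentity || hr$length < minLength) next
    out[[length(out) + 1L]] <- data.frame(
      locusA = x$locusId, locusB = y$locusId,
      leftIdentity = hl$identity, rightIdentity = hr$identity,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Colinearity check between two full loci
#'
#' Scores large-scale colinearity between two locus sequences
#' (flank + element + flank) by exact k-mer anchors: k-mers unique to both
#' sequences are matched, chained monotonically (longest increasing
#' subsequence in both coordinates), and the score is the fraction of
#' flank positions covered by chained anchors. A locus pair is accepted
#' when both the left and the right flank reach \code{minCover} coverage.
#' This replaces a visual synteny judgement with a deterministic
#' statistic; the cutoff is configurable. For loci whose element lacks
#' TIR-defined limits, extract the locus with an extra 10-kb walk-out on
#' each flank and score that extended window instead.
#'
#' @param locusX,locusY full locus sequences.
#' @param flankX,flankY c(left, right) flank lengths within each locus.
#' @param k anchor k-mer size. The default of 12 keeps exact anchors
#'   frequent enough to chain at the 5-10\% flank divergences orthologous
#'   insertions show, while chance k-mer collisions between unrelated
#'   2-kb flanks still contribute negligible coverage.
#' @param minCover per-flank coverage needed for acceptance.
#' @return list: \code{score} (mean flank coverage of locus X),
#'   \code{leftCover}, \code{rightCover}, \code{accept}, \code{reason}.
#' @export
colinearityCheck <- function(locusX, locusY, flankX, flankY, k = 12L,
                             minCover = 0.5) {
  sx <- as.character(locusX); sy <- as.character(locusY)
  if (nchar(sx) < k || nchar(sy) < k)
    return(list(score = 0, leftCover = 0, rightCover = 0, accept = FALSE,
                reason = "sequence shorter than anchor size"))
  kmersOf <- function(s) {
    starts <- 1:(nchar(s) - k + 1L)
    setNames(starts, substring(s, starts, starts + k - 1L))
  }
  kx <- kmersOf(sx); ky <- kmersOf(sy)
  ux <- names(kx)[!(duplicated(names(kx)) |
                    duplicated(names(kx), fromLast = TRUE))]
  uy <- names(ky)[!(duplicated(names(ky)) |
                    duplicated(names(ky), fromLast = TRUE))]
  shared <- intersect(ux, uy)
  if (!length(shared))
    return(list(score = 0, leftCover = 0, rightCover = 0, accept = FALSE,
                reason = "no shared unique anchors"))
  px <- kx[shared]; py <- ky[shared]
  o <- order(px)
  px <- px[o]; py <- py[o]
  # longest increasing subsequence of py (monotone chain in both coords)
  lis <- integer(0)     # indices into px/py
  tails <- integer(0)   # py values of chain tails
  prev <- integer(length(py))
  tailIdx <- integer(0)
  for (i in seq_along(py)) {
    pos <- findInterval(py[i] - 1L, tails) + 1L
    tails[pos] <- py[i]
    tailIdx[pos] <- i
    prev[i] <- if (pos > 1L) tailIdx[pos - 1L] else 0L
    length(tails) <- max(length(tails), pos)
  }
  chain <- integer(0)
  i <- tailIdx[length(tails)]
  while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
  anchors <- px[chain]
  covered <- IRanges::reduce(IRanges::IRanges(anchors, anchors + k - 1L))
  nx <- nchar(sx)
  leftRange <- IRanges::IRanges(1L, flankX[1])
  rightRange <- IRanges::IRanges(nx - flankX[2] + 1L, nx)
  coverOf <- function(range) {
    ov <- IRanges::intersect(covered, range)
    sum(IRanges::width(ov)) / IRanges::width(range)
  }
  leftCover <- coverOf(leftRange)
  rightCover <- coverOf(rightRange)
  list(score = mean(c(leftCover, rightCover)), leftCover = leftCover,
       rightCover = rightCover,
       accept = leftCover >= minCover && rightCover >= minCover,
       reason = NA_character_)
}

#' Group accepted ortholog pairs into ortholog groups
#'
#' Connected components over the locus graph defined by accepted pairs;
#' each component with >= 2 members is one ortholog group. Grouping is
#' independent of input order (members are sorted).
#'
#' @param pairs data.frame with columns \code{locusA}, \code{locusB}.
#' @return list of character vectors (sorted member locus ids), ordered by
#'   first member.
#' @export
groupOrthologs <- function(pairs) {
  if (!nrow(pairs)) return(list())
  g <- igraph::graph_from_data_frame(
    pairs[, c("locusA", "locusB")], directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(x) sort(unname(x)))
  groups <- groups[lengths(groups) >= 2L]
  unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

#' Minimum insertion age of an ortholog group
#'
#' The insertion predates the divergence of the carrier species, so the
#' group's minimum age is the divergence age of the carriers' most recent
#' common ancestor, looked up in a host divergence-age table (the maximum
#' pairwise divergence among carriers). This is a conservative lower
#' bound, not an estimate of the insertion date.
#'
#' @param carrierSpecies character vector (>= 2) of carrier species.
#' @param ageTable data.frame: \code{taxonA}, \code{taxonB}, \code{mean},
#'   \code{lower}, \code{upper} (Ma).
#' @return one-row data.frame: \code{mean}, \code{lower}, \code{upper}.
#' @export
orthologGroupAge <- function(carrierSpecies, ageTable) {
  stopifnot(length(carrierSpecies) >= 2L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tabKey <- key(ageTable$taxonA, ageTable$taxonB)
  pairs <- utils::combn(sort(unique(carrierSpecies)), 2)
  idx <- match(key(pairs[1, ], pairs[2, ]), tabKey)
  if (anyNA(idx))
    stop("age table lacks a divergence for: ",
         paste(pairs[, which(is.na(idx))[1]], collapse = " vs "))
  best <- idx[which.max(ageTable$mean[idx])]
  ageTable[best, c("mean", "lower", "upper")]
}

#' Lognormal calibration prior for a divergence age
#'
#' Builds the smallest-variance lognormal prior whose real-space mean
#' equals the reported mean age and whose central 95\% interval contains
#' the reported bounds: sigma is the smallest scale (found by monotone
#' bisection to |delta sigma| < 1e-8) such that the lognormal with
#' meanlog = ln(mean) - sigma^2/2 has its 2.5\% quantile at or below
#' \code{lower} and its 97.5\% quantile at or above \code{upper}.
#'
#' @param mean reported mean age (Ma).
#' @param lower,upper reported 95\% interval bounds, with
#'   0 < lower < mean < upper.
#' @return a \code{\linkS4class{CalibrationPrior}}.
#' @export
lognormalCalibration <- function(mean, lower, upper) {
  if (!(0 < lower && lower < mean && mean < upper))
    stop("need 0 < lower < mean < upper")
  z <- qnorm(0.975)
  contains <- function(sigma) {
    mu <- log(mean) - sigma^2 / 2
    qlnorm(0.025, mu, sigma) <= lower && qlnorm(0.975, mu, sigma) >= upper
  }
  # containment is monotone in sigma on (0, z]: the 2.5% quantile
  # decreases and the 97.5% quantile increases up to sigma = z
  hi <- z
  if (!contains(hi))
    stop("no lognormal with this mean can contain the interval")
  lo <- 0
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (contains(mid)) hi <- mid else lo <- mid
  }
  sigma <- hi
  new("CalibrationPrior", mean = mean, meanlog = log(mean) - sigma^2 / 2,
      sdlog = sigma, lower = lower, upper = upper)
}
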