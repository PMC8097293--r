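# Rejection ABC for cophylogenetic event probabilities.

# symmetric Dirichlet / Dirichlet-kernel draws on the 4-simplex
.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- rep(1, length(alpha))
  x / sum(x)
}

# Aggregate summary statistics over the surviving lineages of one draw:
# lineage survival count, summed per-tree statistics, overall host-tip
# coverage. `sims` is a list of successful .simCophyloOnce results.
.multiLineageStats <- function(hi, sims, nParasites) {
  per <- vapply(sims, function(s)
    summaryStatistics(hi$tree, s$parasiteTree, s$associations,
                      hostIndex = hi), numeric(7))
  per <- matrix(per, nrow = 7)
  cov <- length(unique(unlist(lapply(sims, function(s)
    s$associations$host)))) / length(hi$tipLabel)
  c(nSurvivingLineages = length(sims),
    nParasiteTips = sum(per[1, ]), nParasiteInternal = sum(per[2, ]),
    cospeciation = sum(per[3, ]), duplication = sum(per[4, ]),
    host_switch = sum(per[5, ]), loss = sum(per[6, ]),
    hostCoverage = cov)
}

#' Summary statistics of an observed multi-lineage system
#'
#' Builds the ABC statistic vector for an observed system of one or more
#' independent parasite lineages on a shared host tree: the number of
#' surviving lineages, the per-lineage statistics of
#' \code{\link{summaryStatistics}} summed over lineages, and the overall
#' fraction of host tips carrying parasites.
#'
#' @param hostTree the host tree.
#' @param lineages either the result of
#'   \code{\link{simulateCophylogeny}} (for one lineage, or its list form
#'   for several), or a list of \code{list(parasiteTree, associations)}.
#' @param nParasites the number of lineages originally seeded (extinct
#'   ones count toward this but contribute no statistics).
#' @return named numeric vector of length 8.
#' @export
observedCophyloStats <- function(hostTree, lineages,
                                 nParasites = length(lineages)) {
  hi <- .hostIndex(hostTree)
  if (!is.null(lineages$parasiteTree) || !is.null(lineages$associations))
    lineages <- list(lineages)
  lineages <- Filter(function(x) !isTRUE(x$failed) &&
                       !is.null(x$associations), lineages)
  if (!length(lineages)) stop("no surviving lineage in the observed data")
  .multiLineageStats(hi, lineages, nParasites)
}

#' Rejection ABC for cophylogenetic event probabilities
#'
#' Infers the probabilities of the four cophylogenetic event classes by
#' multi-round rejection ABC against the event-based simulator
#' (\code{\link{simulateCophylogeny}}): per round, parameter vectors are
#' drawn (round 1: flat Dirichlet over the simplex; later rounds: a
#' Dirichlet kernel centred on draws accepted in the previous round),
#' a parasite system of \code{nParasites} independent lineages is
#' simulated on the host tree for each draw, its summary statistics are
#' compared to the observed ones in normalised Euclidean distance, and
#' the closest \code{tolerance} fraction of draws is accepted. Five
#' rounds at tolerance 0.1 are the canonical settings. Each lineage is
#' simulated once; extinctions are informative (they enter the
#' surviving-lineage count, and a draw with no surviving lineage is
#' rejected outright), so the loss probability is identified rather than
#' masked by resimulation.
#'
#' @param observedStats statistic vector from
#'   \code{\link{observedCophyloStats}} (or
#'   \code{\link{summaryStatistics}} output; it is then padded with a
#'   lineage count of 1).
#' @param hostTree host tree to simulate on.
#' @param nSims simulations per round (>= 100).
#' @param tolerance accepted fraction per round.
#' @param rounds number of rounds.
#' @param seed integer seed (optional).
#' @param nParasites independent parasite lineages per simulated system;
#'   should match the observed system.
#' @param kernelConcentration Dirichlet kernel concentration for rounds
#'   2+.
#' @return an \code{\linkS4class{AbcResult}}.
#' @export
abcRejection <- function(observedStats, hostTree, nSims = 2000L,
                         tolerance = 0.1, rounds = 5L, seed = NULL,
                         nParasites = NULL, kernelConcentration = 100) {
  if (nSims < 100L) stop("nSims must be at least 100")
  hi <- .hostIndex(hostTree)
  if (length(observedStats) == 7L)
    observedStats <- c(nSurvivingLineages = 1, observedStats)
  nParasites <- as.integer(nParasites %||% observedStats[[1]])
  .withSeed(seed, {
    accepted <- NULL
    roundMeans <- matrix(NA_real_, rounds, 4,
                         dimnames = list(NULL, .EVENTS))
    nFail <- 0L; nTotal <- 0L
    for (r in seq_len(rounds)) {
      draws <- matrix(NA_real_, nSims, 4, dimnames = list(NULL, .EVENTS))
      stats <- matrix(NA_real_, nSims, length(observedStats))
      for (i in seq_len(nSims)) {
        p <- if (is.null(accepted)) .rdirichlet(rep(1, 4))
        else {
          centre <- accepted[sample.int(nrow(accepted), 1L), ]
          .rdirichlet(kernelConcentration * centre + 0.05)
        }
        draws[i, ] <- p
        st <- .abcDrawStats(hi, p, nParasites)
        nTotal <- nTotal + 1L
        if (is.null(st)) { nFail <- nFail + 1L; next }
        stats[i, ] <- st
      }
      keepN <- max(1L, floor(tolerance * nSims))
      ok <- !is.na(stats[, 1])
      if (sum(ok) < max(10L, keepN %/% 4L))
        stop("simulator failure rate too high (", round(nFail / nTotal, 2),
             "): too few surviving simulations to select from")
      scale <- apply(stats[ok, , drop = FALSE], 2, sd)
      scale[!is.finite(scale) | scale == 0] <- 1
      d2 <- colSums((t(stats[ok, , drop = FALSE]) - observedStats)^2 /
                    scale^2)
      keep <- which(ok)[order(d2)[seq_len(min(keepN, sum(ok)))]]
      accepted <- draws[keep, , drop = FALSE]
      roundMeans[r, ] <- colMeans(accepted)
    }
    new("AbcResult", accepted = accepted,
        posteriorMean = colMeans(accepted),
        posteriorSD = apply(accepted, 2, sd), roundMeans = roundMeans,
        tolerance = tolerance, rounds = as.integer(rounds),
        nSims = as.integer(nSims), failureRate = nFail / nTotal)
  })
}
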