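# Event-based simulation of parasite evolution along a host tree.

#' Simulate cophylogenetic evolution along a host tree
#'
#' A parasite lineage enters the host tree at the root edge; at every host
#' node it reaches, an event is drawn from the four classes: cospeciation
#' (the lineage splits and follows both host daughters), duplication (two
#' copies that independently continue at the same node), host switch (one
#' copy continues, the other jumps to a host edge alive at that time and
#' continues there), or loss (the lineage dies). Lineages reaching host
#' tips become parasite tips associated with that host. Simulations where
#' fewer than one lineage survives (or a lineage-count cap is exceeded)
#' are retried up to \code{maxRetries}; the complete draw log across all
#' attempts is returned so event frequencies can be audited without
#' survivorship bias.
#'
#' @param hostTree rooted binary \code{phylo} with branch lengths (unit
#'   lengths are assumed when absent).
#' @param params event probabilities (cospeciation, duplication,
#'   host_switch, loss) summing to 1; see
#'   \code{\link{eventProbabilities}}.
#' @param nParasites number of independent starting lineages (each yields
#'   an independent replicate; default 1).
#' @param seed integer seed (optional).
#' @param maxRetries retry cap before reporting failure.
#' @param maxLineages cap on simultaneously alive lineages.
#' @return for \code{nParasites = 1} a list: \code{parasiteTree}
#'   (\code{phylo}, or NULL when a single lineage survived),
#'   \code{associations} (data.frame \code{parasite}, \code{host}),
#'   \code{eventLog} (draws of the successful attempt: \code{event},
#'   \code{hostEdge}), \code{allDraws} (draws across every attempt, with
#'   \code{attempt}), \code{attempts}, \code{failed} (TRUE when all
#'   retries went extinct). For \code{nParasites > 1}, a list of such
#'   lists.
#' @export
simulateCophylogeny <- function(hostTree, params, nParasites = 1L,
                                seed = NULL, maxRetries = 100L,
                                maxLineages = 200L) {
  params <- eventProbabilities(params)
  hi <- .hostIndex(hostTree)
  .withSeed(seed, {
    if (nParasites > 1L)
      return(lapply(seq_len(nParasites), function(i)
        .simCophyloOnce(hi, params, maxRetries, maxLineages)))
    .simCophyloOnce(hi, params, maxRetries, maxLineages)
  })
}

.simCophyloOnce <- function(hi, params, maxRetries, maxLineages) {
  allEv <- integer(0); allEdge <- integer(0); allAttempt <- integer(0)
  for (attempt in seq_len(maxRetries)) {
    env <- new.env(parent = emptyenv())
    env$ev <- integer(64); env$edge <- integer(64); env$n <- 0L
    env$log <- TRUE
    env$nAlive <- 1L
    env$overflow <- FALSE
    env$maxLineages <- maxLineages
    res <- .simLineage(hi, params, hi$rootEdge, env)
    if (env$n) {
      allEv <- c(allEv, env$ev[seq_len(env$n)])
      allEdge <- c(allEdge, env$edge[seq_len(env$n)])
      allAttempt <- c(allAttempt, rep(attempt, env$n))
    }
    if (env$overflow || is.null(res)) next
    out <- .lineageToTree(res, hi)
    return(list(parasiteTree = out$tree, associations = out$associations,
                eventLog = data.frame(
                  event = .EVENTS[env$ev[seq_len(env$n)]],
                  hostEdge = env$edge[seq_len(env$n)]),
                allDraws = data.frame(event = .EVENTS[allEv],
                                      hostEdge = allEdge,
                                      attempt = allAttempt),
                attempts = attempt, failed = FALSE))
  }
  list(parasiteTree = NULL, associations = NULL, eventLog = NULL,
       allDraws = data.frame(event = .EVENTS[allEv], hostEdge = allEdge,
                             attempt = allAttempt),
       attempts = maxRetries, failed = TRUE)
}

# recursive lineage simulation; returns a nested list (tip: host tip id;
# children: two subtrees) or NULL on loss/extinction
.simLineage <- function(hi, params, e, env) {
  if (env$overflow) return(NULL)
  if (hi$pendant[e])
    return(list(tip = hi$child[e]))
  draw <- sample.int(4L, 1L, prob = params)
  if (env$log) {
    env$n <- env$n + 1L
    if (env$n > length(env$ev)) {
      length(env$ev) <- 2L * length(env$ev)
      length(env$edge) <- 2L * length(env$edge)
    }
    env$ev[env$n] <- draw
    env$edge[env$n] <- e
  }
  if (draw == 4L) {                         # loss
    env$nAlive <- env$nAlive - 1L
    return(NULL)
  }
  env$nAlive <- env$nAlive + 1L
  if (env$nAlive > env$maxLineages) {
    env$overflow <- TRUE
    return(NULL)
  }
  if (draw == 1L) {                         # cospeciation
    ds <- hi$daughters[[e]]
    a <- .simLineage(hi, params, ds[1], env)
    b <- .simLineage(hi, params, ds[2], env)
  } else if (draw == 2L) {                  # duplication
    a <- .simLineage(hi, params, e, env)
    b <- .simLineage(hi, params, e, env)
  } else {                                  # host switch
    tEvent <- hi$tBottom[e] - 1e-9
    alive <- which(hi$tTop < tEvent & hi$tBottom > tEvent)
    alive <- alive[alive != e]
    a <- .simLineage(hi, params, e, env)
    b <- if (length(alive))
      .simLineage(hi, params, alive[sample.int(length(alive), 1L)], env)
    else NULL
  }
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(children = list(a, b))
}

# Minimal simulate-and-summarise path for the ABC inner loop: simulates
# nParasites lineages (one attempt each, no logging) and returns the
# aggregated statistic vector, or NULL when no lineage survives.
.abcDrawStats <- function(hi, params, nParasites, maxLineages = 200L) {
  E <- hi$E
  totTips <- 0L; totInternal <- 0L
  counts <- c(0, 0, 0, 0)
  hostCovered <- logical(length(hi$tipLabel))
  nSurv <- 0L
  unitCosts <- c(1, 1, 1, 1)
  for (k in seq_len(nParasites)) {
    env <- new.env(parent = emptyenv())
    env$log <- FALSE
    env$nAlive <- 1L
    env$overflow <- FALSE
    env$maxLineages <- maxLineages
    res <- .simLineage(hi, params, hi$rootEdge, env)
    if (env$overflow || is.null(res)) next
    flat <- .flattenLineage(res)
    nSurv <- nSurv + 1L
    hostCovered[flat$hostTips] <- TRUE
    nTip <- length(flat$hostTips)
    totTips <- totTips + nTip
    if (nTip < 2L) next
    totInternal <- totInternal + nTip - 1L
    cnt <- cpp_reconcile_counts(E, hi$cpp$pendant, hi$cpp$daughters,
                                hi$cpp$descPtr, hi$cpp$descIdx,
                                hi$cpp$descSteps, hi$allowedSwitch,
                                nTip, 2L * nTip - 1L, flat$kids,
                                hi$tipEdge[flat$hostTips] - 1L,
                                unitCosts)
    if (!is.na(cnt[1])) counts <- counts + cnt[2:5]
  }
  if (!nSurv) return(NULL)
  c(nSurv, totTips, totInternal, counts,
    sum(hostCovered) / length(hostCovered))
}

# flatten a nested lineage into 0-based postorder kids rows + host tip
# indices (ape numbering: tips 1..n, internal n+1.., root = n+1)
.flattenLineage <- function(res) {
  env <- new.env(parent = emptyenv())
  env$hostTips <- integer(0)
  cnt <- function(x) if (!is.null(x$tip)) 1L
                     else cnt(x$children[[1]]) + cnt(x$children[[2]])
  nTip <- cnt(res)
  if (nTip < 2L) {
    return(list(hostTips = res$tip, kids = NULL))
  }
  env$tipCount <- 0L
  env$nodeCount <- nTip
  env$hostTips <- integer(nTip)
  env$kids <- matrix(0L, nTip - 1L, 3L)
  env$kidRow <- 0L
  build <- function(x) {
    if (!is.null(x$tip)) {
      env$tipCount <- env$tipCount + 1L
      env$hostTips[env$tipCount] <- x$tip
      return(env$tipCount)
    }
    env$nodeCount <- env$nodeCount + 1L
    id <- env$nodeCount
    a <- build(x$children[[1]])
    b <- build(x$children[[2]])
    env$kidRow <- env$kidRow + 1L
    env$kids[env$kidRow, ] <- c(id, a, b)
    id
  }
  build(res)
  list(hostTips = env$hostTips, kids = env$kids - 1L)
}

# convert the nested lineage structure into an ape tree + associations
.lineageToTree <- function(res, hi) {
  count <- function(x) if (!is.null(x$tip)) 1L
                       else count(x$children[[1]]) + count(x$children[[2]])
  nTip <- count(res)
  if (nTip < 2L) {
    hostTip <- hi$tipLabel[res$tip]
    return(list(tree = NULL,
                associations = data.frame(parasite = "P1", host = hostTip,
                                          stringsAsFactors = FALSE)))
  }
  env <- new.env(parent = emptyenv())
  env$edge <- matrix(0L, 2L * nTip - 2L, 2L)
  env$nEdge <- 0L
  env$tipCount <- 0L
  env$nodeCount <- nTip
  env$assoc <- character(nTip)
  build <- function(x) {
    if (!is.null(x$tip)) {
      env$tipCount <- env$tipCount + 1L
      env$assoc[env$tipCount] <- hi$tipLabel[x$tip]
      return(env$tipCount)
    }
    env$nodeCount <- env$nodeCount + 1L
    id <- env$nodeCount
    a <- build(x$children[[1]])
    b <- build(x$children[[2]])
    env$edge[env$nEdge + 1L, ] <- c(id, a)
    env$edge[env$nEdge + 2L, ] <- c(id, b)
    env$nEdge <- env$nEdge + 2L
    id
  }
  build(res)
  tree <- list(edge = env$edge, Nnode = env$nodeCount - nTip,
               tip.label = paste0("P", seq_len(nTip)))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  list(tree = tree,
       associations = data.frame(
         parasite = paste0("P", seq_len(nTip)),
         host = env$assoc, stringsAsFactors = FALSE))
}
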