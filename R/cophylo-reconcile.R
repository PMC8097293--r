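# Event-based host/parasite reconciliation: cost transform, host-tree
# indexing, the dynamic program over (parasite node x host edge), and
# switch-branch labelling.

.EVENTS <- c("cospeciation", "duplication", "host_switch", "loss")

#' Validate cophylogenetic event probabilities
#'
#' @param p numeric length-4 (cospeciation, duplication, host_switch,
#'   loss); each in [0, 1], summing to 1 within 1e-12 (after naming).
#' @return the named, validated probability vector.
#' @export
eventProbabilities <- function(p) {
  if (length(p) != 4L) stop("need four event probabilities")
  if (is.null(names(p))) names(p) <- .EVENTS
  p <- p[.EVENTS]
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("event probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop("event probabilities must sum to 1 (within 1e-12)")
  p
}

#' Transform event probabilities into reconciliation costs
#'
#' cost_i = -ln(p_i) for each event class; a zero-probability event gets
#' infinite cost (the event is disallowed).
#'
#' @param p event probabilities (see \code{\link{eventProbabilities}}).
#' @return named numeric cost vector.
#' @export
probsToCosts <- function(p) {
  p <- eventProbabilities(p)
  costs <- ifelse(p > 0, -log(p), Inf)
  names(costs) <- names(p)
  costs
}

# Index a rooted binary host tree for reconciliation: edges are the tree
# edges plus a root edge (id nEdge + 1) above the root node. For each
# edge: bottom node, pendant flag, daughters, descendant edge sets with
# loss steps, time span, and allowed switch targets (time-overlapping,
# neither ancestor nor descendant).
.hostIndex <- function(host) {
  stopifnot(inherits(host, "phylo"))
  if (!ape::is.binary(host)) stop("host tree must be binary")
  nTip <- length(host$tip.label)
  nEdge <- nrow(host$edge)
  rootNode <- nTip + 1L
  E <- nEdge + 1L                       # + root edge
  child <- c(host$edge[, 2], rootNode)
  parentEdge <- integer(E)
  daughters <- vector("list", E)
  for (e in seq_len(nEdge)) {
    kids <- which(host$edge[, 1] == child[e])
    daughters[[e]] <- kids
  }
  daughters[[E]] <- which(host$edge[, 1] == rootNode)
  for (e in seq_len(E)) for (d in daughters[[e]]) parentEdge[d] <- e
  pendant <- child <= nTip
  pendant[E] <- FALSE
  # depths in edge counts (levels) and in time
  len <- host$edge.length %||% rep(1, nEdge)
  level <- integer(E); tTop <- numeric(E); tBottom <- numeric(E)
  level[E] <- 0L
  tTop[E] <- -1e-6; tBottom[E] <- 0
  order <- E
  queue <- daughters[[E]]
  while (length(queue)) {
    e <- queue[1]; queue <- queue[-1]
    p <- parentEdge[e]
    level[e] <- level[p] + 1L
    tTop[e] <- tBottom[p]
    tBottom[e] <- tTop[e] + len[e]
    order <- c(order, e)
    queue <- c(queue, daughters[[e]])
  }
  # descendant edge lists (inclusive) with loss steps
  descList <- vector("list", E)
  stepsList <- vector("list", E)
  for (e in rev(order)) {
    dl <- e; st <- 0L
    for (d in daughters[[e]]) {
      dl <- c(dl, descList[[d]])
      st <- c(st, stepsList[[d]] + 1L)
    }
    descList[[e]] <- dl
    stepsList[[e]] <- st
  }
  isDesc <- matrix(FALSE, E, E)
  for (e in seq_len(E)) isDesc[e, descList[[e]]] <- TRUE
  overlap <- outer(tTop, tBottom, `<`) & t(outer(tTop, tBottom, `<`))
  allowedSwitch <- overlap & !isDesc & !t(isDesc)
  diag(allowedSwitch) <- FALSE
  tipEdge <- integer(nTip)
  for (e in seq_len(nEdge)) if (pendant[e]) tipEdge[child[e]] <- e
  # flattened 0-based tables for the C++ counts-only DP
  daughtersMat <- matrix(-1L, E, 2)
  for (e in seq_len(E)) if (length(daughters[[e]]) == 2L)
    daughtersMat[e, ] <- daughters[[e]] - 1L
  descPtr <- c(0L, cumsum(lengths(descList)))
  list(tree = host, nTip = nTip, E = E, rootEdge = E, child = child,
       daughters = daughters, pendant = pendant, level = level,
       tTop = tTop, tBottom = tBottom, descList = descList,
       stepsList = stepsList, isDesc = isDesc,
       allowedSwitch = allowedSwitch, tipEdge = tipEdge,
       tipLabel = host$tip.label,
       cpp = list(pendant = as.integer(pendant),
                  daughters = daughtersMat, descPtr = descPtr,
                  descIdx = unlist(descList) - 1L,
                  descSteps = as.integer(unlist(stepsList))))
}

# counts-only reconciliation through the C++ DP (same model and
# tie-breaks as reconcile(); agreement is tested). Returns named counts
# with attribute "totalCost", or NULL when infeasible.
.reconcileCountsFast <- function(hi, parasite, associations, costs) {
  nTip <- length(parasite$tip.label)
  nNode <- nTip + parasite$Nnode
  edge <- parasite$edge
  kidsA <- integer(nNode); kidsB <- integer(nNode)
  seen <- logical(nNode)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    if (!seen[p]) { kidsA[p] <- edge[k, 2]; seen[p] <- TRUE }
    else kidsB[p] <- edge[k, 2]
  }
  # postorder over internal nodes
  post <- integer(0)
  stack <- nTip + 1L
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    for (k in c(kidsA[v], kidsB[v]))
      if (k > nTip) stack <- c(stack, k)
  }
  post <- rev(out)
  kids <- cbind(post, kidsA[post], kidsB[post]) - 1L
  assocEdge <- hi$tipEdge[match(
    associations$host[match(parasite$tip.label, associations$parasite)],
    hi$tipLabel)]
  if (anyNA(assocEdge)) stop("unassociated or unknown parasite tip")
  res <- cpp_reconcile_counts(hi$E, hi$cpp$pendant, hi$cpp$daughters,
                              hi$cpp$descPtr, hi$cpp$descIdx,
                              hi$cpp$descSteps, hi$allowedSwitch,
                              nTip, nNode, kids, assocEdge - 1L,
                              as.numeric(costs[.EVENTS]))
  if (is.na(res[1])) return(NULL)
  structure(setNames(res[2:5], .EVENTS), totalCost = res[1])
}

# parasite tree postorder tables
.parasiteIndex <- function(parasite) {
  stopifnot(inherits(parasite, "phylo"))
  if (!ape::is.binary(parasite)) stop("parasite tree must be binary")
  nTip <- length(parasite$tip.label)
  nNode <- nTip + parasite$Nnode
  kids <- vector("list", nNode)
  for (e in seq_len(nrow(parasite$edge)))
    kids[[parasite$edge[e, 1]]] <-
      c(kids[[parasite$edge[e, 1]]], parasite$edge[e, 2])
  post <- integer(0)
  visit <- function(v) {
    for (k in kids[[v]]) visit(k)
    post <<- c(post, v)
  }
  root <- nTip + 1L
  visit(root)
  list(tree = parasite, nTip = nTip, nNode = nNode, kids = kids,
       post = post, root = root, tipLabel = parasite$tip.label)
}

#' Most parsimonious host/parasite reconciliation
#'
#' Computes the minimum-cost reconciliation of a parasite tree with a host
#' tree by dynamic programming over (parasite node x host edge), with the
#' four event classes cospeciation, duplication, host switch and loss, all
#' carrying their own cost (typically -ln of the inferred event
#' probabilities). Host switches are restricted to host edges that can be
#' contemporaneous with the source edge under the host node time order.
#' Ties are broken toward fewer switches, then the lexicographically
#' smallest host edge id. The backtracked event multiset is replayed
#' against the total cost (validity of the returned object).
#'
#' @param host,parasite rooted binary \code{phylo} trees.
#' @param associations data.frame with columns \code{parasite},
#'   \code{host} mapping every parasite tip to a host tip.
#' @param costs named cost vector (see \code{\link{probsToCosts}}).
#' @return a \code{\linkS4class{Reconciliation}}.
#' @export
reconcile <- function(host, parasite, associations, costs) {
  hi <- .hostIndex(host)
  pi_ <- .parasiteIndex(parasite)
  stopifnot(all(.EVENTS %in% names(costs)))
  cCo <- costs[["cospeciation"]]; cDu <- costs[["duplication"]]
  cSwTrue <- costs[["host_switch"]]; cLo <- costs[["loss"]]
  # tiny penalty on switches implements the "fewer switches" tie-break
  # inside the DP; the reported total is replayed with the true costs
  tieEps <- 1e-9 * (1 + max(0, costs[is.finite(costs)]))
  cSw <- cSwTrue + tieEps
  E <- hi$E
  assoc <- setNames(match(associations$host, hi$tipLabel),
                    associations$parasite)
  if (anyNA(assoc)) stop("association names an unknown host tip")
  tipHostEdge <- assoc[pi_$tipLabel]
  if (anyNA(tipHostEdge))
    stop("unassociated parasite tip: ",
         paste(pi_$tipLabel[is.na(tipHostEdge)], collapse = ", "))

  C <- matrix(Inf, pi_$nNode, E)
  INC <- matrix(Inf, pi_$nNode, E)
  computeInc <- function(p) {
    v <- C[p, ]
    inc <- numeric(E)
    for (e in seq_len(E))
      inc[e] <- min(v[hi$descList[[e]]] + cLo * hi$stepsList[[e]])
    inc
  }
  for (v in pi_$post) {
    if (v <= pi_$nTip) {
      C[v, hi$tipEdge[tipHostEdge[v]]] <- 0
      INC[v, ] <- computeInc(v)
      next
    }
    a <- pi_$kids[[v]][1]; b <- pi_$kids[[v]][2]
    incA <- INC[a, ]; incB <- INC[b, ]
    # best switch-in values per source edge
    swA <- vapply(seq_len(E), function(e) {
      t <- incA[hi$allowedSwitch[e, ]]
      if (length(t)) min(t) else Inf
    }, numeric(1))
    swB <- vapply(seq_len(E), function(e) {
      t <- incB[hi$allowedSwitch[e, ]]
      if (length(t)) min(t) else Inf
    }, numeric(1))
    for (e in seq_len(E)) {
      cand <- Inf
      if (!hi$pendant[e] && length(hi$daughters[[e]]) == 2L) {
        d1 <- hi$daughters[[e]][1]; d2 <- hi$daughters[[e]][2]
        cand <- min(cand, cCo + min(incA[d1] + incB[d2],
                                    incA[d2] + incB[d1]))
      }
      cand <- min(cand, cDu + incA[e] + incB[e])
      cand <- min(cand, cSw + min(incA[e] + swB[e], incB[e] + swA[e]))
      C[v, e] <- cand
    }
    INC[v, ] <- computeInc(v)
  }
  total <- min(C[pi_$root, ])
  if (!is.finite(total))
    return(new("Reconciliation",
               mapping = data.frame(pnode = integer(0),
                                    hostEdge = integer(0),
                                    event = character(0)),
               eventCounts = setNames(rep(0, 4), .EVENTS),
               totalCost = Inf, costs = costs, switchEdges = integer(0)))

  # -------- backtracking (ties: non-switch first, then lowest edge id) ----
  counts <- setNames(rep(0, 4), .EVENTS)
  mapRows <- list()
  switchNodes <- integer(0)
  eps <- 1e-9
  resolveInc <- function(p, e) {
    # choose the landing edge f below e realising INC[p, e]
    dl <- hi$descList[[e]]; st <- hi$stepsList[[e]]
    vals <- C[p, dl] + cLo * st
    k <- which(vals <= min(vals) + eps)
    k <- k[order(st[k], dl[k])][1]      # fewest losses, lowest edge id
    list(edge = dl[k], losses = st[k])
  }
  assignNode <- function(v, e) {
    if (v <= pi_$nTip) {
      mapRows[[length(mapRows) + 1L]] <<- data.frame(
        pnode = v, hostEdge = e, event = "tip")
      return(invisible(NULL))
    }
    a <- pi_$kids[[v]][1]; b <- pi_$kids[[v]][2]
    val <- C[v, e]
    # try cospeciation
    if (!hi$pendant[e] && length(hi$daughters[[e]]) == 2L) {
      d1 <- hi$daughters[[e]][1]; d2 <- hi$daughters[[e]][2]
      for (ord in list(c(d1, d2), c(d2, d1))) {
        if (cCo + INC[a, ord[1]] + INC[b, ord[2]] <= val + eps) {
          counts[["cospeciation"]] <<- counts[["cospeciation"]] + 1
          mapRows[[length(mapRows) + 1L]] <<- data.frame(
            pnode = v, hostEdge = e, event = "cospeciation")
          ra <- resolveInc(a, ord[1]); rb <- resolveInc(b, ord[2])
          counts[["loss"]] <<- counts[["loss"]] + ra$losses + rb$losses
          assignNode(a, ra$edge); assignNode(b, rb$edge)
          return(invisible(NULL))
        }
      }
    }
    # duplication
    if (cDu + INC[a, e] + INC[b, e] <= val + eps) {
      counts[["duplication"]] <<- counts[["duplication"]] + 1
      mapRows[[length(mapRows) + 1L]] <<- data.frame(
        pnode = v, hostEdge = e, event = "duplication")
      ra <- resolveInc(a, e); rb <- resolveInc(b, e)
      counts[["loss"]] <<- counts[["loss"]] + ra$losses + rb$losses
      assignNode(a, ra$edge); assignNode(b, rb$edge)
      return(invisible(NULL))
    }
    # host switch: one child stays, the other jumps
    targets <- which(hi$allowedSwitch[e, ])
    targets <- targets[order(targets)]
    for (stay in list(list(s = a, m = b), list(s = b, m = a))) {
      for (f in targets) {
        if (cSw + INC[stay$s, e] + INC[stay$m, f] <= val + eps) {
          counts[["host_switch"]] <<- counts[["host_switch"]] + 1
          mapRows[[length(mapRows) + 1L]] <<- data.frame(
            pnode = v, hostEdge = e, event = "host_switch")
          switchNodes <<- c(switchNodes, stay$m)
          rs <- resolveInc(stay$s, e); rm <- resolveInc(stay$m, f)
          counts[["loss"]] <<- counts[["loss"]] + rs$losses + rm$losses
          assignNode(stay$s, rs$edge); assignNode(stay$m, rm$edge)
          return(invisible(NULL))
        }
      }
    }
    stop("internal error: backtracking failed at parasite node ", v)
  }
  rootChoices <- which(C[pi_$root, ] <= total + eps)
  assignNode(pi_$root, rootChoices[1])
  mapping <- do.call(rbind, mapRows)
  # parasite edges leading to nodes reached via a switch
  pedge <- pi_$tree$edge
  switchEdges <- which(pedge[, 2] %in% switchNodes)
  trueCosts <- costs
  pos <- counts[counts > 0]
  totalTrue <- sum(pos * trueCosts[names(pos)])
  new("Reconciliation", mapping = mapping, eventCounts = counts,
      totalCost = totalTrue, costs = trueCosts,
      switchEdges = as.integer(switchEdges))
}

#' Label parasite branches involved in host switches
#'
#' Produces the branch-class map used by the switch/no-switch codon model:
#' each parasite-tree edge is labelled "switch" when the reconciliation
#' places a host-switch event on it (the branch leading to the lineage
#' that jumped), otherwise "no_switch".
#'
#' @param reconciliation a \code{\linkS4class{Reconciliation}} computed on
#'   \code{parasite}.
#' @param parasite the parasite tree the reconciliation refers to.
#' @return character vector along \code{parasite$edge} rows.
#' @export
labelSwitchBranches <- function(reconciliation, parasite) {
  stopifnot(is(reconciliation, "Reconciliation"),
            inherits(parasite, "phylo"))
  if (length(reconciliation@switchEdges) &&
      max(reconciliation@switchEdges) > nrow(parasite$edge))
    stop("reconciliation does not match this parasite tree")
  if (nrow(reconciliation@mapping) &&
      max(reconciliation@mapping$pnode) >
        length(parasite$tip.label) + parasite$Nnode)
    stop("reconciliation does not match this parasite tree")
  labels <- rep("no_switch", nrow(parasite$edge))
  labels[reconciliation@switchEdges] <- "switch"
  labels
}

#' Summary statistics for ABC on cophylogenetic data
#'
#' The statistic vector compared between observed and simulated
#' host/parasite systems: parasite tip count, parasite internal node
#' count, the four event counts of a unit-cost reconciliation, and the
#' fraction of host tips carrying at least one associated parasite tip.
#' The vector is invariant to tip input order.
#'
#' @param host,parasite rooted binary trees.
#' @param associations data.frame (\code{parasite}, \code{host}); every
#'   parasite tip must be associated.
#' @param hostIndex optional prepared host index (internal; lets repeated
#'   calls on the same host skip re-indexing).
#' @return named numeric vector of length 7.
#' @export
summaryStatistics <- function(host, parasite, associations,
                              hostIndex = NULL) {
  if (is.null(parasite) || length(parasite$tip.label) < 2L) {
    # degenerate single-lineage outcome: no tree, no events
    tips <- if (is.null(parasite)) unique(associations$parasite)
            else parasite$tip.label
    return(c(nParasiteTips = length(tips), nParasiteInternal = 0,
             cospeciation = 0, duplication = 0, host_switch = 0, loss = 0,
             hostCoverage = length(unique(
               associations$host[associations$parasite %in% tips])) /
               length(host$tip.label)))
  }
  if (!all(parasite$tip.label %in% associations$parasite))
    stop("unassociated parasite tip")
  unitCosts <- setNames(rep(1, 4), .EVENTS)
  hi <- hostIndex %||% .hostIndex(host)
  cnt <- .reconcileCountsFast(hi, parasite, associations, unitCosts)
  if (is.null(cnt)) stop("reconciliation infeasible")
  c(nParasiteTips = length(parasite$tip.label),
    nParasiteInternal = parasite$Nnode,
    cospeciation = cnt[["cospeciation"]],
    duplication = cnt[["duplication"]],
    host_switch = cnt[["host_switch"]], loss = cnt[["loss"]],
    hostCoverage = length(unique(
      associations$host[associations$parasite %in% parasite$tip.label])) /
      length(host$tip.label))
}
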