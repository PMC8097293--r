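# Maximum-likelihood fitting of codon branch models, LRT and AIC.

#' Branch-class maps for the standard branch models
#'
#' Builds the edge-class vector for the model family: "one" (a single
#' class), "internal_terminal" (class 1 = internal edges, class 2 =
#' pendant/terminal edges, defined on the unrooted tree), or "custom"
#' from explicit labels.
#'
#' @param tree a \code{phylo} tree.
#' @param type "one", "internal_terminal" or "custom".
#' @param labels for "custom": character/integer vector per edge; unique
#'   values become classes in sorted order.
#' @return integer vector per \code{tree$edge} row, with a
#'   \code{"classNames"} attribute.
#' @export
branchClassMap <- function(tree, type = c("one", "internal_terminal",
                                          "custom"), labels = NULL) {
  type <- match.arg(type)
  nEdge <- nrow(tree$edge)
  nTip <- length(tree$tip.label)
  if (type == "one")
    return(structure(rep(1L, nEdge), classNames = "all"))
  if (type == "internal_terminal") {
    terminal <- tree$edge[, 2] <= nTip
    return(structure(ifelse(terminal, 2L, 1L),
                     classNames = c("internal", "terminal")))
  }
  stopifnot(length(labels) == nEdge)
  lev <- sort(unique(as.character(labels)))
  structure(match(as.character(labels), lev), classNames = lev)
}

# initial branch lengths from pairwise codon p-distances (very rough;
# star-like split of the mean distance)
.initBranchLengths <- function(idx, tree) {
  nEdge <- nrow(tree$edge)
  nTip <- length(tree$tip.label)
  ps <- c()
  rows <- seq_len(nrow(idx))
  if (nrow(idx) >= 2) {
    for (i in 1:(nrow(idx) - 1)) for (j in (i + 1):nrow(idx)) {
      keep <- idx[i, ] >= 0 & idx[j, ] >= 0
      if (any(keep)) ps <- c(ps, mean(idx[i, keep] != idx[j, keep]))
    }
  }
  p <- mean(ps)
  if (!is.finite(p) || p <= 0) p <- 0.05
  d <- -log(1 - min(p, 0.95))          # Poisson-corrected codon distance
  rep(max(d / 2, 1e-4), nEdge)
}

#' Carry per-edge labels through unrooting
#'
#' Unroots a rooted binary tree and transfers edge labels: edges are
#' matched by the tip bipartition they induce; the two root edges merge
#' into one, which is labelled "switch" when either of them was (other
#' ties keep the first label).
#'
#' @param tree rooted binary \code{phylo}.
#' @param labels character vector per \code{tree$edge} row.
#' @return list: \code{tree} (unrooted) and \code{labels} (per unrooted
#'   edge).
#' @export
unrootWithLabels <- function(tree, labels) {
  stopifnot(length(labels) == nrow(tree$edge))
  if (!ape::is.rooted(tree)) return(list(tree = tree, labels = labels))
  u <- ape::unroot(tree)
  splitKeys <- function(tr) {
    nTip <- length(tr$tip.label)
    below <- vector("list", nTip + tr$Nnode)
    for (i in seq_len(nTip)) below[[i]] <- tr$tip.label[i]
    edgeOrd <- ape::reorder.phylo(tr, "postorder")$edge
    for (k in seq_len(nrow(edgeOrd)))
      below[[edgeOrd[k, 1]]] <- c(below[[edgeOrd[k, 1]]],
                                  below[[edgeOrd[k, 2]]])
    vapply(seq_len(nrow(tr$edge)), function(e) {
      side <- sort(unique(below[[tr$edge[e, 2]]]))
      other <- sort(setdiff(tr$tip.label, side))
      min(paste(side, collapse = ","), paste(other, collapse = ","))
    }, character(1))
  }
  keyR <- splitKeys(tree)
  keyU <- splitKeys(u)
  newLabels <- vapply(keyU, function(k) {
    src <- labels[keyR == k]
    if ("switch" %in% src) "switch" else src[1]
  }, character(1), USE.NAMES = FALSE)
  list(tree = u, labels = newLabels)
}

#' Fit a codon branch model by maximum likelihood
#'
#' Fits one of the branch models used for selection analysis on
#' elements: \code{neutral_w1} (single ratio fixed at omega = 1),
#' \code{one_ratio} (single estimated omega), \code{internal_terminal}
#' (two ratios: internal vs terminal branches) or \code{switch_noswitch}
#' (two ratios from a host-switch branch labelling, see
#' \code{\link{labelSwitchBranches}}). Parameters (omega per class, kappa
#' and all branch lengths) are optimised by bounded quasi-Newton
#' (L-BFGS-B on log scale) with multiple starts; trees are treated as
#' unrooted (the likelihood is invariant to the root position under this
#' reversible model).
#'
#' @param alignment codon character matrix (rows = tree tips).
#' @param tree \code{phylo}; fitting uses its unrooted topology.
#' @param model model name (above).
#' @param branchClass required for "switch_noswitch" (or any custom
#'   2-class map): integer/character labels per edge of the tree passed
#'   in. Ignored for the other models.
#' @param pi codon frequencies: "uniform", "F1x4", "F61" or a length-61
#'   vector.
#' @param kappaStart,omegaStart optional starting values.
#' @param nStarts number of optimisation starts (default 3).
#' @param control passed to \code{optim} (factr default tightens
#'   convergence to ~1e-6 lnL units).
#' @return a \code{\linkS4class{CodonFit}}.
#' @export
fitBranchModel <- function(alignment, tree,
                           model = c("one_ratio", "neutral_w1",
                                     "internal_terminal",
                                     "switch_noswitch"),
                           branchClass = NULL, pi = "uniform",
                           kappaStart = 2, omegaStart = NULL,
                           nStarts = 3L, control = list()) {
  model <- match.arg(model)
  idx <- if (is.character(alignment)) .codonIndices(alignment) else alignment
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    if (!is.null(branchClass)) {
      ul <- unrootWithLabels(tree, as.character(branchClass))
      tree <- ul$tree
      branchClass <- ul$labels
    } else tree <- ape::unroot(tree)
  }
  nEdge <- nrow(tree$edge)
  cls <- switch(model,
    neutral_w1 = branchClassMap(tree, "one"),
    one_ratio = branchClassMap(tree, "one"),
    internal_terminal = branchClassMap(tree, "internal_terminal"),
    switch_noswitch = {
      if (is.null(branchClass))
        stop("switch_noswitch needs a branchClass labelling")
      branchClassMap(tree, "custom", labels = branchClass)
    })
  nClass <- length(unique(cls))
  classNames <- attr(cls, "classNames")
  fixedOmega <- model == "neutral_w1"
  tab <- .codonTable()
  piVec <- if (is.numeric(pi)) pi
           else codonFrequencies(if (is.character(alignment)) alignment
                                 else matrix(tab$codons[idx + 1L],
                                             nrow = nrow(idx)),
                                 method = if (pi == "uniform") "uniform"
                                          else pi)

  sp <- .sitePatterns(idx[tree$tip.label, , drop = FALSE])
  pt <- .pruningTables(tree, tree$tip.label)
  perm <- match(paste(pt$tree$edge[, 1], pt$tree$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  clsPerm <- as.integer(cls[perm]) - 1L
  nbr <- tab$nbr
  trace <- numeric(0)
  lnLfun <- function(kappa, omega, t) {
    val <- cpp_codon_lnL(pt$edge, nrow(sp$patterns), sp$patterns,
                         sp$weights, piVec, kappa, omega, clsPerm,
                         t[perm], nbr[, 1L] - 1L, nbr[, 2L] - 1L,
                         nbr[, 3L], nbr[, 4L])
    prev <- if (length(trace)) trace[length(trace)] else -Inf
    trace <<- c(trace, max(val, prev))
    val
  }

  t0 <- .initBranchLengths(idx, tree)
  if (!is.null(tree$edge.length) && all(tree$edge.length > 0))
    t0 <- pmax(tree$edge.length, 1e-5)
  om0 <- omegaStart %||% {
    est <- .quickOmega(idx)
    rep(max(min(est, 50), 1e-4), nClass)
  }
  if (length(om0) == 1L) om0 <- rep(om0, nClass)

  obj <- function(par) {
    kappa <- exp(par[1])
    omega <- if (fixedOmega) rep(1, nClass) else exp(par[2:(1 + nClass)])
    t <- exp(par[(if (fixedOmega) 2L else 2L + nClass):length(par)])
    -lnLfun(kappa, omega, t)
  }
  lb <- c(log(0.05), if (!fixedOmega) rep(log(1e-6), nClass),
          rep(log(1e-7), nEdge))
  ub <- c(log(100), if (!fixedOmega) rep(log(100), nClass),
          rep(log(20), nEdge))
  makeStart <- function(i) {
    if (i == 2L)   # neutral point: guarantees nesting above neutral_w1
      return(c(log(2), if (!fixedOmega) rep(0, nClass),
               log(pmin(pmax(t0, 1e-6), 19))))
    jitter <- if (i == 1L) 1 else exp(runif(1, -1, 1))
    c(log(kappaStart * jitter),
      if (!fixedOmega) log(pmin(pmax(om0 * jitter^2, 1e-5), 90)),
      log(pmin(pmax(t0 * jitter, 1e-6), 19)))
  }
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  best <- NULL
  for (i in seq_len(nStarts)) {
    fit <- tryCatch(
      optim(makeStart(i), obj, method = "L-BFGS-B", lower = lb,
            upper = ub, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimisation failed from every start")
  par <- best$par
  kappa <- exp(par[1])
  omega <- if (fixedOmega) setNames(rep(1, nClass), classNames)
           else setNames(exp(par[2:(1 + nClass)]), classNames)
  t <- exp(par[(if (fixedOmega) 2L else 2L + nClass):length(par)])
  new("CodonFit", model = model, lnL = -best$value, omega = omega,
      kappa = kappa, branchLengths = t, np = as.integer(length(par)),
      convergence = best$convergence == 0L, trace = trace)
}

# counting-style omega estimate from pairwise comparisons of codons
# differing at one position (cheap initialisation only)
.quickOmega <- function(idx) {
  tab <- .codonTable()
  nbr <- tab$nbr
  key <- nbr[, "i"] * 62L + nbr[, "j"]
  nsMap <- setNames(nbr[, "nonsyn"], key)
  nS <- nN <- 0
  nr <- nrow(idx)
  if (nr >= 2) {
    for (i in 1:(nr - 1)) for (j in (i + 1):nr) {
      a <- idx[i, ] + 1L; b <- idx[j, ] + 1L
      keep <- a > 0 & b > 0 & a != b
      k <- paste0(a[keep] * 62L + b[keep])
      hit <- nsMap[k]
      nN <- nN + sum(hit == 1L, na.rm = TRUE)
      nS <- nS + sum(hit == 0L, na.rm = TRUE)
    }
  }
  # ~70% of single-nucleotide codon changes are nonsynonymous at omega=1
  if (nS == 0) return(1)
  (nN / max(nS, 1)) * (0.3 / 0.7)
}

#' Likelihood-ratio test between nested codon models
#'
#' 2 (lnL_alt - lnL_null) compared with the chi-square distribution on
#' the difference in parameter counts; the statistic is clipped at 0.
#'
#' @param fitNull,fitAlt \code{\linkS4class{CodonFit}} objects; the
#'   alternative must have more free parameters.
#' @param df degrees of freedom; default: the difference in free
#'   parameter counts of the two fits.
#' @return list: \code{statistic}, \code{df}, \code{pValue}.
#' @export
likelihoodRatioTest <- function(fitNull, fitAlt, df = NULL) {
  npNull <- fitNull@np
  npAlt <- fitAlt@np
  if (npAlt <= npNull)
    stop("models are not nested with fitAlt larger; use aicCompare for ",
         "non-nested models")
  df <- df %||% (npAlt - npNull)
  stat <- max(0, 2 * (fitAlt@lnL - fitNull@lnL))
  list(statistic = stat, df = df,
       pValue = pchisq(stat, df, lower.tail = FALSE))
}

#' Rank codon model fits by AIC
#'
#' AIC = 2k - 2 lnL; fits are returned in ascending AIC order with
#' delta-AIC. Intended for non-nested comparisons (e.g.
#' internal/terminal vs switch/no-switch).
#'
#' @param fits list of \code{\linkS4class{CodonFit}} objects on the same
#'   data.
#' @return data.frame: \code{model}, \code{lnL}, \code{k}, \code{AIC},
#'   \code{deltaAIC}, ordered best first.
#' @export
aicCompare <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits")
  k <- vapply(fits, function(f) f@np, numeric(1))
  lnL <- vapply(fits, function(f) f@lnL, numeric(1))
  aic <- 2 * k - 2 * lnL
  ord <- order(aic)
  data.frame(model = vapply(fits, function(f) f@model, character(1))[ord],
             lnL = lnL[ord], k = k[ord], AIC = aic[ord],
             deltaAIC = aic[ord] - min(aic), stringsAsFactors = FALSE)
}
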