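# Central S4 containers.

#' ElementBlueprint: design of a synthetic Maverick element
#'
#' Describes the layout of a synthetic Maverick/Polinton element: total
#' length, terminal-inverted-repeat (TIR) length, terminal end-motif family,
#' the order of the eight core genes plus \code{pm} in two gene modules, the
#' module orientation, and the lengths of the two accessory regions flanking
#' the core modules. Default bounds follow the sizes observed for intact
#' vertebrate elements: total length 12,723--24,620 bp and TIR length
#' 46--1,447 bp.
#'
#' @slot totalLength total element length in bp.
#' @slot tirLength length of each terminal inverted repeat in bp.
#' @slot endMotifFamily one of \code{"AGT"} (5'-(AGT)2...(ACT)2-3'),
#'   \code{"AG"} (5'-(AG)3...(CT)3-3') or \code{"AC"} (5'-(AC)3A...T(GT)3-3').
#' @slot coreGeneOrder gene ids, module 1 then module 2.
#' @slot moduleOrientation \code{"convergent"} (both modules transcribed
#'   toward the element centre), \code{"divergent"} or \code{"same_strand"}.
#' @slot accessoryLengths lengths in bp of the 5' and 3' accessory regions.
#' @exportClass ElementBlueprint
setClass("ElementBlueprint",
  representation(totalLength = "integer",
                 tirLength = "integer",
                 endMotifFamily = "character",
                 coreGeneOrder = "character",
                 moduleOrientation = "character",
                 accessoryLengths = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@totalLength < 12723L || object@totalLength > 24620L)
      msg <- c(msg, "totalLength outside [12723, 24620] bp")
    if (object@tirLength < 46L || object@tirLength > 1447L)
      msg <- c(msg, "tirLength outside [46, 1447] bp")
    if (!object@endMotifFamily %in% c("AGT", "AG", "AC"))
      msg <- c(msg, "endMotifFamily must be AGT, AG or AC")
    if (!object@moduleOrientation %in%
        c("convergent", "divergent", "same_strand"))
      msg <- c(msg, "unknown moduleOrientation")
    if (length(object@accessoryLengths) != 2L ||
        any(object@accessoryLengths < 0L))
      msg <- c(msg, "accessoryLengths must be two non-negative lengths")
    if (length(msg)) msg else TRUE
  })

#' SyntheticElement: a generated element with ground-truth annotation
#'
#' Holds the DNA sequence of a synthetic element together with its feature
#' table (TIRs, genes, accessory regions; 1-based inclusive coordinates on
#' the element) and the log of any degradation lesions applied.
#'
#' @slot seq element DNA (\code{DNAString}).
#' @slot features data.frame with columns \code{type}, \code{id},
#'   \code{start}, \code{end}, \code{strand}.
#' @slot family end-motif family.
#' @slot lesions data.frame logging degradation edits (possibly 0 rows).
#' @exportClass SyntheticElement
setClass("SyntheticElement",
  representation(seq = "DNAString", features = "data.frame",
                 family = "character", lesions = "data.frame"))

#' TirProfile: per-position nucleotide frequency model of element termini
#'
#' A position frequency matrix over the first 200 bp of aligned 5' TIRs,
#' with additive pseudocounts, used for log-odds scanning of candidate
#' regions.
#'
#' @slot matrix 4 x 200 matrix of relative frequencies (rows A, C, G, T);
#'   every column sums to 1.
#' @slot pseudocount additive pseudocount used per nucleotide.
#' @slot nSequences number of termini the profile was built from.
#' @slot motifFamily end-motif family tag ("AGT", "AG", "AC" or "none").
#' @slot species species/partition tag.
#' @exportClass TirProfile
setClass("TirProfile",
  representation(matrix = "matrix", pseudocount = "numeric",
                 nSequences = "integer", motifFamily = "character",
                 species = "character"),
  validity = function(object) {
    m <- object@matrix
    if (!identical(dim(m), c(4L, 200L)))
      return("profile matrix must be 4 x 200")
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      return("profile rows must be A, C, G, T")
    cs <- colSums(m)
    bad <- abs(cs - 1) > 1e-9 & cs > 0  # all-zero columns allowed (pc = 0, no data)
    if (any(bad)) return("profile columns must sum to 1 (within 1e-9)")
    TRUE
  })

#' ElementAnnotation: one annotated element copy
#'
#' The result of boundary mapping plus core-ORF detection for a single
#' element locus: coordinates on the source contig, the TIR pair, end-motif
#' family, TSD status, the core-ORF table and the intact/fossil call.
#' Coordinates are 1-based inclusive.
#'
#' @slot locusId locus identifier.
#' @slot contig source contig name.
#' @slot start,end element boundaries on the contig.
#' @slot tirLeft,tirRight numeric length-2 (start, end) of each TIR arm on
#'   the contig, or NA if no TIR was resolved.
#' @slot motifFamily "AGT", "AG", "AC" or "none".
#' @slot tsd the duplicated 6-mer, or NA.
#' @slot tsdPerfect TRUE when the two TSD copies match exactly.
#' @slot orfs core-ORF table (one row per detected gene).
#' @slot intact intact/fossil call.
#' @slot layout module layout: convergent / divergent / same_strand /
#'   unresolved.
#' @slot reasons character vector of failed intactness criteria.
#' @exportClass ElementAnnotation
setClass("ElementAnnotation",
  representation(locusId = "character", contig = "character",
                 start = "numeric", end = "numeric",
                 tirLeft = "numeric", tirRight = "numeric",
                 motifFamily = "character", tsd = "character",
                 tsdPerfect = "logical", orfs = "data.frame",
                 intact = "logical", layout = "character",
                 reasons = "character"))

#' CalibrationPrior: lognormal node-age calibration
#'
#' A lognormal prior for a divergence age, parameterised so that the
#' real-space mean equals a reported mean age and the scale is the smallest
#' one whose central 95\% interval contains the reported confidence bounds.
#'
#' @slot mean real-space mean age (Ma).
#' @slot meanlog,sdlog lognormal location and scale.
#' @slot lower,upper the reported 95\% bounds the prior must contain.
#' @exportClass CalibrationPrior
setClass("CalibrationPrior",
  representation(mean = "numeric", meanlog = "numeric", sdlog = "numeric",
                 lower = "numeric", upper = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (abs(exp(object@meanlog + object@sdlog^2 / 2) - object@mean) >
        1e-6 * max(1, object@mean))
      msg <- c(msg, "exp(meanlog + sdlog^2/2) must equal mean within 1e-6")
    q <- qlnorm(c(0.025, 0.975), object@meanlog, object@sdlog)
    if (q[1] > object@lower + 1e-8 || q[2] < object@upper - 1e-8)
      msg <- c(msg, "95% interval does not contain the target bounds")
    if (length(msg)) msg else TRUE
  })

#' Reconciliation: a most-parsimonious host/parasite reconciliation
#'
#' Maps every parasite-tree node to a host-tree edge with an event label
#' (cospeciation, duplication, host switch; losses are counted along the
#' way), under per-event costs.
#'
#' @slot mapping data.frame with one row per parasite node: \code{pnode},
#'   \code{hostEdge}, \code{event} ("cospeciation", "duplication",
#'   "host_switch" or "tip").
#' @slot eventCounts named counts of the four event classes.
#' @slot totalCost summed event costs.
#' @slot costs the cost vector used.
#' @slot switchEdges parasite edge indices on which a host switch occurred.
#' @exportClass Reconciliation
setClass("Reconciliation",
  representation(mapping = "data.frame", eventCounts = "numeric",
                 totalCost = "numeric", costs = "numeric",
                 switchEdges = "integer"),
  validity = function(object) {
    cnt <- object@eventCounts
    cnt <- cnt[cnt > 0]
    replay <- sum(cnt * object@costs[names(cnt)])
    if (is.finite(object@totalCost) && is.finite(replay) &&
        abs(replay - object@totalCost) > 1e-6 * max(1, abs(object@totalCost)))
      return("event multiset does not replay to the reported total cost")
    TRUE
  })

#' AbcResult: rejection-ABC posterior for cophylogenetic event probabilities
#'
#' @slot accepted accepted draws of the final round (rows: draws; columns:
#'   cospeciation, duplication, host_switch, loss).
#' @slot posteriorMean,posteriorSD posterior summaries per event class.
#' @slot roundMeans per-round means of the accepted draws (rounds x 4).
#' @slot tolerance acceptance fraction per round.
#' @slot rounds number of rounds run.
#' @slot nSims simulations per round.
#' @slot failureRate fraction of simulator calls that failed (extinction).
#' @exportClass AbcResult
setClass("AbcResult",
  representation(accepted = "matrix", posteriorMean = "numeric",
                 posteriorSD = "numeric", roundMeans = "matrix",
                 tolerance = "numeric", rounds = "integer",
                 nSims = "integer", failureRate = "numeric"))

#' CodonFit: maximum-likelihood fit of a codon branch model
#'
#' @slot model model name ("neutral_w1", "one_ratio", "internal_terminal",
#'   "switch_noswitch").
#' @slot lnL maximised log-likelihood.
#' @slot omega fitted dN/dS per branch class (named).
#' @slot kappa fitted transition/transversion rate ratio.
#' @slot branchLengths fitted branch lengths (expected substitutions per
#'   codon), in tree edge order.
#' @slot np number of free parameters.
#' @slot convergence TRUE when the optimiser reported convergence.
#' @slot trace best-so-far lnL after each optimiser evaluation (audit).
#' @exportClass CodonFit
setClass("CodonFit",
  representation(model = "character", lnL = "numeric", omega = "numeric",
                 kappa = "numeric", branchLengths = "numeric",
                 np = "integer", convergence = "logical",
                 trace = "numeric"))

setMethod("show", "ElementBlueprint", function(object) {
  cat("ElementBlueprint:", object@totalLength, "bp,",
      object@tirLength, "bp TIRs,", object@endMotifFamily, "motif,",
      object@moduleOrientation, "modules\n")
})

setMethod("show", "SyntheticElement", function(object) {
  cat("SyntheticElement:", length(object@seq), "bp,",
      sum(object@features$type == "gene"), "genes,",
      object@family, "motif family,",
      nrow(object@lesions), "lesions\n")
})

setMethod("show", "TirProfile", function(object) {
  cat("TirProfile over 200 bp termini (", object@nSequences,
      " sequences, pseudocount ", object@pseudocount,
      ", family ", object@motifFamily, ", species ", object@species, ")\n",
      sep = "")
})

setMethod("show", "ElementAnnotation", function(object) {
  cat("ElementAnnotation ", object@locusId, ": ", object@contig, ":",
      object@start, "-", object@end,
      " [", if (object@intact) "intact" else "fossil", "]",
      " motif=", object@motifFamily,
      " layout=", object@layout, "\n", sep = "")
  if (!object@intact && length(object@reasons))
    cat("  reasons:", paste(object@reasons, collapse = "; "), "\n")
})

setMethod("show", "CalibrationPrior", function(object) {
  cat("CalibrationPrior: mean", object@mean, "Ma, meanlog",
      round(object@meanlog, 4), "sdlog", round(object@sdlog, 4),
      "covering [", object@lower, ",", object@upper, "] Ma\n")
})

setMethod("show", "Reconciliation", function(object) {
  cat("Reconciliation: total cost", round(object@totalCost, 4), "\n ",
      paste(names(object@eventCounts), object@eventCounts, sep = "=",
            collapse = ", "), "\n")
})

setMethod("show", "AbcResult", function(object) {
  cat("AbcResult (", object@rounds, " rounds x ", object@nSims,
      " sims, tolerance ", object@tolerance, ")\n", sep = "")
  s <- rbind(mean = object@posteriorMean, sd = object@posteriorSD)
  print(round(s, 4))
})

setMethod("show", "CodonFit", function(object) {
  cat("CodonFit [", object@model, "]: lnL = ", round(object@lnL, 4),
      ", kappa = ", round(object@kappa, 4), ", omega = ",
      paste(names(object@omega), round(object@omega, 6), sep = "=",
            collapse = ", "),
      ", np = ", object@np,
      if (!object@convergence) " (NOT converged)", "\n", sep = "")
})
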