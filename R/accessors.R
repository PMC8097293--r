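# Accessor generics and methods for the S4 containers.

#' Element sequence accessor
#' @param x a SyntheticElement.
#' @return a \code{DNAString}.
#' @export
setGeneric("elementSeq", function(x) standardGeneric("elementSeq"))
#' @rdname elementSeq
setMethod("elementSeq", "SyntheticElement", function(x) x@seq)

#' Ground-truth / annotation feature table accessor
#' @param x a SyntheticElement.
#' @return a data.frame of features (1-based inclusive coordinates).
#' @export
setGeneric("elementFeatures", function(x) standardGeneric("elementFeatures"))
#' @rdname elementFeatures
setMethod("elementFeatures", "SyntheticElement", function(x) x@features)

#' Degradation lesion log accessor
#' @param x a SyntheticElement.
#' @return a data.frame, one row per lesion.
#' @export
setGeneric("elementLesions", function(x) standardGeneric("elementLesions"))
#' @rdname elementLesions
setMethod("elementLesions", "SyntheticElement", function(x) x@lesions)

#' End-motif family accessor
#' @param x a SyntheticElement, TirProfile or ElementAnnotation.
#' @return a character scalar ("AGT", "AG", "AC" or "none").
#' @export
setGeneric("motifFamily", function(x) standardGeneric("motifFamily"))
#' @rdname motifFamily
setMethod("motifFamily", "SyntheticElement", function(x) x@family)
#' @rdname motifFamily
setMethod("motifFamily", "TirProfile", function(x) x@motifFamily)
#' @rdname motifFamily
setMethod("motifFamily", "ElementAnnotation", function(x) x@motifFamily)

#' Intactness accessor
#' @param x an ElementAnnotation.
#' @return logical: TRUE for intact, FALSE for fossil.
#' @export
setGeneric("isIntact", function(x) standardGeneric("isIntact"))
#' @rdname isIntact
setMethod("isIntact", "ElementAnnotation", function(x) x@intact)

#' Core-ORF table accessor
#' @param x an ElementAnnotation.
#' @return data.frame of detected core ORFs.
#' @export
setGeneric("coreOrfs", function(x) standardGeneric("coreOrfs"))
#' @rdname coreOrfs
setMethod("coreOrfs", "ElementAnnotation", function(x) x@orfs)

#' Element boundaries accessor
#' @param x an ElementAnnotation.
#' @return numeric c(start, end), 1-based inclusive on the contig.
#' @export
setGeneric("elementBounds", function(x) standardGeneric("elementBounds"))
#' @rdname elementBounds
setMethod("elementBounds", "ElementAnnotation",
          function(x) c(start = x@start, end = x@end))

#' Profile frequency matrix accessor
#' @param x a TirProfile.
#' @return the 4 x 200 frequency matrix.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname profileMatrix
setMethod("profileMatrix", "TirProfile", function(x) x@matrix)

#' Posterior mean accessor
#' @param x an AbcResult.
#' @return named numeric of posterior means per event class.
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @rdname posteriorMean
setMethod("posteriorMean", "AbcResult", function(x) x@posteriorMean)

#' Posterior standard deviation accessor
#' @param x an AbcResult.
#' @return named numeric of posterior SDs per event class.
#' @export
setGeneric("posteriorSD", function(x) standardGeneric("posteriorSD"))
#' @rdname posteriorSD
setMethod("posteriorSD", "AbcResult", function(x) x@posteriorSD)

#' Total reconciliation cost accessor
#' @param x a Reconciliation.
#' @return numeric total cost.
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
#' @rdname totalCost
setMethod("totalCost", "Reconciliation", function(x) x@totalCost)

#' Event count accessor
#' @param x a Reconciliation.
#' @return named numeric counts of cospeciation, duplication, host_switch,
#'   loss events.
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))
#' @rdname eventCounts
setMethod("eventCounts", "Reconciliation", function(x) x@eventCounts)

#' Log-likelihood accessor
#' @param object a CodonFit.
#' @param ... unused.
#' @return the maximised log-likelihood.
#' @export
setMethod("logLik", "CodonFit", function(object, ...) {
  structure(object@lnL, df = object@np, class = "logLik")
})

#' Fitted omega accessor
#' @param x a CodonFit.
#' @return named numeric of dN/dS estimates per branch class.
#' @export
setGeneric("omegaEstimates", function(x) standardGeneric("omegaEstimates"))
#' @rdname omegaEstimates
setMethod("omegaEstimates", "CodonFit", function(x) x@omega)
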