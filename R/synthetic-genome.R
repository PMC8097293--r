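# Synthetic host genomes, element implantation with target-site
# duplication, and orthologous insertions across a host phylogeny.

#' Generate a random host genome
#'
#' Produces an i.i.d. nucleotide sequence of the requested length and GC
#' content. Host repeat structure is deliberately not simulated; the
#' discovery logic under test does not depend on it.
#'
#' @param length genome length in bp (> 0).
#' @param gcFraction expected GC content, in (0, 1).
#' @param seed integer seed (optional).
#' @return a \code{DNAString}.
#' @export
generateHostGenome <- function(length, gcFraction = 0.42, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("length must be a single positive number")
  if (gcFraction <= 0 || gcFraction >= 1)
    stop("gcFraction must lie strictly between 0 and 1")
  .withSeed(seed, Biostrings::DNAString(
    paste(.randomDnaChars(as.integer(length), gcFraction), collapse = "")))
}

#' Implant an element into a genome with a 6-bp target site duplication
#'
#' Inserts the element immediately after position \code{site} and
#' duplicates the 6-mer ending at \code{site} on the 3' side of the
#' element, emulating the perfect 6-bp TSDs generated upon integration.
#' The output length is input length + element length + 6.
#'
#' @param genome a \code{DNAString} (or character).
#' @param element a \code{DNAString}, character, or
#'   \code{\linkS4class{SyntheticElement}}.
#' @param site insertion point: the element is placed after base
#'   \code{site} (1-based); must satisfy \code{6 <= site <= length(genome)}.
#' @param genomeId optional identifier recorded in the implant record.
#' @return a list with \code{genome} (the new \code{DNAString}) and
#'   \code{record}, a one-row data.frame with \code{genomeId},
#'   \code{site}, \code{tsd}, \code{elementStart}, \code{elementEnd}
#'   (1-based inclusive element coordinates in the new genome).
#' @export
implantElement <- function(genome, element, site, genomeId = "genome") {
  g <- as.character(genome)
  e <- if (is(element, "SyntheticElement")) as.character(element@seq)
       else as.character(element)
  n <- nchar(g)
  if (!is.numeric(site) || length(site) != 1L || site < 6 || site > n)
    stop("site must satisfy 6 <= site <= length(genome)")
  site <- as.integer(site)
  tsd <- substr(g, site - 5L, site)
  out <- paste0(substr(g, 1L, site), e, tsd, substr(g, site + 1L, n))
  list(genome = Biostrings::DNAString(out),
       record = data.frame(genomeId = genomeId, site = site, tsd = tsd,
                           elementStart = site + 1L,
                           elementEnd = site + nchar(e),
                           stringsAsFactors = FALSE))
}

# mutate a character vector of bases: each site substituted with
# probability p (to a uniformly drawn different base)
.mutateChars <- function(chars, p, protect = rep(FALSE, length(chars))) {
  if (p <= 0) return(chars)
  hit <- which(runif(length(chars)) < p & !protect)
  if (length(hit)) {
    for (i in hit) {
      alt <- setdiff(.DNA_BASES, chars[i])
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  chars
}

#' Simulate orthologous element insertions across a host tree
#'
#' Simulates one genomic locus per host-tree tip, where the tips inside a
#' target clade share an element insertion at a homologous position
#' (inherited from a single integration on the clade's stem branch) while
#' tips outside carry the empty site. Flanking host DNA diverges along the
#' tree: each branch substitutes each flank site with probability
#' \code{flankDivergence * branch length}. The element itself is copied
#' unchanged into every carrier.
#'
#' @param hostTree an \code{ape} \code{phylo} tree with branch lengths.
#' @param element element DNA (\code{DNAString}, character or
#'   \code{\linkS4class{SyntheticElement}}).
#' @param targetTips tip labels forming the carrier clade (>= 1).
#' @param flankDivergence substitutions per site per unit branch length.
#' @param locusLength length of the simulated locus (bp) before insertion.
#' @param seed integer seed (optional).
#' @param gcFraction ancestral locus GC content.
#' @return list with \code{genomes} (named \code{DNAStringSet}) and
#'   \code{truth}, a data.frame per tip: \code{tip}, \code{carrier},
#'   \code{elementStart}, \code{elementEnd}, \code{tsd} (NA for empty
#'   sites).
#' @export
simulateOrthologousInsertions <- function(hostTree, element, targetTips,
                                          flankDivergence = 0.05,
                                          locusLength = 12000L, seed = NULL,
                                          gcFraction = 0.42) {
  stopifnot(inherits(hostTree, "phylo"))
  if (!all(targetTips %in% hostTree$tip.label))
    stop("unknown clade: tips not in tree: ",
         paste(setdiff(targetTips, hostTree$tip.label), collapse = ", "))
  e <- if (is(element, "SyntheticElement")) as.character(element@seq)
       else as.character(element)
  .withSeed(seed, {
    anc <- .randomDnaChars(as.integer(locusLength), gcFraction)
    nTip <- length(hostTree$tip.label)
    mrca <- if (length(targetTips) == 1L)
      match(targetTips, hostTree$tip.label)
    else ape::getMRCA(hostTree, targetTips)
    # tips below the MRCA are the carriers
    desc <- if (mrca <= nTip) mrca else {
      kids <- integer(0)
      stack <- mrca
      edge <- hostTree$edge
      while (length(stack)) {
        nd <- stack[1]; stack <- stack[-1]
        ch <- edge[edge[, 1] == nd, 2]
        kids <- c(kids, ch[ch <= nTip])
        stack <- c(stack, ch[ch > nTip])
      }
      kids
    }
    carrierTips <- hostTree$tip.label[desc]
    site <- as.integer(locusLength %/% 2L)
    tsd <- paste(anc[(site - 5L):site], collapse = "")

    edge <- hostTree$edge
    len <- hostTree$edge.length %||% rep(1, nrow(edge))
    root <- nTip + 1L
    genomes <- vector("list", nTip)
    elementRegion <- NULL

    recurse <- function(node, chars, hasElement, protect) {
      if (node == mrca && !hasElement) {
        left <- chars[1:site]
        right <- chars[(site - 5L):site]  # TSD copy
        rest <- chars[(site + 1L):length(chars)]
        chars <- c(left, strsplit(e, "")[[1]], right, rest)
        protect <- c(rep(FALSE, site), rep(TRUE, nchar(e)),
                     rep(FALSE, 6L + (locusLength - site)))
        hasElement <- TRUE
      }
      if (node <= nTip) {
        genomes[[node]] <<- list(chars = chars, hasElement = hasElement)
        return(invisible(NULL))
      }
      for (k in which(edge[, 1] == node)) {
        child <- edge[k, 2]
        mutated <- .mutateChars(chars, flankDivergence * len[k], protect)
        recurse(child, mutated, hasElement, protect)
      }
    }
    recurse(root, anc, FALSE, rep(FALSE, length(anc)))

    truth <- data.frame(tip = hostTree$tip.label,
                        carrier = hostTree$tip.label %in% carrierTips,
                        elementStart = NA_integer_, elementEnd = NA_integer_,
                        tsd = NA_character_, stringsAsFactors = FALSE)
    out <- Biostrings::DNAStringSet(vapply(genomes, function(gn)
      paste(gn$chars, collapse = ""), character(1)))
    names(out) <- hostTree$tip.label
    isCarrier <- vapply(genomes, `[[`, logical(1), "hasElement")
    truth$elementStart[isCarrier] <- site + 1L
    truth$elementEnd[isCarrier] <- site + nchar(e)
    truth$tsd[isCarrier] <- tsd
    list(genomes = out, truth = truth)
  })
}
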