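# Core-ORF detection, intact/fossil classification, genome-architecture
# validation, and the genome-level annotation pipeline.

#' Detect core ORFs in an element sequence
#'
#' Extracts every intronless ORF of at least \code{minCodons} codons from
#' all six reading frames and assigns each to the best-scoring core-gene
#' peptide profile (local alignment, one ORF per gene, maximal score
#' wins). A gene is called "clean" when its ORF has a start codon, no
#' internal stop, a terminal stop, and the alignment covers at least
#' \code{coverageMin} of the reference peptide. Genes without a clean ORF
#' are probed by frame-aware comparison of the reference against the six
#' translations to report lesions: internal stop codons in the matched
#' span, frameshifts (reference covered by hits in different frames) and
#' insertions (>= \code{insertionMin} bp of extra DNA interrupting the
#' profile match).
#'
#' @param elementSeq element DNA (\code{DNAString} or character).
#' @param geneProfiles named \code{AAStringSet} of core-gene peptides
#'   (see \code{\link{coreGeneProfiles}}).
#' @param minScore minimal profile alignment score for an assignment.
#' @param minCodons minimal ORF length in codons.
#' @param coverageMin minimal reference coverage for a clean call.
#' @param insertionMin minimal insertion size (bp) flagged as a lesion.
#' @return data.frame with one row per detected gene: \code{gene},
#'   \code{strand}, \code{start}, \code{end} (1-based on the element),
#'   \code{hasStartCodon}, \code{hasTerminalStop}, \code{internalStops},
#'   \code{frameshiftSuspected}, \code{insertionSuspected},
#'   \code{profileScore}, \code{coverage}, \code{clean}.
#' @export
detectCoreOrfs <- function(elementSeq, geneProfiles = coreGeneProfiles(),
                           minScore = 150, minCodons = 100L,
                           coverageMin = 0.9, insertionMin = 50L) {
  if (is.null(names(geneProfiles)) || !length(geneProfiles))
    stop("configuration error: gene profiles must be a named peptide set")
  s <- as.character(elementSeq)
  emptyRes <- data.frame(gene = character(0), strand = character(0),
                         start = integer(0), end = integer(0),
                         hasStartCodon = logical(0),
                         hasTerminalStop = logical(0),
                         internalStops = integer(0),
                         frameshiftSuspected = logical(0),
                         insertionSuspected = logical(0),
                         profileScore = numeric(0), coverage = numeric(0),
                         clean = logical(0))
  if (!nchar(s)) return(emptyRes)
  frames <- sixFrameTranslate(s)
  n <- nchar(s)

  # 1. clean intronless ORFs >= minCodons
  orfs <- list()
  for (fr in names(frames)) {
    pep <- as.character(frames[[fr]]$peptide)
    if (nchar(pep) < minCodons) next
    frameNum <- as.integer(fr)
    # segments between stops; ORF = first M .. segment end
    stops <- c(0L, which(strsplit(pep, "", fixed = TRUE)[[1]] == "*"),
               nchar(pep) + 1L)
    for (k in seq_len(length(stops) - 1L)) {
      segStart <- stops[k] + 1L
      segEnd <- stops[k + 1L] - 1L
      if (segEnd - segStart + 1L < minCodons) next
      seg <- substr(pep, segStart, segEnd)
      mPos <- regexpr("M", seg, fixed = TRUE)
      if (mPos == -1L) next
      aaStart <- segStart + as.integer(mPos) - 1L
      if (segEnd - aaStart + 1L < minCodons) next
      hasStop <- stops[k + 1L] <= nchar(pep)
      orfs[[length(orfs) + 1L]] <- list(
        frame = frameNum, aaStart = aaStart, aaEnd = segEnd,
        pep = substr(pep, aaStart, segEnd), hasStop = hasStop)
    }
  }

  rows <- list()
  genes <- names(geneProfiles)
  if (length(orfs)) {
    scores <- matrix(0, length(orfs), length(genes),
                     dimnames = list(NULL, genes))
    covers <- matrix(0, length(orfs), length(genes))
    refLens <- Biostrings::width(geneProfiles)
    for (i in seq_along(orfs)) for (g in seq_along(genes)) {
      # an intact gene ORF has nearly the reference length; fragments are
      # handled by the lesion probe below, so skip hopeless comparisons
      orfLen <- nchar(orfs[[i]]$pep)
      if (orfLen < 0.7 * refLens[g] || orfLen > 1.4 * refLens[g]) next
      al <- proteinLocalAlign(geneProfiles[[genes[g]]], orfs[[i]]$pep)
      scores[i, g] <- al$score
      covers[i, g] <- if (anyNA(al$queryRange)) 0 else
        (al$queryRange[2] - al$queryRange[1] + 1L) /
          length(geneProfiles[[genes[g]]])
    }
    for (g in seq_along(genes)) {
      i <- which.max(scores[, g])
      if (scores[i, g] < minScore) next
      o <- orfs[[i]]
      dna <- .aaToDna(o$frame, o$aaStart,
                      o$aaEnd + if (o$hasStop) 1L else 0L, n)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes[g], strand = if (o$frame > 0) "+" else "-",
        start = dna[1], end = dna[2],
        hasStartCodon = TRUE, hasTerminalStop = o$hasStop,
        internalStops = 0L, frameshiftSuspected = FALSE,
        insertionSuspected = FALSE, profileScore = scores[i, g],
        coverage = covers[i, g],
        clean = o$hasStop && covers[i, g] >= coverageMin,
        stringsAsFactors = FALSE)
    }
  }
  found <- vapply(rows, function(r) r$gene, character(1))
  cleanFound <- found[vapply(rows, function(r) r$clean, logical(1))]

  # 2. lesion probing for genes without a clean ORF
  pepByFrame <- lapply(frames, function(f) as.character(f$peptide))
  maskedByFrame <- lapply(pepByFrame, function(p) chartr("*", "X", p))
  for (g in setdiff(genes, cleanFound)) {
    ref <- geneProfiles[[g]]
    hits <- list()
    for (fr in names(frames)) {
      if (!nchar(maskedByFrame[[fr]])) next
      masked <- maskedByFrame[[fr]]
      for (iter in 1:2) {   # up to two hits per frame (split matches)
        al <- proteinLocalAlign(ref, masked)
        if (al$score < minScore / 3 || anyNA(al$targetRange)) break
        hits[[length(hits) + 1L]] <- c(al, list(frame = as.integer(fr)))
        mm <- strsplit(masked, "", fixed = TRUE)[[1]]
        mm[al$targetRange[1]:al$targetRange[2]] <- "X"
        masked <- paste(mm, collapse = "")
      }
    }
    if (!length(hits)) next
    sc <- vapply(hits, `[[`, numeric(1), "score")
    best <- hits[[which.max(sc)]]
    frameNum <- best$frame
    bestFr <- sprintf("%+d", frameNum)
    span <- substr(pepByFrame[[bestFr]], best$targetRange[1],
                   best$targetRange[2])
    nStops <- lengths(regmatches(span, gregexpr("*", span, fixed = TRUE)))
    refCov <- (best$queryRange[2] - best$queryRange[1] + 1L) / length(ref)
    # a secondary hit covering a further part of the reference indicates a
    # frameshift when it lies in a different frame, and an insertion when
    # the genomic span between reference-adjacent hits carries >=
    # insertionMin bp of extra DNA
    frameshift <- FALSE; insertion <- FALSE
    for (h2 in hits[-which.max(sc)]) {
      overlap <- min(best$queryRange[2], h2$queryRange[2]) -
        max(best$queryRange[1], h2$queryRange[1]) + 1L
      extra <- (h2$queryRange[2] - h2$queryRange[1] + 1L) - max(0L, overlap)
      if (extra >= 15L) {
        if (h2$frame != frameNum) frameshift <- TRUE
        d1 <- .aaToDna(frameNum, best$targetRange[1], best$targetRange[2], n)
        d2 <- .aaToDna(h2$frame, h2$targetRange[1], h2$targetRange[2], n)
        gapBp <- max(d1[1], d2[1]) - min(d1[2], d2[2]) - 1L
        refGapAa <- max(h2$queryRange[1], best$queryRange[1]) -
          min(h2$queryRange[2], best$queryRange[2]) - 1L
        if (gapBp - 3L * max(0L, refGapAa) >= insertionMin)
          insertion <- TRUE
      }
    }
    dna <- .aaToDna(frameNum, best$targetRange[1], best$targetRange[2], n)
    if (g %in% found) {
      # replace the non-clean ORF row with the probed description
      idx <- which(found == g)
      rows[[idx]]$internalStops <- as.integer(nStops)
      rows[[idx]]$frameshiftSuspected <- frameshift
      rows[[idx]]$insertionSuspected <- insertion
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, strand = if (frameNum > 0) "+" else "-",
        start = dna[1], end = dna[2], hasStartCodon = FALSE,
        hasTerminalStop = FALSE, internalStops = as.integer(nStops),
        frameshiftSuspected = frameshift, insertionSuspected = insertion,
        profileScore = best$score, coverage = refCov, clean = FALSE,
        stringsAsFactors = FALSE)
      found <- c(found, g)
    }
  }
  if (!length(rows)) return(emptyRes)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Classify an annotated element as intact or fossil
#'
#' An element is intact when all of the following hold: the required core
#' genes (the eight conserved genes; seven when
#' \code{xenopusVariant = TRUE}) are present as clean intronless ORFs with
#' no internal stops, frameshifts or large insertions; discernible TIRs
#' are present; and the element carries a perfect 6-bp TSD. Every failed
#' criterion is reported as a reason.
#'
#' @param annotation an \code{\linkS4class{ElementAnnotation}}.
#' @param xenopusVariant allow seven of the eight core genes (the
#'   X. tropicalis-like layout).
#' @return the annotation with \code{intact} and \code{reasons} filled in.
#' @export
classifyIntactness <- function(annotation, xenopusVariant = FALSE) {
  stopifnot(is(annotation, "ElementAnnotation"))
  orfs <- annotation@orfs
  required <- if (xenopusVariant) 7L else 8L
  reasons <- character(0)
  core <- orfs[orfs$gene %in% .INTACTNESS_GENES, , drop = FALSE]
  cleanGenes <- core$gene[core$clean & core$internalStops == 0L &
                          !core$frameshiftSuspected &
                          !core$insertionSuspected]
  if (length(cleanGenes) < required)
    reasons <- c(reasons, paste0("only ", length(cleanGenes), " of ",
                                 required,
                                 " required core ORFs are intact"))
  lesioned <- core[core$internalStops > 0L | core$frameshiftSuspected |
                   core$insertionSuspected, , drop = FALSE]
  if (nrow(lesioned))
    reasons <- c(reasons, paste0("lesions in: ",
                                 paste(lesioned$gene, collapse = ", ")))
  if (anyNA(annotation@tirLeft) || anyNA(annotation@tirRight))
    reasons <- c(reasons, "no discernible TIRs")
  if (!isTRUE(annotation@tsdPerfect))
    reasons <- c(reasons, "no perfect 6-bp TSD")
  annotation@intact <- length(reasons) == 0L
  annotation@reasons <- unique(reasons)
  annotation
}

#' Validate the two-module genome architecture
#'
#' Checks the conserved gene arrangement: module 1 (\code{ppolb},
#' \code{atp}, \code{pm}, \code{pz}) and module 2 (\code{int}, \code{mcp},
#' \code{pw}, \code{Mcp}, \code{pro}) on the two element halves, and
#' classifies the module layout from the strand pattern: convergent (both
#' modules transcribed toward the element centre - the conserved state),
#' divergent (pointing away, as in Rhinella marina), or same_strand (as in
#' Xenopus tropicalis).
#'
#' @param orfs core-ORF table from \code{\link{detectCoreOrfs}} (>= 2
#'   genes).
#' @return list: \code{layout} ("convergent", "divergent", "same_strand"
#'   or "unresolved") and \code{deviations} (character).
#' @export
validateArchitecture <- function(orfs) {
  if (nrow(orfs) < 2L)
    return(list(layout = "unresolved",
                deviations = "fewer than 2 core ORFs detected"))
  m1 <- orfs[orfs$gene %in% .MODULE1_GENES, , drop = FALSE]
  m2 <- orfs[orfs$gene %in% .MODULE2_GENES, , drop = FALSE]
  deviations <- character(0)
  if (!nrow(m1) || !nrow(m2))
    return(list(layout = "unresolved",
                deviations = "one gene module entirely missing"))
  strand1 <- names(sort(table(m1$strand), decreasing = TRUE))[1]
  strand2 <- names(sort(table(m2$strand), decreasing = TRUE))[1]
  if (length(unique(m1$strand)) > 1L)
    deviations <- c(deviations, "module 1 genes on mixed strands")
  if (length(unique(m2$strand)) > 1L)
    deviations <- c(deviations, "module 2 genes on mixed strands")
  c1 <- mean(c(m1$start, m1$end)); c2 <- mean(c(m2$start, m2$end))
  layout <- if (strand1 == strand2) "same_strand"
  else {
    # which module points toward the other?
    firstLeft <- c1 < c2
    leftStrand <- if (firstLeft) strand1 else strand2
    rightStrand <- if (firstLeft) strand2 else strand1
    if (leftStrand == "+" && rightStrand == "-") "convergent"
    else if (leftStrand == "-" && rightStrand == "+") "divergent"
    else "unresolved"
  }
  list(layout = layout, deviations = deviations)
}

#' Annotate all Maverick elements in a genome
#'
#' The full discovery pipeline on one genome: translated seed scan
#' (\code{\link{scanGenome}}), 4-40 kb colocalization
#' (\code{\link{findColocalizedCandidates}}), 20-kb flank extraction,
#' boundary mapping by inverted-repeat detection with end-motif/TSD
#' refinement (\code{\link{mapElementBoundaries}}), core-ORF detection and
#' intact/fossil classification.
#'
#' @param genome \code{DNAStringSet} or \code{DNAString}.
#' @param seeds named \code{AAStringSet} with entries INT and pPOLB;
#'   default: the packaged int/ppolb profiles.
#' @param geneProfiles core-gene peptides for ORF assignment.
#' @param scoreThreshold seed-scan score threshold.
#' @param flank flank length added to candidate cores.
#' @param xenopusVariant passed to \code{\link{classifyIntactness}}.
#' @param ... further arguments for \code{\link{mapElementBoundaries}}.
#' @return a list of \code{\linkS4class{ElementAnnotation}} objects.
#' @export
annotateGenome <- function(genome, seeds = NULL,
                           geneProfiles = coreGeneProfiles(),
                           scoreThreshold = 100, flank = 20000,
                           xenopusVariant = FALSE, ...) {
  if (is.null(seeds))
    seeds <- Biostrings::AAStringSet(c(
      INT = as.character(geneProfiles[["int"]]),
      pPOLB = as.character(geneProfiles[["ppolb"]])))
  if (is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(setNames(list(genome), "contig1"))
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  hits <- scanGenome(genome, seeds, scoreThreshold = scoreThreshold)
  regions <- findColocalizedCandidates(hits)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    ext <- extractWithFlanks(genome, regions[i, ], flank = flank)
    bounds <- mapElementBoundaries(ext$seq, ...)
    if (is.null(bounds)) {
      # no discernible TIRs: annotate ORFs on the core span anyway
      coreSeq <- Biostrings::subseq(
        genome[[regions$contig[i]]], regions$coreStart[i],
        regions$coreEnd[i])
      orfs <- detectCoreOrfs(coreSeq, geneProfiles)
      if (nrow(orfs)) {
        orfs$start <- orfs$start + regions$coreStart[i] - 1L
        orfs$end <- orfs$end + regions$coreStart[i] - 1L
      }
      ann <- new("ElementAnnotation",
                 locusId = paste0(regions$contig[i], ":",
                                  regions$coreStart[i]),
                 contig = regions$contig[i], start = regions$coreStart[i],
                 end = regions$coreEnd[i],
                 tirLeft = c(NA_real_, NA_real_),
                 tirRight = c(NA_real_, NA_real_), motifFamily = "none",
                 tsd = NA_character_, tsdPerfect = FALSE, orfs = orfs,
                 intact = FALSE, layout = "unresolved",
                 reasons = character(0))
    } else {
      elStart <- ext$start + bounds$start - 1L
      elEnd <- ext$start + bounds$end - 1L
      elSeq <- Biostrings::subseq(genome[[regions$contig[i]]],
                                  elStart, elEnd)
      orfs <- detectCoreOrfs(elSeq, geneProfiles)
      layout <- validateArchitecture(orfs)$layout
      if (nrow(orfs)) {
        orfs$start <- orfs$start + elStart - 1L
        orfs$end <- orfs$end + elStart - 1L
      }
      ann <- new("ElementAnnotation",
                 locusId = paste0(regions$contig[i], ":", elStart),
                 contig = regions$contig[i], start = elStart, end = elEnd,
                 tirLeft = bounds$tirLeft + ext$start - 1,
                 tirRight = bounds$tirRight + ext$start - 1,
                 motifFamily = bounds$family,
                 tsd = bounds$tsd %||% NA_character_,
                 tsdPerfect = isTRUE(bounds$tsdPerfect), orfs = orfs,
                 intact = FALSE, layout = layout, reasons = character(0))
    }
    ann <- classifyIntactness(ann, xenopusVariant = xenopusVariant)
    out[[length(out) + 1L]] <- ann
  }
  out
}

#' Copy-number summaries per genome and grouping
#'
#' Summarises element counts per genome within taxonomic groupings:
#' per-group mean, median and sample standard deviation (n - 1; reported
#' as NA for singleton groups).
#'
#' @param counts data.frame with columns \code{genome}, \code{group},
#'   \code{n} (element count per genome).
#' @return data.frame per group: \code{group}, \code{genomes},
#'   \code{total}, \code{mean}, \code{median}, \code{sd}.
#' @export
summarizeCopyNumbers <- function(counts) {
  if (!nrow(counts))
    return(data.frame(group = character(0), genomes = integer(0),
                      total = numeric(0), mean = numeric(0),
                      median = numeric(0), sd = numeric(0)))
  stopifnot(all(c("genome", "group", "n") %in% names(counts)))
  out <- lapply(split(counts, counts$group), function(sub) {
    data.frame(group = sub$group[1], genomes = nrow(sub),
               total = sum(sub$n), mean = mean(sub$n),
               median = median(sub$n),
               sd = if (nrow(sub) > 1L) sd(sub$n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Size statistics for intact elements
#'
#' @param elementLengths numeric vector of element lengths (bp); at least
#'   one value.
#' @param tirLengths optional numeric vector of TIR lengths (bp).
#' @return data.frame with rows "element" (and "tir"): mean, sd (sample),
#'   min, max.
#' @export
sizeStatistics <- function(elementLengths, tirLengths = NULL) {
  if (!length(elementLengths)) stop("at least one intact element required")
  statRow <- function(x, what) data.frame(
    what = what, n = length(x), mean = mean(x),
    sd = if (length(x) > 1L) sd(x) else 0, min = min(x), max = max(x),
    stringsAsFactors = FALSE)
  out <- statRow(elementLengths, "element")
  if (!is.null(tirLengths) && length(tirLengths))
    out <- rbind(out, statRow(tirLengths, "tir"))
  rownames(out) <- NULL
  out
}
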