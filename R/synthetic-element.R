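# Synthetic Maverick elements: blueprints, assembly, and mutational
# degradation with full ground truth.

.MODULE1_GENES <- c("ppolb", "atp", "pm", "pz")
.MODULE2_GENES <- c("int", "mcp", "pw", "Mcp", "pro")
.CORE_GENES <- c(.MODULE1_GENES, .MODULE2_GENES)
# the eight-gene intactness criterion predates the description of pm
.INTACTNESS_GENES <- setdiff(.CORE_GENES, "pm")

.END_MOTIFS <- list(
  AGT = list(five = "AGTAGT", three = "ACTACT"),
  AG  = list(five = "AGAGAG", three = "CTCTCT"),
  AC  = list(five = "ACACACA", three = "TGTGTGT"))

#' Packaged core-gene peptide profiles
#'
#' Loads the peptide reference set for the nine core genes (the eight
#' conserved genes plus \code{pm}). The packaged set is synthetic: random
#' but fixed peptides of realistic lengths, shipped so that the whole
#' pipeline runs with no database access. Pass \code{file} to use real seed
#' proteins instead.
#'
#' @param file optional path to a FASTA of peptides named by gene id.
#' @return an \code{AAStringSet} named by gene id.
#' @export
coreGeneProfiles <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "core_gene_peptides_synthetic.faa",
                        package = "mavkit", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(file)
  names(aa) <- sub("\\s.*$", "", names(aa))
  missing <- setdiff(.CORE_GENES, names(aa))
  if (length(missing))
    stop("gene profile file lacks: ", paste(missing, collapse = ", "))
  aa[.CORE_GENES]
}

#' Construct an element blueprint
#'
#' @param totalLength total element length in bp (default the observed mean
#'   for intact vertebrate elements).
#' @param tirLength TIR arm length in bp.
#' @param endMotifFamily "AGT", "AG" or "AC".
#' @param moduleOrientation "convergent" (the conserved layout),
#'   "divergent" or "same_strand".
#' @param accessoryLengths optional c(5' length, 3' length); when NULL the
#'   space left after TIRs, genes and spacers is split evenly.
#' @param geneProfiles peptide set used to size the genes (see
#'   \code{\link{coreGeneProfiles}}).
#' @return an \code{\linkS4class{ElementBlueprint}}.
#' @export
elementBlueprint <- function(totalLength = 16862L, tirLength = 300L,
                             endMotifFamily = "AGT",
                             moduleOrientation = "convergent",
                             accessoryLengths = NULL,
                             geneProfiles = coreGeneProfiles()) {
  totalLength <- as.integer(totalLength)
  tirLength <- as.integer(tirLength)
  spacer <- 30L
  geneBp <- 3L * (Biostrings::width(geneProfiles)[
    match(.CORE_GENES, names(geneProfiles))] + 2L)
  coreBp <- sum(geneBp) + spacer * length(.CORE_GENES) - spacer + 2L * spacer
  # layout: tir | acc1 | m1 genes+spacers | mid spacer | m2 | acc2 | tir
  used <- 2L * tirLength + coreBp
  if (is.null(accessoryLengths)) {
    rest <- totalLength - used
    if (rest < 0L)
      stop("layout error: genes, spacers and TIRs exceed totalLength by ",
           -rest, " bp")
    accessoryLengths <- c(rest %/% 2L, rest - rest %/% 2L)
  }
  accessoryLengths <- as.integer(accessoryLengths)
  if (2L * tirLength + coreBp + sum(accessoryLengths) != totalLength)
    stop("layout error: TIRs + genes + spacers + accessory regions (",
         used + sum(accessoryLengths), " bp) do not fill totalLength (",
         totalLength, " bp)")
  new("ElementBlueprint", totalLength = totalLength, tirLength = tirLength,
      endMotifFamily = endMotifFamily, coreGeneOrder = .CORE_GENES,
      moduleOrientation = moduleOrientation,
      accessoryLengths = accessoryLengths)
}

# uniform random choice among synonymous codons, per residue
.reverseTranslate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  byAa <- split(names(gc), unname(gc))
  res <- strsplit(as.character(peptide), "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    opts <- byAa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stops <- byAa[["*"]]
  paste0("ATG", paste(codons, collapse = ""),
         stops[sample.int(length(stops), 1L)])
}

.randomDnaChars <- function(n, gc = 0.42) {
  if (n <= 0L) return(character(0))
  sample(.DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic Maverick element
#'
#' Assembles an element following a blueprint: exact reverse-complement
#' TIRs starting with the family end-motif, two accessory regions, and the
#' nine core genes in two modules (\code{ppolb}, \code{atp}, \code{pm},
#' \code{pz}; and \code{int}, \code{mcp}, \code{pw}, \code{Mcp},
#' \code{pro}), each an intronless ORF with a start codon, no internal
#' stop, and a terminal stop. In the conserved "convergent" layout both
#' modules are transcribed toward the element centre.
#'
#' @param blueprint an \code{\linkS4class{ElementBlueprint}}.
#' @param geneProfiles peptide set to reverse-translate (defaults to the
#'   packaged synthetic profiles).
#' @param seed integer seed for reproducibility (optional).
#' @param gcFraction GC content of TIR/accessory/spacer sequence.
#' @return a \code{\linkS4class{SyntheticElement}}.
#' @export
makeElement <- function(blueprint, geneProfiles = coreGeneProfiles(),
                        seed = NULL, gcFraction = 0.42) {
  stopifnot(is(blueprint, "ElementBlueprint"))
  validObject(blueprint)
  .withSeed(seed, {
    motif <- .END_MOTIFS[[blueprint@endMotifFamily]]
    tirLen <- blueprint@tirLength
    tir5 <- paste0(motif$five,
                   paste(.randomDnaChars(tirLen - nchar(motif$five),
                                         gcFraction), collapse = ""))
    tir3 <- .revcomp(tir5)
    spacer <- function() paste(.randomDnaChars(30L, gcFraction),
                               collapse = "")
    geneDna <- lapply(.CORE_GENES, function(g)
      .reverseTranslate(geneProfiles[[g]]))
    names(geneDna) <- .CORE_GENES

    strands <- switch(blueprint@moduleOrientation,
      convergent = c(m1 = "+", m2 = "-"),
      divergent = c(m1 = "-", m2 = "+"),
      same_strand = c(m1 = "+", m2 = "+"))

    # per module: genomic order of the gene blocks; a minus-strand module
    # keeps its transcription order by reversing the block order and
    # reverse-complementing each gene (so in the convergent layout int
    # sits closest to the 3' TIR, transcribed toward the centre)
    layoutModule <- function(genes, strand) {
      ord <- if (strand == "-") rev(genes) else genes
      lapply(ord, function(g) {
        dna <- geneDna[[g]]
        if (strand == "-") dna <- .revcomp(dna)
        list(id = g, dna = dna, strand = strand, type = "gene")
      })
    }
    m1 <- layoutModule(.MODULE1_GENES, strands[["m1"]])
    m2 <- layoutModule(.MODULE2_GENES, strands[["m2"]])

    acc <- blueprint@accessoryLengths
    parts <- list(list(id = "tir5", dna = tir5, strand = "+",
                       type = "terminal_inverted_repeat"),
                  list(id = "acc1",
                       dna = paste(.randomDnaChars(acc[1], gcFraction),
                                   collapse = ""),
                       strand = "+", type = "accessory"))
    addSp <- function(parts) c(parts, list(list(id = "spacer",
      dna = spacer(), strand = "+", type = "spacer")))
    parts <- addSp(parts)
    for (i in seq_along(m1)) {
      parts <- c(parts, m1[i])
      parts <- addSp(parts)
    }
    for (i in seq_along(m2)) {
      parts <- c(parts, m2[i])
      parts <- addSp(parts)
    }
    parts <- c(parts,
               list(list(id = "acc2",
                         dna = paste(.randomDnaChars(acc[2], gcFraction),
                                     collapse = ""),
                         strand = "+", type = "accessory"),
                    list(id = "tir3", dna = tir3, strand = "+",
                         type = "terminal_inverted_repeat")))

    seqs <- vapply(parts, `[[`, character(1), "dna")
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    feat <- data.frame(
      type = vapply(parts, `[[`, character(1), "type"),
      id = vapply(parts, `[[`, character(1), "id"),
      start = starts, end = ends,
      strand = vapply(parts, `[[`, character(1), "strand"),
      stringsAsFactors = FALSE)
    feat <- feat[feat$type != "spacer", , drop = FALSE]
    rownames(feat) <- NULL
    seq <- Biostrings::DNAString(paste(seqs, collapse = ""))
    stopifnot(length(seq) == blueprint@totalLength)
    new("SyntheticElement", seq = seq, features = feat,
        family = blueprint@endMotifFamily,
        lesions = data.frame(gene = character(0), type = character(0),
                             position = numeric(0), detail = character(0),
                             stringsAsFactors = FALSE))
  })
}

#' Degrade an element into a genomic fossil
#'
#' Introduces host-mutation style lesions into a synthetic element:
#' premature stop codons, 1-bp frameshift deletions, and insertions inside
#' core ORFs (positions drawn uniformly), and optionally erodes the TIRs
#' (both arms truncated to a 20-bp remnant, removing the end-motifs). The
#' lesion log in the returned element records every edit.
#'
#' @param element a \code{\linkS4class{SyntheticElement}}.
#' @param nStops number of premature stop codons to introduce.
#' @param nFrameshifts number of 1-bp deletions to introduce.
#' @param insertionLengths integer vector; one insertion per entry.
#' @param erodeTirs truncate both TIRs so that no terminal repeat remains
#'   detectable.
#' @param seed integer seed (optional).
#' @return the degraded \code{\linkS4class{SyntheticElement}} with updated
#'   coordinates and lesion log.
#' @export
degradeElement <- function(element, nStops = 0L, nFrameshifts = 0L,
                           insertionLengths = integer(0), erodeTirs = FALSE,
                           seed = NULL) {
  stopifnot(is(element, "SyntheticElement"))
  .withSeed(seed, {
    feat <- element@features
    genes <- feat[feat$type == "gene", , drop = FALSE]
    if (nrow(genes) == 0L) stop("element has no ground-truth ORFs")
    chars <- .dnaChars(element@seq)
    lesions <- element@lesions

    nCodingLesions <- nStops + nFrameshifts + length(insertionLengths)
    codonsAvail <- sum((genes$end - genes$start + 1L) %/% 3L - 10L)
    if (nCodingLesions > codonsAvail)
      stop("requested more lesions than available codons")

    # draw (gene, codon) targets; keep codons >= 5 from either end
    drawTarget <- function() {
      g <- genes[sample.int(nrow(genes), 1L), ]
      nc <- (g$end - g$start + 1L) %/% 3L
      codon <- sample(5:(nc - 5L), 1L)
      list(gene = g, codon = codon)
    }
    # genome coordinates of codon c of a gene, on the gene's strand
    codonCoords <- function(g, codon) {
      if (g$strand == "+") g$start + 3L * (codon - 1L) + 0:2
      else g$end - 3L * (codon - 1L) - (0:2)
    }

    edits <- list()
    for (i in seq_len(nStops)) {
      t <- drawTarget()
      edits[[length(edits) + 1L]] <- list(type = "stop", t = t)
    }
    for (i in seq_len(nFrameshifts)) {
      t <- drawTarget()
      edits[[length(edits) + 1L]] <- list(type = "frameshift", t = t)
    }
    for (L in insertionLengths) {
      t <- drawTarget()
      edits[[length(edits) + 1L]] <- list(type = "insertion", t = t,
                                          len = as.integer(L))
    }

    # substitutions first (no coordinate changes)
    for (e in edits) {
      if (e$type != "stop") next
      g <- e$t$gene; codon <- e$t$codon
      pos <- sort(codonCoords(g, codon))
      stopCodon <- if (g$strand == "+") c("T", "A", "A") else c("T", "T", "A")
      chars[pos] <- stopCodon
      lesions <- rbind(lesions, data.frame(
        gene = g$id, type = "stop_codon", position = pos[1],
        detail = paste0("codon ", codon), stringsAsFactors = FALSE))
    }

    # indels applied right-to-left so earlier coordinates stay valid
    indels <- Filter(function(e) e$type != "stop", edits)
    if (length(indels)) {
      at <- vapply(indels, function(e)
        min(codonCoords(e$t$gene, e$t$codon)), numeric(1))
      indels <- indels[order(at, decreasing = TRUE)]
      for (e in indels) {
        pos <- min(codonCoords(e$t$gene, e$t$codon))
        if (e$type == "frameshift") {
          chars <- chars[-pos]
          feat$start <- ifelse(feat$start > pos, feat$start - 1L, feat$start)
          feat$end <- ifelse(feat$end >= pos, feat$end - 1L, feat$end)
          lesions <- rbind(lesions, data.frame(
            gene = e$t$gene$id, type = "frameshift", position = pos,
            detail = "1-bp deletion", stringsAsFactors = FALSE))
        } else {
          ins <- .randomDnaChars(e$len)
          chars <- append(chars, ins, after = pos - 1L)
          feat$start <- ifelse(feat$start >= pos, feat$start + e$len,
                               feat$start)
          feat$end <- ifelse(feat$end >= pos, feat$end + e$len, feat$end)
          lesions <- rbind(lesions, data.frame(
            gene = e$t$gene$id, type = "insertion", position = pos,
            detail = paste0(e$len, " bp"), stringsAsFactors = FALSE))
        }
        genes <- feat[feat$type == "gene", , drop = FALSE]
      }
    }

    if (isTRUE(erodeTirs)) {
      tirs <- which(feat$type == "terminal_inverted_repeat")
      stopifnot(length(tirs) == 2L)
      keep <- 20L
      lenNow <- length(chars)
      t5 <- feat[tirs[1], ]; t3 <- feat[tirs[2], ]
      cut3 <- (t3$end - t3$start + 1L) - keep
      cut5 <- (t5$end - t5$start + 1L) - keep
      if (cut3 > 0L) {
        chars <- chars[-((t3$end - cut3 + 1L):t3$end)]
        feat$end[tirs[2]] <- feat$end[tirs[2]] - cut3
      }
      if (cut5 > 0L) {
        chars <- chars[-(t5$start:(t5$start + cut5 - 1L))]
        feat$start <- ifelse(feat$start > t5$start, feat$start - cut5,
                             feat$start)
        feat$end <- feat$end - cut5
      }
      lesions <- rbind(lesions, data.frame(
        gene = "tir", type = "tir_erosion", position = 1,
        detail = paste0("arms truncated to ", keep, " bp"),
        stringsAsFactors = FALSE))
    }

    new("SyntheticElement",
        seq = Biostrings::DNAString(paste(chars, collapse = "")),
        features = feat, family = element@family, lesions = lesions)
  })
}
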