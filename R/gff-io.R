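# Interoperability: annotations as GRanges / GFF3, labelled Newick trees.

#' Convert element annotations to a GRanges object
#'
#' One range per element plus one per TIR arm and core ORF, with
#' intactness, motif family and TSD carried in the metadata columns;
#' suitable for export to GFF3 via \code{rtracklayer::export}.
#'
#' @param annotations list of \code{\linkS4class{ElementAnnotation}}.
#' @return a \code{GRanges}.
#' @export
annotationsToGRanges <- function(annotations) {
  rows <- list()
  for (ann in annotations) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = ann@contig, start = ann@start, end = ann@end,
      strand = "*", type = "mobile_genetic_element", ID = ann@locusId,
      gene = NA_character_,
      intact = ann@intact, motifFamily = ann@motifFamily,
      tsd = ann@tsd %||% NA_character_, stringsAsFactors = FALSE)
    if (!anyNA(ann@tirLeft))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = ann@contig, start = ann@tirLeft[1], end = ann@tirLeft[2],
        strand = "+", type = "terminal_inverted_repeat",
        ID = paste0(ann@locusId, ":tir5"), gene = NA_character_,
        intact = NA, motifFamily = ann@motifFamily, tsd = NA_character_,
        stringsAsFactors = FALSE)
    if (!anyNA(ann@tirRight))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = ann@contig, start = ann@tirRight[1],
        end = ann@tirRight[2], strand = "-",
        type = "terminal_inverted_repeat",
        ID = paste0(ann@locusId, ":tir3"), gene = NA_character_,
        intact = NA, motifFamily = ann@motifFamily, tsd = NA_character_,
        stringsAsFactors = FALSE)
    orfs <- ann@orfs
    for (k in seq_len(nrow(orfs)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = ann@contig, start = orfs$start[k], end = orfs$end[k],
        strand = orfs$strand[k], type = "CDS",
        ID = paste0(ann@locusId, ":", orfs$gene[k]), gene = orfs$gene[k],
        intact = NA, motifFamily = NA_character_, tsd = NA_character_,
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID, gene = df$gene, intact = df$intact,
    motifFamily = df$motifFamily, tsd = df$tsd)
}

#' Write and read parasite trees with branch labels
#'
#' Branch labels (e.g. switch / no_switch) are stored as node labels of
#' each edge's child node (tip labels get a "#label" suffix), so they
#' round-trip through Newick.
#'
#' @param tree \code{phylo}.
#' @param labels character per \code{tree$edge} row.
#' @param file path to write to.
#' @return \code{writeLabeledTree}: the file path, invisibly.
#' @export
writeLabeledTree <- function(tree, labels, file) {
  stopifnot(length(labels) == nrow(tree$edge))
  nTip <- length(tree$tip.label)
  out <- tree
  nodeLab <- rep("", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nTip)
      out$tip.label[child] <- paste0(tree$tip.label[child], "#", labels[e])
    else nodeLab[child - nTip] <- labels[e]
  }
  out$node.label <- nodeLab
  ape::write.tree(out, file = file)
  invisible(file)
}

#' @rdname writeLabeledTree
#' @return \code{readLabeledTree}: list with \code{tree} (labels
#'   stripped) and \code{labels} (per edge; edges to the root keep "").
#' @export
readLabeledTree <- function(file) {
  tr <- ape::read.tree(file)
  nTip <- length(tr$tip.label)
  labels <- character(nrow(tr$edge))
  tipParts <- strsplit(tr$tip.label, "#", fixed = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    labels[e] <- if (child <= nTip) {
      parts <- tipParts[[child]]
      if (length(parts) > 1L) parts[length(parts)] else ""
    } else {
      lab <- tr$node.label[child - nTip]
      if (is.null(lab) || is.na(lab)) "" else lab
    }
  }
  tr$tip.label <- vapply(tipParts, function(p)
    if (length(p) > 1L) paste(p[-length(p)], collapse = "#") else p[1],
    character(1))
  tr$node.label <- NULL
  list(tree = tr, labels = labels)
}
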