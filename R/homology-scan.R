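# Translated homology scanning: six-frame translation, exact affine-gap
# Smith-Waterman (tBLASTn analogue), seed-hit colocalization, and flank
# extraction.

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six frames (frames -1..-3 on the
#' reverse complement). Codons containing N translate to X; trailing bases
#' that do not complete a codon are dropped.
#'
#' @param dna a \code{DNAString} or character over the alphabet ACGTN.
#' @return a list of six entries named "+1".."+3", "-1".."-3"; each holds
#'   \code{peptide} (an \code{AAString}, stops as "*") and \code{offset}
#'   (frame start on its strand, 1-based), plus \code{seqLength}.
#' @export
sixFrameTranslate <- function(dna) {
  .checkDnaAlphabet(dna)
  dna <- .asDnaString(dna)
  n <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  # fuzzy-codon handling is only needed when N is present (building the
  # fuzzy code table is costly relative to translation itself)
  hasN <- Biostrings::countPattern("N", dna) > 0L
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (f in 1:3) {
      stop_at <- f + ((n - f + 1L) %/% 3L) * 3L - 1L
      pep <- if (stop_at >= f + 2L) {
        sub <- Biostrings::subseq(s, f, stop_at)
        if (hasN)
          suppressWarnings(Biostrings::translate(sub,
                                                 if.fuzzy.codon = "solve"))
        else Biostrings::translate(sub)
      } else Biostrings::AAString("")
      out[[paste0(strand, f)]] <- list(peptide = pep, offset = f,
                                       seqLength = n)
    }
  }
  out
}

# forward-strand DNA coordinates (1-based inclusive) of peptide positions
# [aaStart, aaEnd] in the given frame (+1..+3 / -1..-3)
.aaToDna <- function(frame, aaStart, aaEnd, seqLength) {
  f <- abs(frame)
  dnaFrom <- f + 3L * (aaStart - 1L)
  dnaTo <- f + 3L * aaEnd - 1L
  if (frame > 0) c(dnaFrom, dnaTo)
  else c(seqLength - dnaTo + 1L, seqLength - dnaFrom + 1L)
}

#' Exact affine-gap local protein alignment
#'
#' Smith-Waterman local alignment with affine gap costs: a gap run of
#' length k costs \code{gapOpen + k * gapExtend}. The score is maximal over
#' all local alignments; disjoint alphabets with all-negative substitution
#' scores yield the empty alignment with score 0.
#'
#' @param query,target peptides (\code{AAString} or character), nonempty.
#' @param matrixName substitution matrix name (e.g. "BLOSUM62", "PAM250");
#'   resolved from the matrices shipped with Biostrings.
#' @param gapOpen,gapExtend affine gap parameters (BLAST protein defaults
#'   11 and 1).
#' @return a list: \code{score}, \code{queryRange} and \code{targetRange}
#'   (1-based inclusive aligned spans; NA when the optimum is the empty
#'   alignment).
#' @export
proteinLocalAlign <- function(query, target, matrixName = "BLOSUM62",
                              gapOpen = 11, gapExtend = 1) {
  q <- as.character(query); t <- as.character(target)
  if (!nzchar(q) || !nzchar(t)) stop("query and target must be nonempty")
  mat <- .substitutionMatrix(matrixName)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = mat, gapOpening = gapOpen, gapExtension = gapExtend)
  sc <- Biostrings::score(pa)
  if (sc <= 0)
    return(list(score = 0, queryRange = c(NA_integer_, NA_integer_),
                targetRange = c(NA_integer_, NA_integer_)))
  list(score = sc,
       queryRange = c(Biostrings::start(Biostrings::pattern(pa)),
                      Biostrings::end(Biostrings::pattern(pa))),
       targetRange = c(Biostrings::start(Biostrings::subject(pa)),
                       Biostrings::end(Biostrings::subject(pa))))
}

.substitutionMatrix <- function(matrixName) {
  if (is.matrix(matrixName)) return(matrixName)
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!matrixName %in% known)
    stop("unknown substitution matrix: ", matrixName)
  e <- new.env()
  utils::data(list = matrixName, package = "Biostrings", envir = e)
  get(matrixName, envir = e)
}

#' Scan a genome for translated seed-protein hits
#'
#' Searches all six reading frames of every contig for local-alignment hits
#' to the seed proteins (integrase INT and protein-primed polymerase pPOLB
#' in the canonical screen), the in-package analogue of a tBLASTn search.
#' Multiple hits per frame are recovered by masking each best hit and
#' realigning; overlapping hits to the same query are merged keeping the
#' maximal score.
#'
#' @param genome a \code{DNAStringSet} (or single \code{DNAString}).
#' @param seeds named \code{AAStringSet} of seed proteins (e.g. INT,
#'   pPOLB).
#' @param scoreThreshold minimal raw alignment score to report (> 0).
#' @param matrixName,gapOpen,gapExtend alignment parameters.
#' @param maxHitsPerFrame cap on mask-and-realign iterations per frame.
#' @return data.frame of hits: \code{contig}, \code{query}, \code{frame},
#'   \code{start}, \code{end} (1-based inclusive, forward strand),
#'   \code{score}. Empty genome gives an empty frame.
#' @export
scanGenome <- function(genome, seeds, scoreThreshold = 100,
                       matrixName = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                       maxHitsPerFrame = 10L) {
  if (scoreThreshold <= 0) stop("scoreThreshold must be > 0")
  if (is(genome, "DNAString") || is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::DNAStringSet(setNames(list(.asDnaString(genome)),
                                                "contig1"))
  if (length(genome) == 0L)
    return(data.frame(contig = character(0), query = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  seeds <- Biostrings::AAStringSet(seeds)
  if (is.null(names(seeds))) stop("seeds must be named")
  hits <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    frames <- sixFrameTranslate(genome[[ci]])
    for (fr in names(frames)) {
      pep <- as.character(frames[[fr]]$peptide)
      if (!nzchar(pep)) next
      frameNum <- as.integer(fr)
      for (qi in seq_along(seeds)) {
        masked <- pep
        for (iter in seq_len(maxHitsPerFrame)) {
          al <- proteinLocalAlign(seeds[[qi]], masked, matrixName,
                                  gapOpen, gapExtend)
          if (al$score < scoreThreshold || anyNA(al$targetRange)) break
          dna <- .aaToDna(frameNum, al$targetRange[1], al$targetRange[2],
                          frames[[fr]]$seqLength)
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig, query = names(seeds)[qi], frame = frameNum,
            start = dna[1], end = dna[2], score = al$score,
            stringsAsFactors = FALSE)
          span <- al$targetRange[1]:al$targetRange[2]
          m <- strsplit(masked, "", fixed = TRUE)[[1]]
          m[span] <- "X"
          masked <- paste(m, collapse = "")
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), query = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  df <- do.call(rbind, hits)
  .mergeOverlappingHits(df)
}

# merge overlapping same-contig same-query hits, keeping the max score
.mergeOverlappingHits <- function(df) {
  out <- list()
  for (key in unique(paste(df$contig, df$query))) {
    sub <- df[paste(df$contig, df$query) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    grp <- IRanges::findOverlaps(ir, IRanges::reduce(ir), select = "first")
    for (g in unique(grp)) {
      rows <- sub[grp == g, , drop = FALSE]
      best <- rows[which.max(rows$score), , drop = FALSE]
      best$start <- min(rows$start); best$end <- max(rows$end)
      out[[length(out) + 1L]] <- best
    }
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Pair colocalized INT/pPOLB hits into candidate regions
#'
#' A candidate element region is formed by an (INT, pPOLB) hit pair on the
#' same contig whose separation - the gap between the nearest ends of the
#' two hits - lies within \code{[minSep, maxSep]} (4-40 kb by default).
#' Overlapping candidate regions are merged.
#'
#' @param hits hit table from \code{\link{scanGenome}}.
#' @param minSep,maxSep separation bounds in bp.
#' @return data.frame of regions: \code{contig}, \code{coreStart},
#'   \code{coreEnd} (1-based inclusive span of the hit pair).
#' @export
findColocalizedCandidates <- function(hits, minSep = 4000, maxSep = 40000) {
  empty <- data.frame(contig = character(0), coreStart = integer(0),
                      coreEnd = integer(0))
  if (!nrow(hits)) return(empty)
  regions <- list()
  for (contig in unique(hits$contig)) {
    sub <- hits[hits$contig == contig, , drop = FALSE]
    a <- sub[sub$query == "INT", , drop = FALSE]
    b <- sub[sub$query == "pPOLB", , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      sep <- max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]) - 1L
      if (sep >= minSep && sep <= maxSep)
        regions[[length(regions) + 1L]] <- data.frame(
          contig = contig,
          coreStart = min(a$start[i], b$start[j]),
          coreEnd = max(a$end[i], b$end[j]), stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty)
  df <- do.call(rbind, regions)
  out <- list()
  for (contig in unique(df$contig)) {
    sub <- df[df$contig == contig, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(sub$coreStart, sub$coreEnd))
    out[[length(out) + 1L]] <- data.frame(
      contig = contig, coreStart = IRanges::start(red),
      coreEnd = IRanges::end(red), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extract a candidate region with flanks
#'
#' Cuts the candidate core span plus \code{flank} bp on each side out of
#' its contig, clipping at contig ends (clipping is flagged).
#'
#' @param genome \code{DNAStringSet} (or \code{DNAString} named contig1).
#' @param region one row of \code{\link{findColocalizedCandidates}} output.
#' @param flank flank length in bp (default 20 kb).
#' @return list: \code{seq} (\code{DNAString}), \code{start}, \code{end}
#'   (1-based region coordinates on the contig), \code{clippedLeft},
#'   \code{clippedRight}.
#' @export
extractWithFlanks <- function(genome, region, flank = 20000) {
  if (is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(setNames(list(genome), "contig1"))
  if (!region$contig %in% names(genome))
    stop("region contig not present in genome")
  contig <- genome[[region$contig]]
  n <- length(contig)
  if (region$coreStart < 1 || region$coreEnd > n)
    stop("region lies outside its contig")
  from <- max(1L, region$coreStart - as.integer(flank))
  to <- min(n, region$coreEnd + as.integer(flank))
  list(seq = Biostrings::subseq(contig, from, to), start = from, end = to,
       contig = region$contig,
       clippedLeft = from > region$coreStart - flank,
       clippedRight = to < region$coreEnd + flank)
}
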