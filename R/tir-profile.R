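# Position-weight-matrix models of element termini: building, log-odds
# scanning, iterative refinement, and information-content profiles.

#' Build a terminus profile from aligned 5' TIRs
#'
#' Constructs a position frequency matrix from the first 200 positions of
#' aligned 5' TIR sequences, with additive pseudocounts: for column counts
#' c_b over the observed nucleotides, p_b = (c_b + pc) / (n_obs + 4 pc).
#' Shorter inputs are padded with gaps (which carry no counts).
#'
#' @param alignedTirs \code{DNAStringSet}, character vector or character
#'   matrix of aligned 5' termini (>= 1 sequence).
#' @param pseudocount additive pseudocount (default 0.5).
#' @param motifFamily,species partition tags stored with the profile.
#' @return a \code{\linkS4class{TirProfile}}.
#' @export
buildTirProfile <- function(alignedTirs, pseudocount = 0.5,
                            motifFamily = "none", species = "unknown") {
  if ((is.matrix(alignedTirs) && nrow(alignedTirs) == 0L) ||
      (!is.matrix(alignedTirs) && length(alignedTirs) == 0L))
    stop("empty input: at least one terminus sequence is required")
  m <- if (is.matrix(alignedTirs)) alignedTirs else {
    x <- toupper(as.character(alignedTirs))
    w <- max(nchar(x), 200L)
    x <- vapply(x, function(s) paste0(s, strrep("-", w - nchar(s))),
                character(1), USE.NAMES = FALSE)
    do.call(rbind, strsplit(x, "", fixed = TRUE))
  }
  if (ncol(m) < 200L)
    m <- cbind(m, matrix("-", nrow(m), 200L - ncol(m)))
  m <- m[, 1:200, drop = FALSE]
  freq <- matrix(0, 4L, 200L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:200) {
    col <- m[, j]
    cnt <- table(factor(col[col %in% .DNA_BASES], levels = .DNA_BASES))
    tot <- sum(cnt) + 4 * pseudocount
    if (tot > 0) freq[, j] <- (as.numeric(cnt) + pseudocount) / tot
  }
  new("TirProfile", matrix = freq, pseudocount = pseudocount,
      nSequences = if (is.matrix(alignedTirs)) nrow(alignedTirs)
                   else length(alignedTirs),
      motifFamily = motifFamily, species = species)
}

#' Scan a sequence with a terminus profile
#'
#' Slides the 200-position profile along both strands of a sequence and
#' scores each window by the summed log2 odds against a background
#' distribution; windows above the threshold are reported, keeping the
#' best hit per locus (hits closer than 200 bp are merged). Forward-strand
#' hits locate 5' termini; reverse-strand hits (the profile matched on the
#' reverse complement) locate 3' termini.
#'
#' @param profile a \code{\linkS4class{TirProfile}}.
#' @param seq \code{DNAString} or character.
#' @param background nucleotide background frequencies (A, C, G, T).
#' @param scoreThreshold minimal log2-odds score.
#' @return data.frame: \code{start} (1-based window start on the forward
#'   strand), \code{strand} ("+" = 5' terminus, "-" = 3' terminus),
#'   \code{score}. Sequences shorter than 200 bp give zero rows.
#' @export
scanWithProfile <- function(profile, seq, background = rep(0.25, 4),
                            scoreThreshold) {
  stopifnot(is(profile, "TirProfile"))
  validObject(profile)
  s <- toupper(as.character(seq))
  empty <- data.frame(start = integer(0), strand = character(0),
                      score = numeric(0))
  if (nchar(s) < 200L) return(empty)
  lo <- log2(pmax(profile@matrix, 1e-12) / background)
  scoreStrand <- function(str) {
    chars <- strsplit(str, "", fixed = TRUE)[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    n <- length(chars)
    nw <- n - 200L + 1L
    total <- numeric(nw)
    for (j in 1:200) {
      b <- idx[j:(j + nw - 1L)]
      contrib <- ifelse(is.na(b), 0, lo[cbind(b, j)])
      total <- total + contrib
    }
    total
  }
  fwd <- scoreStrand(s)
  rev <- scoreStrand(.revcomp(s))
  n <- nchar(s)
  fi <- which(fwd >= scoreThreshold)
  ri <- which(rev >= scoreThreshold)
  hits <- rbind(
    data.frame(start = fi, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(start = n - 200L + 2L - ri, strand = rep("-", length(ri)),
               score = rev[ri]))
  if (!nrow(hits)) return(empty)
  # best per locus: cluster hits within 200 bp on the same strand
  out <- list()
  for (str in unique(hits$strand)) {
    sub <- hits[hits$strand == str, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$start) > 200L))
    for (g in unique(grp)) {
      rows <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- rows[which.max(rows$score), , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Maximal achievable profile score
#'
#' The log2-odds score of the profile's consensus sequence, i.e. the
#' per-column maximum summed over the 200 positions. Useful for setting
#' scan thresholds as a fraction of the maximum.
#'
#' @param profile a \code{\linkS4class{TirProfile}}.
#' @param background background frequencies.
#' @return numeric scalar.
#' @export
profileMaxScore <- function(profile, background = rep(0.25, 4)) {
  lo <- log2(pmax(profile@matrix, 1e-12) / background)
  sum(apply(lo, 2, max))
}

#' Per-position information content of a terminus alignment
#'
#' Sequence-logo style conservation: IC = 2 + sum_i p_i log2 p_i bits per
#' column, where p_i is the relative frequency of nucleotide i among the
#' observed (non-gap) residues of the column. Invariant columns score 2
#' bits, uniform columns 0; all-gap columns are reported as NA.
#'
#' @param alignment aligned termini (\code{DNAStringSet}, character vector
#'   or character matrix).
#' @return numeric vector of per-column IC values in [0, 2] (NA where no
#'   residue is observed).
#' @export
informationContentProfile <- function(alignment) {
  m <- .alignmentMatrix(alignment)
  m[] <- toupper(m)
  apply(m, 2, function(col) {
    obs <- col[col %in% .DNA_BASES]
    if (!length(obs)) return(NA_real_)
    p <- table(factor(obs, levels = .DNA_BASES)) / length(obs)
    p <- p[p > 0]
    ic <- 2 + sum(p * log2(p))
    min(2, max(0, ic))
  })
}

#' Read and write terminus profiles as TSV
#'
#' Profiles are stored as tab-separated 4 x 200 frequency matrices with
#' the pseudocount, sequence count, motif family and species carried in
#' '#'-prefixed header lines, so they survive plain-text round trips.
#'
#' @param profile a \code{\linkS4class{TirProfile}}.
#' @param file path.
#' @return \code{writeTirProfile}: the path, invisibly;
#'   \code{readTirProfile}: a \code{\linkS4class{TirProfile}}.
#' @export
writeTirProfile <- function(profile, file) {
  stopifnot(is(profile, "TirProfile"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# pseudocount=", profile@pseudocount),
    paste0("# nSequences=", profile@nSequences),
    paste0("# motifFamily=", profile@motifFamily),
    paste0("# species=", profile@species)), con)
  utils::write.table(profile@matrix, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname writeTirProfile
#' @export
readTirProfile <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^# ", key, "="), "",
                            grep(paste0("^# ", key, "="), hdr,
                                 value = TRUE))
  m <- utils::read.table(text = grep("^#", lines, value = TRUE,
                                     invert = TRUE),
                         sep = "\t", row.names = 1)
  m <- as.matrix(m)
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  new("TirProfile", matrix = m,
      pseudocount = as.numeric(getv("pseudocount")),
      nSequences = as.integer(getv("nSequences")),
      motifFamily = getv("motifFamily"), species = getv("species"))
}

#' Iterative profile refinement over unresolved candidate regions
#'
#' Implements the iterative annotation loop: build terminus profiles per
#' species/end-motif partition from the currently resolved elements, scan
#' every unresolved candidate region with each profile on both strands,
#' pair 5' and 3' terminus hits, and accept a new element when its implied
#' boundaries carry a perfect 6-bp TSD. The loop repeats until no new
#' acceptance or \code{maxRounds}; the accepted set only grows.
#'
#' @param candidates a list; each entry needs \code{seq} (region sequence),
#'   \code{species} (partition tag), and optionally a resolved annotation:
#'   \code{start}, \code{end}, \code{family}, \code{resolved} (logical).
#' @param maxRounds maximal refinement rounds (default 5).
#' @param relThreshold acceptance threshold as a fraction of the profile's
#'   maximal score.
#' @param minLength minimal accepted element length in bp.
#' @return the candidate list with newly resolved entries filled in; a
#'   \code{rounds} attribute records per-round acceptance counts.
#' @export
iterativeRefinement <- function(candidates, maxRounds = 5L,
                                relThreshold = 0.5, minLength = 1000L) {
  resolved <- vapply(candidates, function(x) isTRUE(x$resolved), logical(1))
  if (!any(resolved)) {
    warning("no seed annotations: returning candidates unchanged")
    return(candidates)
  }
  roundsLog <- integer(0)
  for (round in seq_len(maxRounds)) {
    newly <- 0L
    # profiles per species/end-motif partition from resolved candidates
    parts <- split(which(resolved), vapply(candidates[resolved], function(x)
      paste(x$species %||% "unknown", x$family %||% "none", sep = "/"),
      character(1)))
    profiles <- lapply(names(parts), function(key) {
      idx <- parts[[key]]
      tirs <- vapply(idx, function(i) {
        x <- candidates[[i]]
        substr(as.character(x$seq), x$start, min(x$start + 199L, x$end))
      }, character(1))
      sp <- strsplit(key, "/", fixed = TRUE)[[1]]
      buildTirProfile(tirs, motifFamily = sp[2], species = sp[1])
    })
    for (i in which(!resolved)) {
      x <- candidates[[i]]
      for (pr in profiles) {
        thr <- relThreshold * profileMaxScore(pr)
        hits <- scanWithProfile(pr, x$seq, scoreThreshold = thr)
        fives <- hits[hits$strand == "+", , drop = FALSE]
        threes <- hits[hits$strand == "-", , drop = FALSE]
        if (!nrow(fives) || !nrow(threes)) next
        found <- FALSE
        for (a in seq_len(nrow(fives))) {
          for (b in seq_len(nrow(threes))) {
            start <- fives$start[a]
            end <- threes$start[b] + 200L - 1L
            if (end - start + 1L < minLength) next
            ok <- tryCatch(verifyTsd(x$seq, start, end),
                           error = function(e) list(perfect = FALSE))
            if (ok$perfect) {
              candidates[[i]]$start <- start
              candidates[[i]]$end <- end
              candidates[[i]]$tsd <- ok$tsd
              candidates[[i]]$family <- tryCatch(classifyEndMotif(
                substr(as.character(x$seq), start, start + 7L),
                substr(as.character(x$seq), end - 7L, end)),
                error = function(e) "none")
              candidates[[i]]$resolved <- TRUE
              candidates[[i]]$resolvedBy <- "profile_scan"
              resolved[i] <- TRUE
              newly <- newly + 1L
              found <- TRUE
            }
            if (found) break
          }
          if (found) break
        }
        if (found) break
      }
    }
    roundsLog <- c(roundsLog, newly)
    if (newly == 0L) break
  }
  attr(candidates, "rounds") <- roundsLog
  candidates
}
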