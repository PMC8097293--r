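# Element boundary mapping: inverted-repeat detection by self-comparison,
# end-motif classification, perfect-TSD verification, and boundary
# refinement with the TSD as arbiter.

#' Find inverted repeat pairs by self-comparison
#'
#' Detects pairs of reverse-complementary arms (TIR candidates) within a
#' sequence, the in-package analogue of blasting a sequence against itself
#' and keeping hits in reverse orientation. An arm pair is an ungapped
#' match between \code{seq[i..i+L-1]} and the reverse complement of
#' \code{seq[j..j+L-1]} (i + L <= j); all such pairs live on anti-diagonals
#' of the comparison matrix, which are scanned exhaustively for the
#' best-scoring window (score = length x identity = number of matching
#' positions) with identity >= \code{minIdentity} and length in
#' \code{[minLen, maxArm]}. For long sequences only anti-diagonals
#' containing an exact \code{seedLength}-mer match are scanned.
#' Non-overlapping pairs are reported ranked by score (ties: leftmost,
#' then longest).
#'
#' @param seq \code{DNAString} or character.
#' @param minLen minimal arm length (bp).
#' @param minIdentity minimal arm identity (imperfect repeats allowed).
#' @param maxArm maximal arm length (bp).
#' @param seedLength exact-match seed size for long sequences.
#' @param exhaustive force scanning of every anti-diagonal (automatic for
#'   sequences up to 600 bp).
#' @return data.frame: \code{leftStart}, \code{leftEnd}, \code{rightStart},
#'   \code{rightEnd} (1-based inclusive), \code{length}, \code{identity},
#'   \code{score}; zero rows when nothing qualifies.
#' @export
findInvertedRepeats <- function(seq, minLen = 46L, minIdentity = 0.8,
                                maxArm = 1447L, seedLength = 12L,
                                exhaustive = NULL) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- data.frame(leftStart = integer(0), leftEnd = integer(0),
                      rightStart = integer(0), rightEnd = integer(0),
                      length = integer(0), identity = numeric(0),
                      score = integer(0))
  if (n < 2L * minLen) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- .complementChars(chars)
  exhaustive <- exhaustive %||% (n <= 600L)

  if (exhaustive) {
    diagonals <- lapply((2L * minLen):(2L * n - 2L * minLen + 2L),
                        function(sv) list(s = sv, lo = 1L, hi = n))
  } else {
    k <- as.integer(seedLength)
    if (n < k) return(empty)
    starts <- 1:(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    rckm <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(chartr("N", "A", km))))
    f <- factor(km)
    tab <- split(starts, f)
    pos <- match(rckm, levels(f))
    svAll <- integer(0); pAll <- integer(0)
    for (p in which(!is.na(pos))) {
      partners <- tab[[pos[p]]]
      if (length(partners) > 50L) next  # low-complexity guard
      partners <- partners[partners >= p]
      if (!length(partners)) next
      svAll <- c(svAll, p + partners + k - 1L)
      pAll <- c(pAll, rep(p, length(partners)))
    }
    if (!length(svAll)) return(empty)
    lo <- tapply(pAll, svAll, min)
    hi <- tapply(pAll, svAll, max) + k - 1L
    diagonals <- lapply(seq_along(lo), function(i)
      list(s = as.integer(names(lo)[i]), lo = max(1L, lo[[i]] - maxArm),
           hi = hi[[i]] + maxArm))
  }

  cands <- list()
  for (d in diagonals) {
    sv <- d$s
    aMin <- max(1L, sv - n, d$lo)
    aMax <- min((sv - 1L) %/% 2L, d$hi)
    W <- aMax - aMin + 1L
    if (W < minLen) next
    a <- aMin:aMax
    m <- chars[a] == comp[sv - a]
    cs <- c(0L, cumsum(m))
    # any window of length >= minLen with identity >= minIdentity contains
    # a minLen-window with identity >= minIdentity, so this filter is exact
    i0 <- (minLen + 1L):(W + 1L)
    if (!any(cs[i0] - cs[i0 - minLen] >= minIdentity * minLen)) next
    best <- NULL
    for (L in minLen:min(maxArm, W)) {
      idxEnd <- (L + 1L):(W + 1L)
      cnt <- cs[idxEnd] - cs[idxEnd - L]
      ok <- cnt >= minIdentity * L
      if (!any(ok)) next
      cntOk <- cnt[ok]
      startOk <- which(ok)          # offset of window start within a
      o <- order(-cntOk, startOk)
      top <- o[1]
      cand <- c(count = cntOk[top], a0 = aMin + startOk[top] - 1L, L = L)
      if (is.null(best) || cand["count"] > best["count"] ||
          (cand["count"] == best["count"] && (cand["a0"] < best["a0"] ||
           (cand["a0"] == best["a0"] && cand["L"] > best["L"]))))
        best <- cand
    }
    if (is.null(best)) next
    a0 <- unname(best["a0"]); L <- unname(best["L"])
    cands[[length(cands) + 1L]] <- data.frame(
      leftStart = a0, leftEnd = a0 + L - 1L,
      rightStart = sv - (a0 + L - 1L), rightEnd = sv - a0,
      length = L, identity = unname(best["count"]) / L,
      score = unname(best["count"]))
  }
  if (!length(cands)) return(empty)
  df <- do.call(rbind, cands)
  df <- df[order(-df$score, df$leftStart, -df$length), , drop = FALSE]
  # greedy selection of non-overlapping arm pairs
  sel <- logical(nrow(df))
  taken <- IRanges::IRanges()
  for (i in seq_len(nrow(df))) {
    arms <- IRanges::IRanges(c(df$leftStart[i], df$rightStart[i]),
                             c(df$leftEnd[i], df$rightEnd[i]))
    if (!length(taken) ||
        !any(IRanges::overlapsAny(arms, taken))) {
      sel[i] <- TRUE
      taken <- c(taken, arms)
    }
  }
  out <- df[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the terminal end-motif family
#'
#' Vertebrate Maverick termini carry one of three conserved end-motifs:
#' 5'-(AGT)2 ... (ACT)2-3', 5'-(AG)3 ... (CT)3-3', or
#' 5'-(AC)3A ... T(GT)3-3'.
#'
#' @param fivePrime first bases of the element (>= 7).
#' @param threePrime last bases of the element (>= 7).
#' @return "AGT", "AG", "AC" or "none".
#' @export
classifyEndMotif <- function(fivePrime, threePrime) {
  f <- toupper(as.character(fivePrime))
  t <- toupper(as.character(threePrime))
  if (nchar(f) < 7L || nchar(t) < 7L)
    stop("termini of at least 7 bp are required")
  endsWith2 <- function(x, suf) substr(x, nchar(x) - nchar(suf) + 1L,
                                       nchar(x)) == suf
  if (startsWith(f, "AGTAGT") && endsWith2(t, "ACTACT")) return("AGT")
  if (startsWith(f, "AGAGAG") && endsWith2(t, "CTCTCT")) return("AG")
  if (startsWith(f, "ACACACA") && endsWith2(t, "TGTGTGT")) return("AC")
  "none"
}

#' Verify a perfect 6-bp target site duplication
#'
#' True exactly when the k-mer immediately 5' of the element equals the
#' k-mer immediately 3' of it ("perfect" means exact).
#'
#' @param regionSeq sequence containing the element and both flanks.
#' @param elementStart,elementEnd element boundaries, 1-based inclusive.
#' @param k TSD length (6 for vertebrate Mavericks).
#' @return list: \code{perfect} (logical) and \code{tsd} (the 5' copy).
#'   Insufficient flank raises an error (distinct from FALSE).
#' @export
verifyTsd <- function(regionSeq, elementStart, elementEnd, k = 6L) {
  s <- as.character(regionSeq)
  n <- nchar(s)
  if (elementStart - k < 1L || elementEnd + k > n)
    stop("insufficient flank for TSD verification (need ", k,
         " bp on both sides)")
  left <- substr(s, elementStart - k, elementStart - 1L)
  right <- substr(s, elementEnd + 1L, elementEnd + k)
  list(perfect = identical(left, right), tsd = left)
}

# Snap provisional IR-pair boundaries to exact element boundaries, using
# the end-motif and the perfect-TSD test as arbiter: a motif-anchored
# boundary pair with a valid TSD wins; ties go to the longer element.
# Returns NULL when no TSD-consistent boundary exists near the IR edges.
.snapBoundaries <- function(regionSeq, leftStart, rightEnd,
                            snapRange = 160L, tsdOnlyRange = 10L, k = 6L) {
  s <- as.character(regionSeq)
  n <- nchar(s)
  motifs <- list(AGT = c("AGTAGT", "ACTACT"),
                 AG = c("AGAGAG", "CTCTCT"),
                 AC = c("ACACACA", "TGTGTGT"))
  best <- NULL
  consider <- function(p, q, family) {
    if (p - k < 1L || q + k > n || q <= p) return(invisible(NULL))
    v <- verifyTsd(s, p, q, k)
    if (!v$perfect) return(invisible(NULL))
    cand <- list(start = p, end = q, family = family, tsd = v$tsd,
                 len = q - p + 1L)
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$start < best$start))
      best <<- cand
    invisible(NULL)
  }
  for (family in names(motifs)) {
    five <- motifs[[family]][1]; three <- motifs[[family]][2]
    ps <- .motifStartsNear(s, five, leftStart, snapRange)
    qs <- .motifEndsNear(s, three, rightEnd, snapRange)
    for (p in ps) for (q in qs) consider(p, q, family)
  }
  if (is.null(best)) {
    for (p in max(1L, leftStart - tsdOnlyRange):(leftStart + tsdOnlyRange))
      for (q in (rightEnd - tsdOnlyRange):min(n, rightEnd + tsdOnlyRange))
        consider(p, q, "none")
  }
  best
}

.motifStartsNear <- function(s, motif, center, range) {
  lo <- max(1L, center - range)
  hi <- min(nchar(s) - nchar(motif) + 1L, center + range)
  if (hi < lo) return(integer(0))
  window <- substr(s, lo, hi + nchar(motif) - 1L)
  # overlapping occurrences matter: repeat motifs overlap themselves
  m <- gregexpr(paste0("(?=", motif, ")"), window, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) + lo - 1L
}

.motifEndsNear <- function(s, motif, center, range) {
  starts <- .motifStartsNear(s, motif, center - nchar(motif) + 1L, range)
  starts + nchar(motif) - 1L
}

#' Map element boundaries within a candidate region
#'
#' Combines inverted-repeat detection, end-motif classification and
#' perfect-TSD verification into a boundary call: the element boundary is
#' the outer edge of the accepted IR pair, refined so that a motif-anchored
#' boundary pair with a perfect 6-bp TSD wins (ties go to the longer
#' element). Without a motif, only a small TSD-consistent adjustment of the
#' raw IR edges is allowed.
#'
#' @param regionSeq candidate region (element plus flanks),
#'   \code{DNAString} or character.
#' @param minLen,minIdentity,maxArm IR detection parameters
#'   (see \code{\link{findInvertedRepeats}}).
#' @param snapRange how far from the IR edges to search for end-motifs.
#' @param maxPairs how many top IR pairs to try.
#' @return a list per resolved element: \code{start}, \code{end},
#'   \code{family}, \code{tsd}, \code{tsdPerfect}, \code{tirLeft},
#'   \code{tirRight} (each c(start, end)); or \code{NULL} when no boundary
#'   is supported. Only the best-supported call is returned.
#' @export
mapElementBoundaries <- function(regionSeq, minLen = 46L, minIdentity = 0.8,
                                 maxArm = 1447L, snapRange = 160L,
                                 maxPairs = 3L) {
  irs <- findInvertedRepeats(regionSeq, minLen = minLen,
                             minIdentity = minIdentity, maxArm = maxArm)
  if (!nrow(irs)) return(NULL)
  for (i in seq_len(min(maxPairs, nrow(irs)))) {
    # the maximal-match window can overshoot an exact repeat by up to
    # ~(1 - identity floor)/(identity floor - background match rate)
    # of the arm length on each side, so the motif search must scale
    # with the detected arm
    snap <- as.integer(max(snapRange, ceiling(0.45 * irs$length[i]) + 30L))
    snap <- .snapBoundaries(regionSeq, irs$leftStart[i], irs$rightEnd[i],
                            snapRange = snap)
    if (!is.null(snap)) {
      return(list(start = snap$start, end = snap$end, family = snap$family,
                  tsd = snap$tsd, tsdPerfect = TRUE,
                  tirLeft = c(snap$start, max(irs$leftEnd[i], snap$start)),
                  tirRight = c(min(irs$rightStart[i], snap$end), snap$end)))
    }
  }
  # no TSD-consistent refinement: fall back to raw IR edges
  i <- 1L
  s <- as.character(regionSeq)
  start <- irs$leftStart[i]; end <- irs$rightEnd[i]
  fam <- tryCatch(classifyEndMotif(substr(s, start, start + 7L),
                                   substr(s, end - 7L, end)),
                  error = function(e) "none")
  tsd <- tryCatch(verifyTsd(s, start, end), error = function(e)
    list(perfect = FALSE, tsd = NA_character_))
  list(start = start, end = end, family = fam, tsd = tsd$tsd,
       tsdPerfect = tsd$perfect,
       tirLeft = c(irs$leftStart[i], irs$leftEnd[i]),
       tirRight = c(irs$rightStart[i], irs$rightEnd[i]))
}
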