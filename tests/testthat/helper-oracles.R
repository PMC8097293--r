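# Independent brute-force oracles used to validate the package's
# algorithmic kernels. These deliberately use naive enumeration, not the
# implementation's data structures.

# ---- affine-gap local alignment by enumeration of monotone matchings ----
# Score of the best local alignment where a gap run of length k costs
# open + k * ext: enumerate every monotone set of aligned position pairs.
bruteLocalAlign <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  rec <- function(pi, pj, sc) {
    if (sc > best) best <<- sc
    if (pi >= n || pj >= m) return(invisible(NULL))
    for (i in (pi + 1):n) for (j in (pj + 1):m) {
      pen <- 0
      if (pi > 0) {
        di <- i - pi - 1; dj <- j - pj - 1
        if (di > 0) pen <- pen + open + ext * di
        if (dj > 0) pen <- pen + open + ext * dj
      }
      rec(i, j, sc + mat[av[i], bv[j]] - pen)
    }
  }
  rec(0, 0, 0)
  best
}

# ---- exhaustive inverted-repeat search ----
# Best ungapped reverse-complement arm pair by scanning every (i, j, L):
# score = number of matching positions, identity >= minIdentity,
# non-overlapping arms. Ties: leftmost start, then longest.
bruteInvertedRepeat <- function(seq, minLen, minIdentity, maxArm) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  rc <- chartr("ACGT", "TGCA", s)
  n <- length(s)
  best <- NULL
  for (i in 1:(n - 2 * minLen + 1)) {
    for (L in minLen:min(maxArm, n)) {
      if (i + 2 * L - 1 > n) break
      for (j in (i + L):(n - L + 1)) {
        matches <- sum(s[i:(i + L - 1)] == rev(rc[j:(j + L - 1)]))
        if (matches < minIdentity * L) next
        cand <- c(score = matches, i = i, j = j, L = L)
        if (is.null(best) || cand["score"] > best["score"] ||
            (cand["score"] == best["score"] &&
             (cand["i"] < best["i"] ||
              (cand["i"] == best["i"] && cand["L"] > best["L"]))))
          best <- cand
      }
    }
  }
  best
}

# ---- naive profile scan ----
bruteProfileScores <- function(profMatrix, seq, background = rep(0.25, 4)) {
  lo <- log2(pmax(profMatrix, 1e-12) / background)
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  n <- length(chars)
  if (n < 200) return(numeric(0))
  vapply(1:(n - 199), function(w) {
    sc <- 0
    for (col in 1:200) {
      b <- idx[w + col - 1]
      if (!is.na(b)) sc <- sc + lo[b, col]
    }
    sc
  }, numeric(1))
}

# ---- declarative reconciliation cost by mapping enumeration ----
# Host bookkeeping built directly from the ape tree (independent of the
# package's internal index).
bruteHostTables <- function(host) {
  nTip <- length(host$tip.label)
  nEdge <- nrow(host$edge)
  E <- nEdge + 1                      # + root edge above the root node
  child <- c(host$edge[, 2], nTip + 1)
  len <- if (is.null(host$edge.length)) rep(1, nEdge) else host$edge.length
  depth <- numeric(nTip + host$Nnode)
  for (k in seq_len(nEdge)) {         # host$edge rows are parent-first? ensure by loop to fixpoint
  }
  # node depths via repeated relaxation (small trees)
  repeat {
    changed <- FALSE
    for (k in seq_len(nEdge)) {
      d <- depth[host$edge[k, 1]] + len[k]
      if (abs(depth[host$edge[k, 2]] - d) > 1e-12) {
        depth[host$edge[k, 2]] <- d
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  tTop <- c(depth[host$edge[, 1]], -1e-6)
  tBottom <- c(depth[host$edge[, 2]], 0)
  inSubtree <- function(e, f) {       # f inside edge-subtree of e?
    if (e == f) return(TRUE)
    v <- child[f]
    target <- child[e]
    while (TRUE) {
      if (v == target) return(TRUE)
      k <- which(host$edge[, 2] == v)
      if (!length(k)) return(FALSE)
      v <- host$edge[k, 1]
      if (v == target) return(TRUE)
      if (v == nTip + 1 && target != nTip + 1) return(FALSE)
    }
  }
  steps <- function(e, f) {           # edges strictly between e and f
    if (e == f) return(0)
    cnt <- 0
    v <- child[f]
    target <- child[e]
    while (v != target) {
      k <- which(host$edge[, 2] == v)
      v <- host$edge[k, 1]
      cnt <- cnt + 1
    }
    cnt
  }
  desc <- outer(1:E, 1:E, Vectorize(inSubtree))
  allowed <- outer(1:E, 1:E, Vectorize(function(e, f)
    e != f && !desc[e, f] && !desc[f, e] &&
      tTop[f] < tBottom[e] && tTop[e] < tBottom[f]))
  daughters <- lapply(1:E, function(e) which(host$edge[, 1] == child[e]))
  tipEdge <- vapply(1:nTip, function(t) which(host$edge[, 2] == t),
                    numeric(1))
  list(E = E, desc = desc, allowed = allowed, daughters = daughters,
       steps = Vectorize(steps), stepsFun = steps, tipEdge = tipEdge,
       pendant = c(host$edge[, 2] <= nTip, FALSE))
}

# minimum reconciliation cost over all mappings of parasite internal
# nodes to host edges, under the declarative event model
bruteReconcileCost <- function(host, parasite, associations, costs) {
  ht <- bruteHostTables(host)
  nTipP <- length(parasite$tip.label)
  nNodeP <- nTipP + parasite$Nnode
  kids <- vector("list", nNodeP)
  for (k in seq_len(nrow(parasite$edge)))
    kids[[parasite$edge[k, 1]]] <- c(kids[[parasite$edge[k, 1]]],
                                     parasite$edge[k, 2])
  tipMap <- ht$tipEdge[match(
    associations$host[match(parasite$tip.label, associations$parasite)],
    host$tip.label)]
  internals <- (nTipP + 1):nNodeP
  cCo <- costs[["cospeciation"]]; cDu <- costs[["duplication"]]
  cSw <- costs[["host_switch"]]; cLo <- costs[["loss"]]
  nodeCost <- function(e, f1, f2) {
    best <- Inf
    ds <- ht$daughters[[e]]
    if (length(ds) == 2) {
      for (ord in list(ds, rev(ds))) {
        if (ht$desc[ord[1], f1] && ht$desc[ord[2], f2])
          best <- min(best, cCo + cLo * (ht$stepsFun(ord[1], f1) +
                                         ht$stepsFun(ord[2], f2)))
      }
    }
    if (ht$desc[e, f1] && ht$desc[e, f2])
      best <- min(best, cDu + cLo * (ht$stepsFun(e, f1) +
                                     ht$stepsFun(e, f2)))
    for (sm in list(c(f1, f2), c(f2, f1))) {
      if (!ht$desc[e, sm[1]]) next
      landCost <- Inf
      for (g in which(ht$allowed[e, ]))
        if (ht$desc[g, sm[2]])
          landCost <- min(landCost, ht$stepsFun(g, sm[2]))
      if (is.finite(landCost))
        best <- min(best, cSw + cLo * (ht$stepsFun(e, sm[1]) + landCost))
    }
    best
  }
  M <- integer(nNodeP)
  M[seq_len(nTipP)] <- tipMap
  bestTotal <- Inf
  assignRec <- function(idx) {
    if (idx > length(internals)) {
      total <- 0
      for (v in internals) {
        cs <- nodeCost(M[v], M[kids[[v]][1]], M[kids[[v]][2]])
        total <- total + cs
        if (!is.finite(total)) return(invisible(NULL))
      }
      if (total < bestTotal) bestTotal <<- total
      return(invisible(NULL))
    }
    for (e in 1:ht$E) {
      M[internals[idx]] <<- e
      assignRec(idx + 1)
    }
  }
  assignRec(1)
  bestTotal
}

# ---- matrix exponential by scaling-and-squaring power series ----
bruteExpm <- function(A) {
  nrm <- max(abs(A))
  s <- max(0, ceiling(log2(max(nrm, 1e-300)) + 4))
  A <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:30) {
    term <- term %*% A / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# ---- counting-style dN/dS estimate for a pair of codon sequences ----
# Nei-Gojobori flavoured: per-codon synonymous site fractions from the
# universal code; differences counted on codons differing at one site.
bruteCountingOmega <- function(codonsA, codonsB) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  synSites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      ch <- strsplit(cod, "")[[1]]
      for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        mc <- paste(mut, collapse = "")
        if (!mc %in% codons) next
        if (gc[[mc]] == gc[[cod]]) s <- s + 1/3
      }
    }
    s
  }
  S <- N <- Sd <- Nd <- 0
  for (k in seq_along(codonsA)) {
    ca <- codonsA[k]; cb <- codonsB[k]
    if (!ca %in% codons || !cb %in% codons) next
    sa <- synSites(ca); sb <- synSites(cb)
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
    if (ca == cb) next
    diffPos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(diffPos) != 1) next
    if (gc[[ca]] == gc[[cb]]) Sd <- Sd + 1 else Nd <- Nd + 1
  }
  pN <- Nd / N; pS <- Sd / S
  if (pS == 0) return(NA_real_)
  pN / pS
}
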