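# Codon alignments, the rate matrix, pruning likelihood and branch-model
# fits.

test_that("codon alignment threading follows the protein guide", {
  cds <- c(s1 = "ATGAAACCCTAA", s2 = "ATGAAACCCTAA")
  guide <- c(s1 = "MKP", s2 = "MKP")
  m <- buildCodonAlignment(cds, guide)
  expect_identical(unname(m[1, ]), c("ATG", "AAA", "CCC"))
  cds2 <- c(s1 = "ATGAAACCCGGG", s2 = "ATGAAACCC")
  guide2 <- c(s1 = "MKPG", s2 = "MKP-")
  m2 <- buildCodonAlignment(cds2, guide2)
  expect_identical(unname(m2[2, 4]), "---")
  # back-translation round trip
  gc <- Biostrings::GENETIC_CODE
  row2 <- m2[2, m2[2, ] != "---"]
  expect_identical(paste(gc[row2], collapse = ""), "MKP")
  badGuide <- c(s1 = "MKPG", s2 = "MKI-")
  expect_error(buildCodonAlignment(cds2, badGuide),
               "translation mismatch for s2 at guide residue 3")
  expect_error(buildCodonAlignment(c(s1 = "ATGAA"), c(s1 = "MK")),
               "divisible by 3")
  expect_error(buildCodonAlignment(c(s1 = "ATGTAACCC"), c(s1 = "M*P")),
               "internal stop")
})

test_that("the codon rate matrix respects omega, scaling and reversibility", {
  tab <- mavkit:::.codonTable()
  Q0 <- codonRateMatrix(0, 2)
  nonsyn <- tab$nbr[tab$nbr[, "nonsyn"] == 1L, , drop = FALSE]
  expect_true(all(Q0[nonsyn[, c("i", "j")]] == 0))
  Q <- codonRateMatrix(0.5, 3)
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  pi <- rep(1 / 61, 61)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance at uniform frequencies
  expect_equal(Q, t(Q), tolerance = 1e-12)
  # transition matrices are stochastic at any t
  P <- bruteExpm(Q * 0.7)
  expect_true(all(abs(rowSums(P) - 1) < 1e-8))
  expect_error(codonRateMatrix(-1, 2), "omega")
  expect_error(codonRateMatrix(0.5, 0), "kappa")
})

test_that("pruning equals direct summation and handles limiting cases", {
  tab <- mavkit:::.codonTable()
  pi <- rep(1 / 61, 61)
  Q <- codonRateMatrix(0.5, 2)
  # two tips, one site: likelihoods over all tip pairs sum to one
  tree2 <- ape::read.tree(text = "(a:0.1,b:0.2);")
  P <- bruteExpm(Q * 0.3)
  tot <- 0
  for (x in c(1, 7, 30)) for (y in c(2, 61)) {
    m <- matrix(tab$codons[c(x, y)], nrow = 2,
                dimnames = list(c("a", "b"), NULL))
    lnl <- codonLogLikelihood(m, tree2, omega = 0.5, kappa = 2)
    expect_equal(lnl, unname(log(pi[x] * P[x, y])), tolerance = 1e-9)
  }
  full <- sum(vapply(1:61, function(x) sum(pi[x] * P[x, ]), numeric(1)))
  expect_equal(full, 1, tolerance = 1e-9)
  # zero branch lengths with identical tips: lnL = n_sites * ln(pi)
  tree0 <- ape::read.tree(text = "(a:0,b:0);")
  m0 <- matrix(tab$codons[c(5, 5, 9, 9)], nrow = 2,
               dimnames = list(c("a", "b"), NULL))
  expect_equal(codonLogLikelihood(m0, tree0, omega = 1, kappa = 2),
               2 * log(1 / 61), tolerance = 1e-9)
  # three tips vs brute-force summation over internal states
  tree3 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.3);")
  P1 <- bruteExpm(Q * 0.1); P2 <- bruteExpm(Q * 0.2)
  P15 <- bruteExpm(Q * 0.15); P3 <- bruteExpm(Q * 0.3)
  m3 <- matrix(tab$codons[c(5, 20, 33, 5, 5, 5)], nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  direct <- 0
  for (site in 1:2) {
    sv <- m3[, site]
    ix <- match(sv, tab$codons)
    tot <- 0
    for (r in 1:61) for (x in 1:61)
      tot <- tot + pi[r] * P15[r, x] * P1[x, ix[1]] * P2[x, ix[2]] *
        P3[r, ix[3]]
    direct <- direct + log(tot)
  }
  expect_equal(codonLogLikelihood(m3, tree3, omega = 0.5, kappa = 2),
               unname(direct), tolerance = 1e-9)
  # gaps are missing data: a fully gapped column contributes nothing
  mg <- cbind(m3, c("---", "---", "---"))
  rownames(mg) <- rownames(m3)
  expect_equal(codonLogLikelihood(mg, tree3, omega = 0.5, kappa = 2),
               codonLogLikelihood(m3, tree3, omega = 0.5, kappa = 2),
               tolerance = 1e-9)
})

test_that("the likelihood is invariant to re-rooting", {
  tr <- fix6TipCodonTree()
  aln <- simulateCodonAlignment(tr, omega = 0.3, kappa = 2,
                                nCodons = 120, seed = 60)
  u <- ape::unroot(tr)
  l1 <- codonLogLikelihood(aln, u, omega = 0.3, kappa = 2)
  r2 <- ape::root(u, outgroup = "t4", resolve.root = TRUE)
  l2 <- codonLogLikelihood(aln, r2, omega = 0.3, kappa = 2)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("branch-model fitting nests correctly and tracks the audit trace", {
  tr <- fix6TipCodonTree()
  aln <- simulateCodonAlignment(tr, omega = 0.2, kappa = 2,
                                nCodons = 400, seed = 61)
  f0 <- fitBranchModel(aln, tr, "neutral_w1", nStarts = 1)
  f1 <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
  expect_lte(f0@lnL, f1@lnL + 1e-6)
  expect_identical(f1@np, f0@np + 1L)
  expect_true(all(diff(f1@trace) >= 0))     # best-so-far lnL is monotone
  expect_true(f1@convergence)
  # no-signal control: two-class fit on one-class data
  f2 <- fitBranchModel(aln, tr, "internal_terminal", nStarts = 1)
  w <- omegaEstimates(f2)
  expect_lt(abs(w[1] - w[2]) / mean(w), 0.6)
  expect_gte(f2@lnL, f1@lnL - 1e-6)
})

test_that("one-ratio omega is recovered within a factor of two (small scale)", {
  tr <- fix6TipCodonTree()
  for (w0 in c(0.1, 1)) {
    ok <- 0L
    for (i in 1:5) {
      aln <- simulateCodonAlignment(tr, omega = w0, kappa = 2,
                                    nCodons = 500, seed = 70 + i)
      fit <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
      w <- unname(omegaEstimates(fit))
      if (w >= w0 / 2 && w <= w0 * 2) ok <- ok + 1L
    }
    expect_gte(ok, 4L)
  }
})

test_that("fitted branch lengths scale with the simulated lengths", {
  tr <- fix6TipCodonTree()
  aln <- simulateCodonAlignment(tr, omega = 0.5, kappa = 2,
                                nCodons = 2000, seed = 62)
  fit <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
  u <- ape::unroot(tr)
  slope <- sum(fit@branchLengths * u$edge.length) /
    sum(u$edge.length^2)
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("LRT follows the chi-square calibration points", {
  mkFit <- function(lnL, np, model = "one_ratio")
    new("CodonFit", model = model, lnL = lnL, omega = c(all = 1),
        kappa = 2, branchLengths = 1, np = as.integer(np),
        convergence = TRUE, trace = lnL)
  eq <- likelihoodRatioTest(mkFit(-100, 3, "neutral_w1"), mkFit(-100, 4))
  expect_equal(eq$pValue, 1)
  crit <- likelihoodRatioTest(mkFit(-100, 3, "neutral_w1"),
                              mkFit(-100 + 3.841459 / 2, 4))
  expect_equal(crit$pValue, 0.05, tolerance = 1e-4)
  expect_error(likelihoodRatioTest(mkFit(-100, 4), mkFit(-101, 4)),
               "aicCompare")
})

test_that("AIC ranking penalises parameters and ignores input order", {
  mkFit <- function(lnL, np, model)
    new("CodonFit", model = model, lnL = lnL, omega = c(all = 1),
        kappa = 2, branchLengths = 1, np = as.integer(np),
        convergence = TRUE, trace = lnL)
  a <- mkFit(-100, 2, "one_ratio")
  b <- mkFit(-100, 3, "internal_terminal")
  r <- aicCompare(list(a, b))
  expect_identical(r$model[1], "one_ratio")
  expect_equal(r$deltaAIC[2], 2)
  r2 <- aicCompare(list(b, a))
  expect_identical(r2$model, r$model)
})

test_that("switch-simulated data prefers the switch model by AIC", {
  tr <- fix6TipCodonTree()
  lab <- rep("no_switch", nrow(tr$edge))
  lab[c(3, 7)] <- "switch"
  cls <- ifelse(lab == "switch", 2L, 1L)
  wins <- 0L
  for (i in 1:5) {
    aln <- simulateCodonAlignment(tr, omega = c(0.05, 0.5), kappa = 2,
                                  branchClass = cls, nCodons = 800,
                                  seed = 80 + i)
    fIT <- fitBranchModel(aln, tr, "internal_terminal", nStarts = 1)
    fSW <- fitBranchModel(aln, tr, "switch_noswitch", branchClass = lab,
                          nStarts = 1)
    if (aicCompare(list(fIT, fSW))$model[1] == "switch_noswitch")
      wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
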