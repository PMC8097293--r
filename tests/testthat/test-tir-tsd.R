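# Inverted repeats, end motifs, TSDs and terminus profiles.

test_that("a constructed exact inverted repeat is found with identity 1", {
  set.seed(21)
  arm <- randomDnaStr(60)
  rcArm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm)))
  s <- paste0(randomDnaStr(99), arm, randomDnaStr(640), rcArm,
              randomDnaStr(141))
  irs <- findInvertedRepeats(s)
  expect_gt(nrow(irs), 0)
  # the top pair covers the implanted arms (it may absorb flanking
  # chance matches while staying above the identity floor; the exact
  # boundary is settled downstream by the motif/TSD arbiter)
  expect_lte(irs$leftStart[1], 100)
  expect_gte(irs$leftEnd[1], 159)
  expect_lte(irs$rightStart[1], 800)
  expect_gte(irs$rightEnd[1], 859)
  expect_gte(irs$identity[1], 0.8)
  expect_gte(irs$score[1], 60)
})

test_that("random sequences rarely contain qualifying inverted repeats", {
  set.seed(22)
  hits <- 0L
  for (i in 1:100) {
    s <- randomDnaStr(1000)
    if (nrow(findInvertedRepeats(s)) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("inverted-repeat search equals the exhaustive oracle on toys", {
  set.seed(23)
  for (rep in 1:3) {
    arm <- randomDnaStr(30)
    ch <- strsplit(arm, "")[[1]]
    if (rep > 1) ch <- mutateAt(ch, sample(30, 3))   # imperfect repeat
    armMut <- paste(ch, collapse = "")
    rcArm <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(arm)))
    s <- paste0(randomDnaStr(20), armMut, randomDnaStr(40), rcArm,
                randomDnaStr(20))
    got <- findInvertedRepeats(s, minLen = 20, minIdentity = 0.8,
                               maxArm = 60)
    oracle <- bruteInvertedRepeat(s, minLen = 20, minIdentity = 0.8,
                                  maxArm = 60)
    expect_false(is.null(oracle))
    expect_gt(nrow(got), 0)
    expect_identical(got$score[1], unname(oracle["score"]))
    expect_identical(got$leftStart[1], unname(oracle["i"]))
    expect_identical(got$length[1], unname(oracle["L"]))
  }
})

test_that("end-motif families classify by their terminal repeats", {
  expect_identical(classifyEndMotif("AGTAGTCC", "GGACTACT"), "AGT")
  expect_identical(classifyEndMotif("AGAGAGTT", "AACTCTCT"), "AG")
  expect_identical(classifyEndMotif("ACACACAT", "ATGTGTGT"), "AC")
  expect_identical(classifyEndMotif("TTTTTTTT", "AAAAAAAA"), "none")
  expect_error(classifyEndMotif("AGT", "ACT"), "7 bp")
})

test_that("perfect TSD verification is exact and flags missing flank", {
  s <- paste0("GATTCA", "AAAAAAA", "GATTCA")
  v <- verifyTsd(s, 7, 13)
  expect_true(v$perfect)
  expect_identical(v$tsd, "GATTCA")
  s2 <- paste0("GATTCA", "AAAAAAA", "GATTCC")
  expect_false(verifyTsd(s2, 7, 13)$perfect)
  expect_error(verifyTsd("ACGTACGT", 2, 5), "insufficient flank")
  imp <- fixImplant()
  expect_true(verifyTsd(imp$genome, imp$record$elementStart,
                        imp$record$elementEnd)$perfect)
})

test_that("profile frequencies follow additive smoothing arithmetic", {
  p0 <- buildTirProfile(rep(strrep("A", 200), 10), pseudocount = 0)
  expect_equal(unname(profileMatrix(p0)[, 1]), c(1, 0, 0, 0))
  p1 <- buildTirProfile(c(paste0("A", strrep("G", 199)),
                          paste0("C", strrep("G", 199))), pseudocount = 0)
  expect_equal(unname(profileMatrix(p1)[, 1]), c(0.5, 0.5, 0, 0))
  p2 <- buildTirProfile(c(strrep("A", 200), strrep("A", 200)),
                        pseudocount = 0.5)
  expect_equal(unname(profileMatrix(p2)[1, 1]), 2.5 / 4)
  expect_error(buildTirProfile(character(0)), "empty")
  expect_true(all(abs(colSums(profileMatrix(p2)) - 1) < 1e-9))
})

test_that("profile scanning: consensus maximum, empirical null, naive oracle", {
  set.seed(24)
  tirs <- replicate(8, {
    ch <- strsplit(randomDnaStr(200), "")[[1]]
    paste(ch, collapse = "")
  })
  base <- tirs[1]
  copies <- vapply(1:8, function(i)
    paste(mutateAt(strsplit(base, "")[[1]], sample(200, 10)),
          collapse = ""), character(1))
  prof <- buildTirProfile(copies)
  maxSc <- profileMaxScore(prof)
  # the consensus achieves the maximal score
  cons <- paste(c("A", "C", "G", "T")[apply(profileMatrix(prof), 2,
                                            which.max)], collapse = "")
  hit <- scanWithProfile(prof, paste0(randomDnaStr(150), cons,
                                      randomDnaStr(150)),
                         scoreThreshold = maxSc - 1e-6)
  expect_identical(hit$start, 151L)
  # uniform-random sequences stay below half the maximal score
  nullHits <- 0L
  for (i in 1:100) {
    h <- scanWithProfile(prof, randomDnaStr(600),
                         scoreThreshold = maxSc / 2)
    if (nrow(h) > 0) nullHits <- nullHits + 1L
  }
  expect_lte(nullHits, 5L)
  # naive rescan oracle on a 500-bp toy
  toy <- paste0(randomDnaStr(120), base, randomDnaStr(180))
  naive <- bruteProfileScores(profileMatrix(prof), toy)
  thr <- maxSc / 2
  got <- scanWithProfile(prof, toy, scoreThreshold = thr)
  fwd <- got[got$strand == "+", ]
  expect_identical(fwd$start, which(naive >= thr))
  expect_equal(fwd$score, naive[naive >= thr])
})

test_that("information content matches its analytic values and symmetry", {
  expect_equal(informationContentProfile(c("A", "A", "A", "A")), 2,
               tolerance = 1e-12)
  expect_equal(informationContentProfile(c("A", "C", "G", "T")), 0,
               tolerance = 1e-12)
  expect_equal(informationContentProfile(c("A", "A", "C", "C")), 1,
               tolerance = 1e-12)
  # label-permutation invariance
  aln <- c("ACGTAC", "AGGTAC", "ACGTTC", "ACGAAC")
  ic1 <- informationContentProfile(aln)
  ic2 <- informationContentProfile(chartr("ACGT", "GTAC", aln))
  expect_equal(ic1, ic2)
  expect_true(all(ic1 >= 0 & ic1 <= 2))
  # all-gap column is reported missing
  expect_true(is.na(informationContentProfile(c("-", "-"))))
})

test_that("terminus profiles round-trip through TSV", {
  set.seed(29)
  prof <- buildTirProfile(replicate(4, randomDnaStr(200)),
                          motifFamily = "AGT", species = "sp1")
  f <- tempfile(fileext = ".tsv")
  writeTirProfile(prof, f)
  back <- readTirProfile(f)
  expect_equal(profileMatrix(back), profileMatrix(prof),
               tolerance = 1e-12)
  expect_identical(motifFamily(back), "AGT")
  expect_identical(back@nSequences, 4L)
  unlink(f)
})

test_that("boundary mapping recovers exact implant coordinates", {
  imp <- fixImplant()
  b <- mapElementBoundaries(imp$genome)
  expect_identical(b$start, imp$record$elementStart)
  expect_identical(b$end, imp$record$elementEnd)
  expect_identical(b$family, "AGT")
  expect_true(b$tsdPerfect)
})

test_that("iterative refinement resolves motif-eroded copies and is monotone", {
  set.seed(30)
  el <- fixElement()
  n0 <- length(elementSeq(el))
  cands <- list()
  truths <- list()
  for (i in 1:5) {
    ch <- strsplit(as.character(elementSeq(el)), "")[[1]]
    ch <- mutateAt(ch, sample(n0, round(0.01 * n0)))
    if (i >= 4) {   # break every exact seed in both TIR copies
      ch <- mutateAt(ch, seq(1, 300, 7))
      ch <- mutateAt(ch, n0 - seq(1, 300, 7) + 1)
    }
    g <- generateHostGenome(6000, 0.42, seed = 600 + i)
    imp <- implantElement(g, paste(ch, collapse = ""), site = 3000)
    b <- mapElementBoundaries(imp$genome)
    resolved <- !is.null(b) && b$family != "none" && b$tsdPerfect
    cands[[i]] <- list(seq = as.character(imp$genome), species = "sp1",
                       start = if (resolved) b$start else NA,
                       end = if (resolved) b$end else NA,
                       family = if (resolved) b$family else NA,
                       resolved = resolved)
    truths[[i]] <- imp$record
  }
  expect_true(sum(vapply(cands, function(x) isTRUE(x$resolved),
                         logical(1))) >= 3)
  out <- iterativeRefinement(cands, maxRounds = 5)
  rounds <- attr(out, "rounds")
  for (i in 1:5) {
    expect_true(isTRUE(out[[i]]$resolved))
    expect_identical(out[[i]]$start, truths[[i]]$elementStart)
    expect_identical(out[[i]]$end, truths[[i]]$elementEnd)
  }
  # accepted set only grows and the loop reaches a fixpoint
  expect_true(all(diff(cumsum(rounds)) >= 0))
  expect_identical(rounds[length(rounds)], 0L)
  out2 <- iterativeRefinement(out, maxRounds = 1)
  expect_identical(attr(out2, "rounds"), 0L)
  # no seed annotations: unchanged with a warning
  blank <- lapply(cands, function(x) { x$resolved <- FALSE; x })
  expect_warning(iterativeRefinement(blank), "no seed annotations")
})

test_that("terminal motif positions are information-rich, host flanks are not", {
  set.seed(31)
  termini <- vapply(1:30, function(i) {
    el <- makeElement(elementBlueprint(totalLength = 12723L,
                                       tirLength = 150L),
                      geneProfiles = fixGeneProfiles(), seed = 700 + i)
    substr(as.character(elementSeq(el)), 1, 200)
  }, character(1))
  ic <- informationContentProfile(termini)
  expect_gt(mean(ic[1:6]), 1)
  flanks <- vapply(1:30, function(i) randomDnaStr(50), character(1))
  expect_lt(mean(informationContentProfile(flanks)), 0.3)
})
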