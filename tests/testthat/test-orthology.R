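# Flank-based orthology calling and lognormal age calibration.

test_that("flank extraction excludes TSD copies and clips at contig ends", {
  g <- generateHostGenome(200000, 0.5, seed = 40)
  fl <- extractFlanks(g, 50001, 60000, flank = 2000)
  expect_identical(length(fl$left), 2000L)
  expect_identical(length(fl$right), 2000L)
  expect_identical(as.character(fl$left),
                   as.character(Biostrings::subseq(g, 47995, 49994)))
  expect_identical(as.character(fl$right),
                   as.character(Biostrings::subseq(g, 60007, 62006)))
  edge <- extractFlanks(g, 501, 1500, flank = 2000)
  expect_true(edge$clippedLeft)
  expect_identical(length(edge$left), 494L)
  expect_true(edge$usable)
  none <- extractFlanks(g, 5, 1500, flank = 2000)
  expect_false(none$usable)
})

# shared simulated clade for the pairing tests
.orthoSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      host <- fix6TipHost()
      el <- paste0("AGTAGT", randomDnaStr(3000), "ACTACT")
      set.seed(41)
      cache <<- simulateOrthologousInsertions(
        host, el, c("A", "B"), flankDivergence = 0.05,
        locusLength = 9000, seed = 41)
    }
    cache
  }
})

lociFrom <- function(sim, tips) {
  out <- list()
  for (tip in tips) {
    tr <- sim$truth[sim$truth$tip == tip, ]
    if (!tr$carrier) next
    fl <- extractFlanks(sim$genomes[[tip]], tr$elementStart,
                        tr$elementEnd)
    out[[length(out) + 1L]] <- list(locusId = tip, genomeId = tip,
                                    left = fl$left, right = fl$right)
  }
  out
}

test_that("simulated orthologs pair by reciprocal flank hits", {
  sim <- .orthoSim()
  loci <- lociFrom(sim, c("A", "B", "C", "D", "E", "F"))
  pairs <- flankPairCandidates(loci)
  expect_identical(nrow(pairs), 1L)
  expect_setequal(c(pairs$locusA, pairs$locusB), c("A", "B"))
  expect_gte(pairs$leftIdentity, 0.7)
})

test_that("independent insertions in unrelated genomes do not pair", {
  set.seed(42)
  misses <- 0L
  for (i in 1:20) {
    l1 <- list(locusId = "x", genomeId = "g1",
               left = Biostrings::DNAString(randomDnaStr(2000)),
               right = Biostrings::DNAString(randomDnaStr(2000)))
    l2 <- list(locusId = "y", genomeId = "g2",
               left = Biostrings::DNAString(randomDnaStr(2000)),
               right = Biostrings::DNAString(randomDnaStr(2000)))
    if (nrow(flankPairCandidates(list(l1, l2))) > 0) misses <- misses + 1L
  }
  expect_lte(misses, 1L)
})

test_that("a one-sided flank hit is not a candidate", {
  sim <- .orthoSim()
  loci <- lociFrom(sim, c("A", "B"))
  set.seed(43)
  loci[[2]]$right <- Biostrings::DNAString(randomDnaStr(2000))
  expect_identical(nrow(flankPairCandidates(loci)), 0L)
})

test_that("colinearity scores identical, diverged and shuffled loci", {
  sim <- .orthoSim()
  ga <- as.character(sim$genomes[["A"]])
  gb <- as.character(sim$genomes[["B"]])
  idSelf <- colinearityCheck(ga, ga, c(2000, 2000), c(2000, 2000))
  expect_equal(idSelf$score, 1)
  expect_true(idSelf$accept)
  div <- colinearityCheck(ga, gb, c(2000, 2000), c(2000, 2000))
  expect_true(div$accept)
  set.seed(44)
  shuf <- paste(sample(strsplit(ga, "")[[1]]), collapse = "")
  bad <- colinearityCheck(ga, shuf, c(2000, 2000), c(2000, 2000))
  expect_lt(bad$score, 0.1)
  expect_false(bad$accept)
  tiny <- colinearityCheck("ACGT", ga, c(1, 1), c(2000, 2000))
  expect_false(tiny$accept)
  expect_match(tiny$reason, "shorter")
})

test_that("ortholog grouping is transitive, size-filtered and order-stable", {
  pairs <- data.frame(locusA = c("a", "b", "x"),
                      locusB = c("b", "c", "y"))
  g <- groupOrthologs(pairs)
  expect_identical(g, list(c("a", "b", "c"), c("x", "y")))
  shuffled <- pairs[c(3, 1, 2), ]
  expect_identical(groupOrthologs(shuffled), g)
  expect_identical(groupOrthologs(pairs[0, ]), list())
})

test_that("group ages equal the carriers' deepest tabulated divergence", {
  ages <- data.frame(taxonA = c("A", "A", "B"), taxonB = c("B", "C", "C"),
                     mean = c(50, 120, 120), lower = c(40, 100, 100),
                     upper = c(65, 140, 140))
  a <- orthologGroupAge(c("A", "B"), ages)
  expect_equal(a$mean, 50)
  b <- orthologGroupAge(c("A", "B", "C"), ages)
  expect_equal(b$mean, 120)
  expect_error(orthologGroupAge(c("A", "Z"), ages), "lacks")
})

test_that("end-to-end ortholog recovery across seeded clades", {
  host <- fix6TipHost()
  ok <- 0L
  nRep <- 20L
  for (i in seq_len(nRep)) {
    carriers <- list(c("A", "B"), c("C", "D"), c("A", "B", "C", "D"),
                     c("E", "F"))[[(i %% 4) + 1]]
    el <- paste0("AGTAGT", randomDnaStr(2500), "ACTACT")
    sim <- simulateOrthologousInsertions(host, el, carriers,
                                         flankDivergence = 0.05,
                                         locusLength = 8000,
                                         seed = 800 + i)
    loci <- lociFrom(sim, host$tip.label)
    pairs <- flankPairCandidates(loci)
    groups <- groupOrthologs(pairs)
    if (length(groups) == 1L && setequal(groups[[1]], carriers))
      ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * nRep))
})

test_that("lognormal calibration matches the mean and minimally covers", {
  cal <- lognormalCalibration(100, 80, 125)
  expect_equal(exp(cal@meanlog + cal@sdlog^2 / 2), 100, tolerance = 1e-6)
  q <- qlnorm(c(0.025, 0.975), cal@meanlog, cal@sdlog)
  expect_lte(q[1], 80 + 1e-6)
  expect_gte(q[2], 125 - 1e-6)
  # shrinking sigma by 1% breaks containment (minimality)
  s2 <- cal@sdlog * 0.99
  mu2 <- log(100) - s2^2 / 2
  expect_false(qlnorm(0.025, mu2, s2) <= 80 &&
               qlnorm(0.975, mu2, s2) >= 125)
  # widening the upper bound strictly increases sigma
  wider <- lognormalCalibration(100, 80, 150)
  expect_gt(wider@sdlog, cal@sdlog)
  expect_error(lognormalCalibration(100, 120, 150), "lower < mean")
})
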