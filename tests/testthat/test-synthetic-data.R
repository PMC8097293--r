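# Synthetic genomes, elements, implants and simulators.

test_that("host genome generation is seeded, GC-calibrated and validated", {
  g1 <- generateHostGenome(100, 0.5, seed = 7)
  g2 <- generateHostGenome(100, 0.5, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g <- generateHostGenome(10000, 0.41, seed = 1)
  gc <- Biostrings::letterFrequency(g, "GC", as.prob = TRUE)[1]
  expect_lt(abs(gc - 0.41), 0.02)     # binomial CI at n = 10000
  expect_error(generateHostGenome(0, 0.5, seed = 1), "positive")
  expect_error(generateHostGenome(100, 1.2), "between")
})

test_that("elements start and end with the family end-motifs", {
  for (fam in c("AGT", "AG", "AC")) {
    el <- makeElement(elementBlueprint(totalLength = 12723L,
                                       tirLength = 150L,
                                       endMotifFamily = fam),
                      geneProfiles = fixGeneProfiles(), seed = 3)
    s <- as.character(elementSeq(el))
    exp5 <- c(AGT = "AGTAGT", AG = "AGAGAG", AC = "ACACACA")[[fam]]
    exp3 <- c(AGT = "ACTACT", AG = "CTCTCT", AC = "TGTGTGT")[[fam]]
    expect_identical(substr(s, 1, nchar(exp5)), exp5)
    expect_identical(substr(s, nchar(s) - nchar(exp3) + 1, nchar(s)), exp3)
    # TIRs are exact reverse complements
    tirs <- elementFeatures(el)
    tirs <- tirs[tirs$type == "terminal_inverted_repeat", ]
    t5 <- substr(s, tirs$start[1], tirs$end[1])
    t3 <- substr(s, tirs$start[2], tirs$end[2])
    expect_identical(t3, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(t5))))
  }
})

test_that("every annotated ORF translates without internal stops", {
  el <- fixElement()
  s <- elementSeq(el)
  genes <- elementFeatures(el)
  genes <- genes[genes$type == "gene", ]
  expect_identical(sort(genes$id),
                   sort(c("ppolb", "atp", "pm", "pz", "int", "mcp", "pw",
                          "Mcp", "pro")))
  for (k in seq_len(nrow(genes))) {
    dna <- Biostrings::subseq(s, genes$start[k], genes$end[k])
    if (genes$strand[k] == "-") dna <- Biostrings::reverseComplement(dna)
    aa <- as.character(Biostrings::translate(dna))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("blueprints reject impossible layouts and out-of-range sizes", {
  expect_error(elementBlueprint(totalLength = 12000L), "12723")
  expect_error(elementBlueprint(tirLength = 20L), "46")
  expect_error(elementBlueprint(totalLength = 12723L, tirLength = 300L,
                                accessoryLengths = c(0L, 0L)),
               "layout error")
})

test_that("degradation lesions are counted, logged and reversible to identity", {
  el <- fixElement()
  same <- degradeElement(el, 0, 0, integer(0), FALSE, seed = 1)
  expect_identical(as.character(elementSeq(same)),
                   as.character(elementSeq(el)))
  one <- degradeElement(el, nStops = 1, seed = 5)
  expect_identical(elementLesions(one)$type, "stop_codon")
  # the stop lands inside the recorded gene, in frame
  les <- elementLesions(one)
  gene <- elementFeatures(one)
  gene <- gene[gene$type == "gene" & gene$id == les$gene, ]
  expect_true(les$position >= gene$start && les$position <= gene$end)
  expect_error(degradeElement(el, nStops = 1e6), "more lesions")
})

test_that("implants duplicate the 6-mer preceding the site", {
  out <- implantElement("AAAAAACGTCGT", "TTTT", site = 12)
  expect_identical(as.character(out$genome), "AAAAAACGTCGTTTTTCGTCGT")
  expect_identical(out$record$tsd, "CGTCGT")
  g <- generateHostGenome(500, 0.5, seed = 2)
  el <- "ACGTACGTACGT"
  res <- implantElement(g, el, site = 250)
  expect_identical(length(res$genome), 500L + nchar(el) + 6L)
  v <- verifyTsd(res$genome, res$record$elementStart,
                 res$record$elementEnd)
  expect_true(v$perfect)
  expect_identical(v$tsd, res$record$tsd)
  # excising the element plus one TSD copy restores the original genome
  s <- as.character(res$genome)
  restored <- paste0(substr(s, 1, res$record$site),
                     substr(s, res$record$elementEnd + 7, nchar(s)))
  expect_identical(restored, as.character(g))
  expect_error(implantElement(g, el, site = 3), "site")
})

test_that("orthologous insertions share position; zero divergence gives identical flanks", {
  host <- fix6TipHost()
  el <- "ATGCATGCATGCATGCATGCA"
  sim <- simulateOrthologousInsertions(host, el, c("A", "B"),
                                       flankDivergence = 0,
                                       locusLength = 2000, seed = 4)
  tr <- sim$truth
  expect_identical(tr$carrier, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  ga <- as.character(sim$genomes[["A"]])
  gb <- as.character(sim$genomes[["B"]])
  expect_identical(ga, gb)              # zero-rate limit
  st <- tr$elementStart[1]
  expect_identical(substr(ga, st, st + nchar(el) - 1L), el)
  expect_error(simulateOrthologousInsertions(host, el, c("A", "ZZZ")),
               "unknown clade")
})

test_that("codon simulation honours omega = 0 and zero branch lengths", {
  tree <- ape::read.tree(text = "(a:0.4,b:0.4);")
  aln <- simulateCodonAlignment(tree, omega = 0, kappa = 2,
                                nCodons = 300, seed = 8)
  gc <- Biostrings::GENETIC_CODE
  aa <- apply(aln, 1, function(r) paste(gc[r], collapse = ""))
  expect_identical(aa[["a"]], aa[["b"]])  # all differences synonymous
  expect_gt(sum(aln["a", ] != aln["b", ]), 0)
  tree0 <- ape::read.tree(text = "(a:0,b:0);")
  aln0 <- simulateCodonAlignment(tree0, omega = 1, kappa = 2,
                                 nCodons = 50, seed = 8)
  expect_identical(aln0["a", ], aln0["b", ])
  expect_error(simulateCodonAlignment(tree, omega = -1, kappa = 2),
               "omega")
  expect_error(simulateCodonAlignment(tree, omega = 1, kappa = 0),
               "kappa")
})

test_that("counting dN/dS on an omega = 1 simulated pair is near 1", {
  tree <- ape::read.tree(text = "(a:0.3,b:0.3);")
  # kappa = 1 so the uncorrected counting estimator is unbiased at
  # omega = 1 (transition bias would deflate pN/pS)
  aln <- simulateCodonAlignment(tree, omega = 1, kappa = 1,
                                nCodons = 3000, seed = 10)
  w <- bruteCountingOmega(aln["a", ], aln["b", ])
  expect_gt(w, 0.8)
  expect_lt(w, 1.25)
})

test_that("pure cospeciation copies the host topology; pure loss fails", {
  host <- fix6TipHost()
  s <- simulateCophylogeny(host, c(1, 0, 0, 0), seed = 2)
  expect_false(s$failed)
  para <- s$parasiteTree
  para$tip.label <- s$associations$host[match(para$tip.label,
                                              s$associations$parasite)]
  expect_identical(ape::dist.topo(ape::unroot(para), ape::unroot(host))[1],
                   0)
  expect_setequal(unique(s$eventLog$event), "cospeciation")
  s2 <- simulateCophylogeny(host, c(0, 0, 0, 1), seed = 2, maxRetries = 5)
  expect_true(s2$failed)
})

test_that("logged event frequencies match the generating probabilities", {
  host <- fix6TipHost()
  params <- c(0.55, 0.15, 0.2, 0.1)
  sims <- simulateCophylogeny(host, params, nParasites = 300, seed = 31,
                              maxRetries = 1)
  draws <- do.call(rbind, lapply(sims, `[[`, "allDraws"))
  n <- nrow(draws)
  freq <- table(factor(draws$event,
                       levels = c("cospeciation", "duplication",
                                  "host_switch", "loss"))) / n
  se <- sqrt(params * (1 - params) / n)
  expect_true(all(abs(as.numeric(freq) - params) <= 3 * se + 1e-9))
})

test_that("event probability vectors are validated", {
  expect_error(eventProbabilities(c(0.5, 0.5, 0.2, -0.2)), "\\[0, 1\\]")
  expect_error(eventProbabilities(c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  p <- eventProbabilities(c(0.25, 0.25, 0.25, 0.25))
  expect_named(p, c("cospeciation", "duplication", "host_switch", "loss"))
})
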