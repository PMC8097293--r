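# Core-ORF detection, intactness classification, architecture and
# summary statistics.

test_that("an intact element yields eight clean core ORFs plus pm", {
  orfs <- detectCoreOrfs(elementSeq(fixElement()),
                         geneProfiles = fixGeneProfiles())
  expect_setequal(orfs$gene, c("ppolb", "atp", "pm", "pz", "int", "mcp",
                               "pw", "Mcp", "pro"))
  expect_true(all(orfs$clean))
  expect_true(all(orfs$internalStops == 0L))
  expect_identical(nrow(detectCoreOrfs("", fixGeneProfiles())), 0L)
  expect_error(detectCoreOrfs("ACGT", NULL), "configuration error")
})

test_that("a premature stop is reported for the damaged gene", {
  el <- fixElement()
  fos <- degradeElement(el, nStops = 1, seed = 77)
  lesion <- elementLesions(fos)
  orfs <- detectCoreOrfs(elementSeq(fos), fixGeneProfiles())
  row <- orfs[orfs$gene == lesion$gene, ]
  expect_identical(nrow(row), 1L)
  expect_false(row$clean)
  expect_gte(row$internalStops, 1L)
  clean <- orfs[orfs$gene != lesion$gene & orfs$gene != "pm", ]
  expect_true(all(clean$clean))
})

test_that("intactness is the conjunction of ORFs, TIRs and a perfect TSD", {
  mkAnn <- function(orfs, tirNA = FALSE, tsdOk = TRUE)
    new("ElementAnnotation", locusId = "L", contig = "c", start = 1,
        end = 100,
        tirLeft = if (tirNA) c(NA_real_, NA_real_) else c(1, 50),
        tirRight = if (tirNA) c(NA_real_, NA_real_) else c(51, 100),
        motifFamily = "AGT", tsd = "ACGTAC", tsdPerfect = tsdOk,
        orfs = orfs, intact = FALSE, layout = "convergent",
        reasons = character(0))
  cleanOrfs <- data.frame(
    gene = c("ppolb", "atp", "pz", "pro", "Mcp", "pw", "mcp", "int"),
    strand = "+", start = 1, end = 3, hasStartCodon = TRUE,
    hasTerminalStop = TRUE, internalStops = 0L,
    frameshiftSuspected = FALSE, insertionSuspected = FALSE,
    profileScore = 999, coverage = 1, clean = TRUE)
  expect_true(isIntact(classifyIntactness(mkAnn(cleanOrfs))))
  noTir <- classifyIntactness(mkAnn(cleanOrfs, tirNA = TRUE))
  expect_false(isIntact(noTir))
  expect_true(any(grepl("no discernible TIRs", noTir@reasons)))
  badTsd <- classifyIntactness(mkAnn(cleanOrfs, tsdOk = FALSE))
  expect_false(isIntact(badTsd))
  # monotone: adding a lesion never converts fossil back to intact
  worse <- cleanOrfs
  worse$internalStops[3] <- 2L
  expect_false(isIntact(classifyIntactness(mkAnn(worse))))
  # seven genes suffice only under the Xenopus-like flag
  seven <- cleanOrfs[-1, ]
  expect_false(isIntact(classifyIntactness(mkAnn(seven))))
  expect_true(isIntact(classifyIntactness(mkAnn(seven),
                                          xenopusVariant = TRUE)))
})

test_that("module layouts classify as convergent, divergent or same strand", {
  for (ori in c("convergent", "divergent", "same_strand")) {
    el <- makeElement(elementBlueprint(totalLength = 12723L,
                                       tirLength = 150L,
                                       moduleOrientation = ori),
                      geneProfiles = fixGeneProfiles(), seed = 55)
    orfs <- detectCoreOrfs(elementSeq(el), fixGeneProfiles())
    expect_identical(validateArchitecture(orfs)$layout, ori)
  }
  expect_identical(
    validateArchitecture(data.frame(gene = "int", strand = "+",
                                    start = 1, end = 3))$layout,
    "unresolved")
})

test_that("copy-number summaries reproduce the published arithmetic", {
  counts <- data.frame(
    genome = c(paste0("tet", 1:4), paste0("tel", 1:13)),
    group = c(rep("tetrapod", 4), rep("teleost", 13)),
    n = c(2, 1, 1, 1, c(11, 38, 5, 1, 9, 2, 3, 25, 7, 13, 4, 6, 5)))
  s <- summarizeCopyNumbers(counts)
  tet <- s[s$group == "tetrapod", ]
  expect_equal(tet$mean, 1.25)
  expect_equal(tet$sd, 0.5)
  tel <- s[s$group == "teleost", ]
  expect_equal(tel$total, 129)
  expect_equal(tel$mean, 129 / 13, tolerance = 1e-12)
  # conservation: group mean times group size equals the total
  expect_equal(s$mean * s$genomes, s$total)
  single <- summarizeCopyNumbers(data.frame(genome = "g", group = "x",
                                            n = 5))
  expect_equal(single$mean, 5)
  expect_equal(single$median, 5)
  expect_true(is.na(single$sd))
  expect_identical(nrow(summarizeCopyNumbers(
    data.frame(genome = character(0), group = character(0),
               n = numeric(0)))), 0L)
})

test_that("size statistics report mean, sample SD and ranges", {
  s <- sizeStatistics(c(10, 10, 10))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 0)
  s2 <- sizeStatistics(c(12723, 24620), tirLengths = c(46, 1447))
  expect_equal(c(s2$min[1], s2$max[1]), c(12723, 24620))
  expect_equal(c(s2$min[2], s2$max[2]), c(46, 1447))
  expect_error(sizeStatistics(numeric(0)), "at least one")
})

test_that("intact/fossil calls match ground truth on mixed genomes", {
  profiles <- fixGeneProfiles()
  seeds <- fixSeeds()
  correct <- 0L
  nRep <- 12L
  for (i in seq_len(nRep)) {
    el <- makeElement(elementBlueprint(totalLength = 12723L,
                                       tirLength = 200L),
                      geneProfiles = profiles, seed = 90000 + i)
    isFossil <- i %% 2L == 0L
    if (isFossil) {
      kind <- (i %/% 2L) %% 3L
      el <- switch(as.character(kind),
        "0" = degradeElement(el, nStops = 2, seed = i),
        "1" = degradeElement(el, nFrameshifts = 1,
                             insertionLengths = 300L, seed = i),
        "2" = degradeElement(el, nStops = 1, erodeTirs = TRUE, seed = i))
    }
    g <- generateHostGenome(8000, 0.41, seed = 91000 + i)
    imp <- implantElement(g, el, site = 4000)
    anns <- annotateGenome(imp$genome, seeds = seeds,
                           geneProfiles = profiles)
    if (length(anns) == 1L && isIntact(anns[[1]]) == !isFossil)
      correct <- correct + 1L
  }
  expect_identical(correct, nRep)
})

test_that("annotations convert to GRanges for GFF3 export", {
  imp <- fixImplant()
  anns <- annotateGenome(imp$genome, seeds = fixSeeds(),
                         geneProfiles = fixGeneProfiles())
  gr <- annotationsToGRanges(anns)
  expect_s4_class(gr, "GRanges")
  expect_true("mobile_genetic_element" %in% gr$type)
  expect_true(sum(gr$type == "CDS") >= 8)
})
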