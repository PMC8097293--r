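# Event costs, reconciliation DP, switch labelling and rejection ABC.

unitCosts <- function() setNames(rep(1, 4), c("cospeciation",
  "duplication", "host_switch", "loss"))

test_that("the cost transform is -ln(p) with infinite cost at p = 0", {
  expect_equal(unname(probsToCosts(c(1, 0, 0, 0))[1]), 0)
  expect_equal(unname(probsToCosts(c(exp(-1), 1 - exp(-1), 0, 0))[1]), 1)
  costs <- probsToCosts(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(unname(costs), rep(log(4), 4))
  expect_identical(unname(probsToCosts(c(0.5, 0.5, 0, 0))[3:4]),
                   c(Inf, Inf))
})

test_that("congruent trees reconcile as pure cospeciation", {
  host <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  para <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  assoc <- data.frame(parasite = c("a", "b", "c"), host = c("A", "B", "C"))
  costs <- probsToCosts(c(0.25, 0.25, 0.25, 0.25))
  rec <- reconcile(host, para, assoc, costs)
  expect_equal(unname(eventCounts(rec)), c(2, 0, 0, 0))
  expect_equal(totalCost(rec), 2 * log(4), tolerance = 1e-9)
  expect_identical(labelSwitchBranches(rec, para),
                   rep("no_switch", nrow(para$edge)))
})

test_that("reconciliation equals brute-force enumeration on all small tree pairs", {
  costs <- probsToCosts(c(0.55, 0.2, 0.15, 0.1))
  tips3 <- c("A", "B", "C")
  hosts <- enumerateRootedTrees(tips3)
  paras <- enumerateRootedTrees(tolower(tips3))
  assoc <- data.frame(parasite = tolower(tips3), host = tips3)
  for (h in hosts) for (p in paras) {
    got <- totalCost(reconcile(h, p, assoc, costs))
    want <- bruteReconcileCost(h, p, assoc, costs)
    expect_equal(got, want, tolerance = 1e-6,
                 info = paste(ape::write.tree(h), ape::write.tree(p)))
  }
  # a sample of 4-tip pairs (the full 4-tip sweep runs in acceptance)
  tips4 <- c("A", "B", "C", "D")
  hosts4 <- enumerateRootedTrees(tips4)
  paras4 <- enumerateRootedTrees(tolower(tips4))
  assoc4 <- data.frame(parasite = tolower(tips4), host = tips4)
  set.seed(50)
  idx <- cbind(sample(length(hosts4), 8), sample(length(paras4), 8))
  for (k in seq_len(nrow(idx))) {
    h <- hosts4[[idx[k, 1]]]; p <- paras4[[idx[k, 2]]]
    expect_equal(totalCost(reconcile(h, p, assoc4, costs)),
                 bruteReconcileCost(h, p, assoc4, costs),
                 tolerance = 1e-6)
  }
})

test_that("total cost is invariant under host-tip relabelling", {
  host <- fix6TipHost()
  costs <- probsToCosts(c(0.6, 0.15, 0.15, 0.1))
  s <- simulateCophylogeny(host, c(0.6, 0.15, 0.15, 0.1), seed = 51)
  rec1 <- reconcile(host, s$parasiteTree, s$associations, costs)
  perm <- setNames(c("U", "V", "W", "X", "Y", "Z"), host$tip.label)
  host2 <- host
  host2$tip.label <- unname(perm[host$tip.label])
  assoc2 <- s$associations
  assoc2$host <- unname(perm[assoc2$host])
  rec2 <- reconcile(host2, s$parasiteTree, assoc2, costs)
  expect_equal(totalCost(rec1), totalCost(rec2), tolerance = 1e-9)
})

test_that("infinite switch cost forbids switches", {
  host <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  para <- ape::read.tree(text = "((a:1,c:1):1,b:2);")
  assoc <- data.frame(parasite = c("a", "b", "c"), host = c("A", "B", "C"))
  rec <- reconcile(host, para, assoc, probsToCosts(c(0.5, 0.25, 0, 0.25)))
  expect_equal(unname(eventCounts(rec)[["host_switch"]]), 0)
})

test_that("switch labels count switches and round-trip through Newick", {
  host <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  para <- ape::read.tree(text = "((a:1,c:1):1,b:2);")
  assoc <- data.frame(parasite = c("a", "b", "c"), host = c("A", "B", "C"))
  rec <- reconcile(host, para, assoc,
                   probsToCosts(c(0.25, 0.25, 0.25, 0.25)))
  labels <- labelSwitchBranches(rec, para)
  expect_identical(sum(labels == "switch"),
                   as.integer(eventCounts(rec)[["host_switch"]]))
  f <- tempfile(fileext = ".nwk")
  writeLabeledTree(para, labels, f)
  back <- readLabeledTree(f)
  expect_identical(back$tree$tip.label, para$tip.label)
  # same child node -> same label, regardless of edge order on disk
  childLabel <- function(tr, lab)
    lab[order(tr$edge[, 2])]
  expect_identical(childLabel(back$tree, back$labels),
                   childLabel(para, labels))
  unlink(f)
})

test_that("the R reconciliation and the C++ counts path agree", {
  host <- fix6TipHost()
  hi <- mavkit:::.hostIndex(host)
  set.seed(52)
  checked <- 0L
  for (i in 1:25) {
    s <- mavkit:::.simCophyloOnce(hi, eventProbabilities(
      c(0.5, 0.2, 0.2, 0.1)), 3, 200)
    if (s$failed || is.null(s$parasiteTree)) next
    rec <- reconcile(host, s$parasiteTree, s$associations, unitCosts())
    fast <- mavkit:::.reconcileCountsFast(hi, s$parasiteTree,
                                          s$associations, unitCosts())
    expect_equal(unname(eventCounts(rec)), unname(as.numeric(fast)))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("summary statistics are order-invariant and handle degenerate input", {
  host <- fix6TipHost()
  s <- simulateCophylogeny(host, c(0.8, 0.1, 0.05, 0.05), seed = 53)
  st1 <- summaryStatistics(host, s$parasiteTree, s$associations)
  shuffled <- s$associations[rev(seq_len(nrow(s$associations))), ]
  st2 <- summaryStatistics(host, s$parasiteTree, shuffled)
  expect_identical(st1, st2)
  single <- summaryStatistics(host, NULL,
                              data.frame(parasite = "P1", host = "A"))
  expect_equal(unname(single[3:6]), c(0, 0, 0, 0))
  expect_error(summaryStatistics(host, s$parasiteTree,
                                 s$associations[-1, ]), "unassociated")
})

test_that("ABC is deterministic under a fixed seed", {
  host <- fix6TipHost()
  obs <- simulateCophylogeny(host, c(0.7, 0.1, 0.15, 0.05),
                             nParasites = 3, seed = 54)
  ostats <- observedCophyloStats(host, obs, nParasites = 3)
  r1 <- abcRejection(ostats, host, nSims = 150, tolerance = 0.1,
                     rounds = 2, seed = 9, nParasites = 3)
  r2 <- abcRejection(ostats, host, nSims = 150, tolerance = 0.1,
                     rounds = 2, seed = 9, nParasites = 3)
  expect_identical(r1@accepted, r2@accepted)
})

test_that("posterior cospeciation mass is ordered along a truth grid", {
  host <- fix6TipHost()
  nPar <- 12L
  for (seedi in 1:3) {
    means <- vapply(c(0.5, 0.64, 0.8), function(pc) {
      rest <- (1 - pc) / 3
      obs <- simulateCophylogeny(host, c(pc, rest, rest, rest),
                                 nParasites = nPar, seed = 910 + seedi)
      ostats <- observedCophyloStats(host, obs, nParasites = nPar)
      res <- abcRejection(ostats, host, nSims = 800, tolerance = 0.1,
                          rounds = 3, seed = seedi, nParasites = nPar)
      posteriorMean(res)[["cospeciation"]]
    }, numeric(1))
    expect_false(is.unsorted(means))
  }
})

test_that("tolerance 1 ignores the data and zero-probability events stay low", {
  host <- fix6TipHost()
  obs <- simulateCophylogeny(host, c(0.7, 0.1, 0.15, 0.05),
                             nParasites = 3, seed = 55)
  ostats <- observedCophyloStats(host, obs, nParasites = 3)
  flat <- abcRejection(ostats, host, nSims = 400, tolerance = 1,
                       rounds = 1, seed = 10, nParasites = 3)
  # at tolerance 1 every surviving draw is accepted, so the result is the
  # survival-conditioned prior: identical for any observed data, and far
  # from degenerate in every class
  other <- ostats * 3 + 5
  flat2 <- abcRejection(other, host, nSims = 400, tolerance = 1,
                        rounds = 1, seed = 10, nParasites = 3)
  sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_identical(sortRows(flat@accepted), sortRows(flat2@accepted))
  expect_true(all(posteriorMean(flat) > 0.1 &
                  posteriorMean(flat) < 0.45))
  # observed data with no duplications at all: posterior duplication mass
  # stays small
  obs0 <- simulateCophylogeny(host, c(0.85, 0, 0, 0.15),
                              nParasites = 4, seed = 56)
  o0 <- observedCophyloStats(host, obs0, nParasites = 4)
  res0 <- abcRejection(o0, host, nSims = 600, tolerance = 0.1,
                       rounds = 3, seed = 11, nParasites = 4)
  expect_lt(posteriorMean(res0)[["duplication"]], 0.15)
  expect_lt(posteriorMean(res0)[["host_switch"]], 0.15)
})
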