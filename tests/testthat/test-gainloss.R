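test_that("traceChanges emits one event per changed branch", {
  # path root 0 -> internal 3 -> leaf 1: one gain and one loss
  m <- makeChar(c(a = 3L, b = 3L, c = 0L, d = 1L))
  tree <- ape::read.tree(text = "(((a,b),d),c);")
  rec <- ancestralStates(tree, m, rootState = 0L)
  ev <- traceChanges(rec)
  tal <- tallyGainLoss(ev)
  expect_true(all(ev$magnitude == abs(ev$to - ev$from)))
  expect_true(all(ev$direction[ev$to > ev$from] == "gain"))
  # implied length conserved: sum of magnitudes equals reconstruction length
  expect_equal(sum(ev$magnitude), rec$length)
  # constant character: zero events
  const <- makeChar(c(a = 2L, b = 2L, c = 2L, d = 2L))
  rec0 <- ancestralStates(ape::read.tree(text = "((a,b),(c,d));"), const,
                          rootState = 0L)
  ev0 <- traceChanges(rec0)
  expect_equal(nrow(ev0), 0L)
  # but the polarization edge can be included on request
  ev0r <- traceChanges(rec0, includeRootEdge = TRUE)
  expect_equal(nrow(ev0r), 1L)
  expect_equal(ev0r$from, 0L)
  expect_equal(ev0r$to, 2L)
})

test_that("tallies classify families by the sign of the net", {
  ev <- data.frame(css = c("x", "x", "x", "y", "y"),
                   parent = 1L, child = 2L, from = 0L,
                   to = c(1L, 1L, -0L, 1L, 0L),
                   direction = c("gain", "gain", "loss", "gain", "loss"),
                   magnitude = c(1L, 1L, 1L, 2L, 2L))
  rec <- tallyGainLoss(ev, chars = c("x", "y", "z"))
  expect_equal(rec$gains, c(2L, 1L, 0L))
  expect_equal(rec$losses, c(1L, 1L, 0L))
  expect_equal(rec$net, c(1L, 0L, 0L))
  expect_equal(rec$class, c("gained", "unchanged", "unchanged"))
  w <- tallyGainLoss(ev, chars = c("x", "y"), magnitudeWeighted = TRUE)
  expect_equal(w$gains, c(2L, 2L))
  expect_equal(w$losses, c(1L, 2L))
})

test_that("event counts match the exhaustive oracle on small trees", {
  set.seed(303)
  for (case in 1:15) {
    n <- sample(4:6, 1)
    x <- setNames(sample(0:4, n, replace = TRUE), letters[seq_len(n)])
    tree <- ape::rtree(n, br = NULL, tip.label = names(x))
    rec <- ancestralStates(tree, makeChar(x), rootState = 0L)
    got <- tallyGainLoss(traceChanges(rec))
    oracle <- oracleTally(tree, oracleReconstruction(tree, x, rootState = 0L))
    expect_equal(got$gains, unname(oracle["gains"]))
    expect_equal(got$losses, unname(oracle["losses"]))
    # gains + losses never exceed the branch count
    expect_lte(got$gains + got$losses, nrow(tree$edge))
  }
})

test_that("ratio summaries follow the stated arithmetic", {
  rec <- data.frame(css = c("x", "y"), gains = c(3L, 1L), losses = c(1L, 1L),
                    net = c(2L, 0L), class = c("gained", "unchanged"),
                    model = "abundance")
  s <- ratioSummary(rec)
  expect_equal(s$totalGains, 4L)
  expect_equal(s$totalLosses, 2L)
  expect_equal(s$ratio, 2)
  expect_false(s$infinite)
  # equal totals give 1.00
  rec$losses <- rec$gains
  expect_equal(ratioSummary(rec)$ratio, 1)
  # zero losses flag infinite, not a number
  rec$losses <- c(0L, 0L)
  s0 <- ratioSummary(rec)
  expect_true(s0$infinite)
  expect_true(is.na(s0$ratio))
})

test_that("epoch binning attributes all of a family's events to its nd age", {
  rec <- data.frame(css = c("x", "y", "z"),
                    gains = c(10L, 6L, 2L), losses = c(5L, 3L, 4L),
                    net = c(5L, 3L, -2L),
                    class = c("gained", "gained", "lost"),
                    model = "abundance")
  nd <- c(x = 0.05, y = 0.3, z = 0.8)
  s <- ratioSummary(rec, ndMap = nd)
  expect_equal(s$perEpoch$gains, c(10L, 6L, 2L))
  expect_equal(s$perEpoch$losses, c(5L, 3L, 4L))
  expect_equal(s$perEpoch$ratio, c(2, 2, 0.5))
  # epoch triples sum to the totals
  expect_equal(sum(s$perEpoch$gains), s$totalGains)
  expect_equal(sum(s$perEpoch$losses), s$totalLosses)
  # merged-epoch ratio is the ratio of summed counts, not a mean of ratios
  merged <- sum(s$perEpoch$gains[1:2]) / sum(s$perEpoch$losses[1:2])
  expect_equal(merged, 2)
  expect_error(ratioSummary(rec, ndMap = nd[1:2]), "nd missing")
})

test_that("superkingdom analysis recomputes changes on the pruned tree", {
  cfg <- simulationConfig(nPerSuperkingdom = c(A = 5L, B = 5L, E = 5L),
                          nFamilies = 40L, seed = 11L)
  sim <- simulateDomainHistories(simulateTaxonTree(cfg), cfg)
  coded <- encodeAbundance(sim$census)
  ana <- superkingdomAnalysis(coded, sim$tree, "B")
  expect_equal(sort(ana$taxa), sort(grep("^B", rownames(codedStates(coded)),
                                         value = TRUE)))
  expect_true(all(ana$tree$tip.label %in% ana$taxa))
  # families absent from every kept taxon are dropped
  S_b <- codedStates(coded)[ana$taxa, , drop = FALSE]
  expect_setequal(ana$records$css, colnames(S_b)[colSums(S_b > 0) > 0])
  # conservation: sum of per-family nets equals gains - losses
  expect_equal(sum(ana$records$net),
               ana$summary$totalGains - ana$summary$totalLosses)
  # a clade identical for a family yields no events for it
  uniform <- names(which(apply(S_b, 2, function(v) length(unique(v)) == 1) &
                           colSums(S_b) > 0))
  if (length(uniform)) {
    sub <- ana$records[ana$records$css %in% uniform, ]
    expect_true(all(sub$gains + sub$losses == 0L))
  }
  expect_error(superkingdomAnalysis(coded, sim$tree, "A",
                                    mode = "re_search", seed = 1L), NA)
  few <- makeCoded(matrix(c(0L, 1L, 1L, 0L), 2, 2), sk = c("A", "B"))
  expect_error(superkingdomAnalysis(few, sim$tree, "A"), "fewer than 4")
})

test_that("equal sampling is deterministic and balanced", {
  cfg <- simulationConfig(nPerSuperkingdom = c(A = 6L, B = 6L, E = 6L),
                          nFamilies = 30L, seed = 21L)
  sim <- simulateDomainHistories(simulateTaxonTree(cfg), cfg)
  coded <- encodeOccurrence(sim$census)
  r1 <- equalSamplingExperiment(coded, k = 4L, reps = 3L, seed = 5L)
  r2 <- equalSamplingExperiment(coded, k = 4L, reps = 3L, seed = 5L)
  expect_identical(r1$ratios, r2$ratios)
  expect_identical(r1$medians, r2$medians)
  expect_equal(dim(r1$ratios), c(3L, 3L))
  expect_error(equalSamplingExperiment(coded, k = 10L, reps = 2L, seed = 1L),
               "fewer than k")
})

test_that("consensus sets keep only families classified alike in both models", {
  ab <- data.frame(css = c("p", "q", "r", "s"),
                   gains = c(3L, 0L, 2L, 1L), losses = c(1L, 2L, 3L, 1L),
                   net = c(2L, -2L, -1L, 0L),
                   class = c("gained", "lost", "lost", "unchanged"),
                   model = "abundance")
  oc <- data.frame(css = c("p", "q", "r", "s"),
                   gains = c(2L, 1L, 4L, 2L), losses = c(1L, 3L, 1L, 1L),
                   net = c(1L, -2L, 3L, 1L),
                   class = c("gained", "lost", "gained", "gained"),
                   model = "occurrence")
  cs <- consensusSets(ab, oc)
  expect_equal(cs$gainedBoth, "p")
  expect_equal(cs$lostBoth, "q")   # r disagrees, s unchanged in abundance
  same <- consensusSets(ab, ab)
  expect_setequal(same$gainedBoth, ab$css[ab$class == "gained"])
  expect_setequal(same$lostBoth, ab$css[ab$class == "lost"])
})
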