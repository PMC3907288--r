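test_that("wagnerLength matches hand-checked ordered-character examples", {
  m <- makeChar(c(a = 0L, b = 2L, c = 5L))
  expect_equal(wagnerLength(ape::read.tree(text = "((a,b),c);"), m)$total, 5)
  m2 <- makeChar(c(a = 0L, b = 23L, c = 0L, d = 23L))
  expect_equal(wagnerLength(ape::read.tree(text = "((a,b),(c,d));"), m2)$total, 46)
  const <- makeChar(c(a = 3L, b = 3L, c = 3L, d = 3L))
  expect_equal(wagnerLength(ape::read.tree(text = "((a,b),(c,d));"), const)$total, 0)
})

test_that("wagnerLength equals brute-force enumeration on random small cases", {
  set.seed(101)
  for (case in 1:40) {
    n <- sample(4:6, 1)
    x <- setNames(sample(0:5, n, replace = TRUE), letters[seq_len(n)])
    tree <- ape::rtree(n, br = NULL, tip.label = names(x))
    if (case %% 2 == 0) tree <- ape::unroot(tree)
    m <- makeChar(x)
    expect_equal(wagnerLength(tree, m)$total, bruteWagner(tree, x))
  }
})

test_that("score is invariant under re-rooting", {
  set.seed(5)
  x <- setNames(sample(0:9, 6, replace = TRUE), letters[1:6])
  m <- makeChar(x)
  tree <- ape::unroot(ape::rtree(6, br = NULL, tip.label = names(x)))
  base <- wagnerLength(tree, m)$total
  for (tip in letters[1:6]) {
    rr <- ape::root(tree, outgroup = tip, resolve.root = TRUE)
    expect_equal(wagnerLength(rr, m)$total, base)
  }
})

test_that("binary characters reduce to Fitch counts (phangorn cross-check)", {
  set.seed(21)
  for (case in 1:10) {
    n <- 7
    S <- matrix(sample(0:1, n * 5, replace = TRUE), n, 5,
                dimnames = list(letters[1:n], sprintf("a.%d.1.1", 1:5)))
    m <- makeCoded(S, model = "occurrence")
    tree <- ape::unroot(ape::rtree(n, br = NULL, tip.label = letters[1:n]))
    pd <- phangorn::phyDat(S, type = "USER", levels = 0:1)
    expect_equal(wagnerLength(tree, m)$total,
                 phangorn::fitch(tree, pd))
  }
})

test_that("multistate scores agree with phangorn sankoff under linear costs", {
  set.seed(31)
  k <- 6L
  cost <- abs(outer(0:(k - 1), 0:(k - 1), "-"))
  dimnames(cost) <- list(0:(k - 1), 0:(k - 1))
  for (case in 1:8) {
    n <- 6
    S <- matrix(sample(0:(k - 1), n * 4, replace = TRUE), n, 4,
                dimnames = list(letters[1:n], sprintf("a.%d.1.1", 1:4)))
    m <- makeCoded(S)
    tree <- ape::unroot(ape::rtree(n, br = NULL, tip.label = letters[1:n]))
    pd <- phangorn::phyDat(S, type = "USER", levels = 0:(k - 1))
    expect_equal(wagnerLength(tree, m)$total,
                 unname(phangorn::sankoff(tree, pd, cost = cost)))
  }
})

test_that("informativeness matches exhaustive topology enumeration", {
  expect_true(bruteInformative(c(a = 0L, b = 0L, c = 1L, d = 2L)))
  expect_false(bruteInformative(c(a = 0L, b = 0L, c = 0L, d = 2L)))
  m <- makeCoded(rbind(c(0L, 0L, 3L), c(0L, 0L, 3L), c(1L, 0L, 3L),
                       c(2L, 2L, 3L)))
  rownames(codedStates(m))
  info <- parsimonyInformative(m)
  mask <- attr(info, "mask")
  expect_true(mask[["a.1.1.1"]])   # {0,0,1,2}
  expect_false(mask[["a.2.1.1"]])  # {0,0,0,2}
  expect_false(mask[["a.3.1.1"]])  # constant
  set.seed(41)
  for (case in 1:25) {
    n <- sample(4:5, 1)
    x <- setNames(sample(0:4, n, replace = TRUE), letters[seq_len(n)])
    got <- attr(parsimonyInformative(makeChar(x)), "mask")[[1]]
    expect_equal(got, bruteInformative(x), info = paste(x, collapse = ","))
  }
})

test_that("ancestral reconstruction is minimal and matches the policy oracle", {
  m <- makeCoded(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                        dimnames = list(letters[1:4], "a.1.1.1")),
                 model = "occurrence")
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  rec <- ancestralStates(tree, m, rootState = 0L)
  ev <- traceChanges(rec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "gain")
  expect_equal(rec$length, 1L)
  set.seed(77)
  for (case in 1:30) {
    n <- sample(4:6, 1)
    x <- setNames(sample(0:5, n, replace = TRUE), letters[seq_len(n)])
    tree <- ape::rtree(n, br = NULL, tip.label = names(x))
    m1 <- makeChar(x)
    for (policy in c("closest", "acctran")) {
      rec <- ancestralStates(tree, m1, policy = policy, rootState = 0L)
      expect_equal(rec$length, bruteWagner(tree, x))
      oracle <- oracleReconstruction(tree, x, rootState = 0L, policy = policy)
      expect_equal(unname(rec$states[, 1]), unname(oracle),
                   info = paste(policy, paste(x, collapse = ",")))
    }
  }
})

test_that("reconstruction length equals wagnerLength for every tie policy", {
  set.seed(13)
  S <- matrix(sample(0:9, 6 * 8, replace = TRUE), 6, 8,
              dimnames = list(letters[1:6], sprintf("a.%d.1.1", 1:8)))
  m <- makeCoded(S)
  tree <- ape::rtree(6, br = NULL, tip.label = letters[1:6])
  wl <- wagnerLength(tree, m)$total
  for (policy in c("closest", "deltran", "acctran")) {
    expect_equal(ancestralStates(tree, m, policy = policy)$length, wl)
  }
  expect_error(ancestralStates(ape::unroot(tree), m), "lundbergRoot")
})

test_that("Lundberg rooting picks the minimum-increase branch", {
  m <- makeChar(c(a = 0L, b = 1L, c = 1L))
  star <- ape::read.tree(text = "(a,b,c);")
  rooted <- lundbergRoot(star, m, 0L)
  lb <- attr(rooted, "lundberg")
  expect_equal(lb$increase, 0)
  # root splits 'a' from {b, c}
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("b", "c")))
  # enumeration oracle: appending the ancestor tip on each branch
  set.seed(55)
  for (case in 1:10) {
    n <- 5
    x <- setNames(sample(0:4, n, replace = TRUE), letters[1:n])
    tr <- ape::unroot(ape::rtree(n, br = NULL, tip.label = names(x)))
    m1 <- makeChar(x)
    rooted <- lundbergRoot(tr, m1, 0L)
    inc <- attr(rooted, "lundberg")$increase
    base <- bruteWagner(tr, x)
    # oracle minimum over attachments: add the ancestor as a tip on
    # every branch of the unrooted tree
    po <- stats::reorder(tr, "postorder")
    incs <- vapply(seq_len(nrow(po$edge)), function(e) {
      t2 <- domtrace:::.attachTip(po, po$edge[e, 1], po$edge[e, 2], "ANC")
      bruteWagner(t2, c(x, ANC = 0L)) - base
    }, numeric(1))
    expect_equal(inc, min(incs))
  }
})

test_that("all-ancestral matrices trigger the first-branch tie rule", {
  S <- matrix(0L, 4, 2, dimnames = list(letters[1:4],
                                        c("a.1.1.1", "a.2.1.1")))
  m <- makeCoded(S)
  tr <- ape::unroot(ape::rtree(4, br = NULL, tip.label = letters[1:4]))
  rooted <- lundbergRoot(tr, m, 0L)
  lb <- attr(rooted, "lundberg")
  expect_equal(lb$increase, 0)
  expect_true(lb$tie)
  expect_error(lundbergRoot(rooted, m, 0L), "unrooted")
  expect_error(lundbergRoot(tr, m, 24L), "0..")
})

test_that("search recovers a compatible-character topology homoplasy free", {
  set.seed(9)
  truth <- ape::unroot(ape::rtree(8, br = NULL,
                                  tip.label = sprintf("t%02d", 1:8)))
  S <- splitMatrix(truth, dup = 4L)
  m <- makeCoded(S, model = "occurrence")
  res <- parsimonySearch(m, searchConfig(nStarts = 2L), seed = 4L)
  expect_equal(ape::dist.topo(ape::unroot(res$tree), truth)[1], 0)
  expect_equal(res$stats$ri, 1)
})

test_that("search is deterministic and beats no start tree", {
  set.seed(15)
  S <- matrix(sample(0:9, 9 * 12, replace = TRUE), 9, 12,
              dimnames = list(letters[1:9], sprintf("a.%d.1.1", 1:12)))
  m <- makeCoded(S)
  r1 <- parsimonySearch(m, searchConfig(nStarts = 2L), seed = 8L)
  r2 <- parsimonySearch(m, searchConfig(nStarts = 2L), seed = 8L)
  expect_equal(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  expect_equal(r1$length, r2$length)
  # never longer than the NJ starting tree
  nj <- ape::nj(dist(S, method = "manhattan"))
  expect_lte(r1$length, wagnerLength(nj, m)$total)
  expect_error(parsimonySearch(makeCoded(S[1:3, ])), "4 taxa")
})

test_that("small searches attain the exhaustive optimum", {
  set.seed(23)
  for (case in 1:10) {
    S <- matrix(sample(0:5, 5 * 8, replace = TRUE), 5, 8,
                dimnames = list(letters[1:5], sprintf("a.%d.1.1", 1:8)))
    m <- makeCoded(S)
    heur <- parsimonySearch(m, searchConfig(nStarts = 2L, exhaustiveMax = 0L),
                            seed = case)
    tops <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
    best <- min(vapply(tops, function(t) wagnerLength(t, m)$total, numeric(1)))
    expect_equal(heur$length, best)
  }
})

test_that("fit statistics reproduce the retention-index worked examples", {
  m <- makeCoded(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                        dimnames = list(letters[1:4], "a.1.1.1")),
                 model = "occurrence")
  good <- fitStatistics(ape::read.tree(text = "((a,b),(c,d));"), m)
  expect_equal(good$ri, 1)        # S=1, M=1, G=2
  expect_equal(good$nInformative, 1L)
  bad <- fitStatistics(ape::read.tree(text = "((a,c),(b,d));"), m)
  expect_equal(bad$ri, 0)         # S=2
  const <- makeCoded(matrix(1L, 4, 1, dimnames = list(letters[1:4], "a.1.1.1")),
                     model = "occurrence")
  expect_true(is.na(fitStatistics(ape::read.tree(text = "((a,b),(c,d));"),
                                  const)$ri))
})

test_that("g1 is computed from the random-length distribution", {
  set.seed(17)
  truth <- ape::unroot(ape::rtree(8, br = NULL,
                                  tip.label = sprintf("t%02d", 1:8)))
  m <- makeCoded(splitMatrix(truth, dup = 4L), model = "occurrence")
  fs <- fitStatistics(truth, m, nRandomTrees = 60L, seed = 3L)
  # strong clean signal: length distribution is left skewed
  expect_lt(fs$g1, 0)
  fs2 <- fitStatistics(truth, m, nRandomTrees = 60L, seed = 3L)
  expect_equal(fs$g1, fs2$g1)
  expect_error(fitStatistics(truth, m, nRandomTrees = 10L), "seed")
})

test_that("bootstrap gives full support on conflict-free duplicated signal", {
  set.seed(19)
  truth <- ape::unroot(ape::rtree(6, br = NULL, tip.label = letters[1:6]))
  m <- makeCoded(splitMatrix(truth, dup = 10L), model = "occurrence")
  bs <- bootstrapSupport(m, truth, nReplicates = 20L, seed = 2L)
  expect_true(all(bs$support == 100))
  bs2 <- bootstrapSupport(m, truth, nReplicates = 20L, seed = 2L)
  expect_identical(bs$support, bs2$support)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_error(bootstrapSupport(m, truth, nReplicates = 0L), ">= 1")
})

test_that("pruning yields induced subtrees with consistent quartets", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::write.tree(pruneToTaxa(tree, c("a", "b"))), "(a,b);")
  full <- pruneToTaxa(tree, c("a", "b", "c", "d"))
  expect_equal(ape::dist.topo(ape::unroot(full), ape::unroot(tree))[1], 0)
  expect_error(pruneToTaxa(tree, c("a", "zz")), "zz")
  big <- ape::rtree(8, br = NULL, tip.label = letters[1:8])
  set.seed(3)
  for (case in 1:5) {
    quart <- sample(letters[1:8], 4)
    sub6 <- pruneToTaxa(big, sample(letters[1:8], 6))
    if (!all(quart %in% sub6$tip.label)) next
    q_direct <- pruneToTaxa(big, quart)
    q_via <- pruneToTaxa(sub6, quart)
    expect_equal(ape::dist.topo(ape::unroot(q_direct), ape::unroot(q_via))[1], 0)
  }
})
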