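test_that("characterMatrixFromComplements derives the six characters", {
  cm <- combineComplements()
  chm <- characterMatrixFromComplements(cm)
  expect_identical(nrow(chm), 35L)
  expect_true(all(chm$EGFR_PRESENT == as.integer(chm$EGFR_COUNT >= 1)))
  expect_true(all(chm$NRG_TYPE_PRESENT ==
                    as.integer(chm$NRG_TYPE_COUNT >= 1)))
  # incomplete rows (ligand columns unknown) are refused
  expect_error(
    characterMatrixFromComplements(bundledComplementMatrix("EGFR_TABLE")),
    "complete")
})

test_that("dolloReconstruct handles simple hand-checked cases", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  # present in a and b only: gain at their MRCA, no losses
  d <- dolloReconstruct(tr, c(a = 1, b = 1, c = 0, d = 0))
  expect_identical(gainNode(d), ape::getMRCA(tr, c("a", "b")))
  expect_identical(nrow(lossEdges(d)), 0L)
  # present everywhere but d: gain at the root, one loss on d's edge
  d2 <- dolloReconstruct(tr, c(a = 1, b = 1, c = 1, d = 0))
  expect_identical(gainNode(d2), ape::Ntip(tr) + 1L)
  expect_identical(lossEdges(d2)$child_label, "d")
  # single possessor: gain on the terminal edge
  d3 <- dolloReconstruct(tr, c(a = 0, b = 0, c = 1, d = 0))
  expect_identical(gainNode(d3), which(tr$tip.label == "c"))
  # errors
  expect_error(dolloReconstruct(tr, c(a = 0, b = 0, c = 0, d = 0)), "absent")
  expect_error(dolloReconstruct(tr, c(a = 2, b = 1, c = 0, d = 0)), "binary")
  expect_error(dolloReconstruct(tr, c(a = 1, b = 1, c = 0)), "no state")
  expect_error(dolloReconstruct(tr, c(1, 1, 0, 0)), "named")
})

test_that("dolloReconstruct works on polytomies", {
  tr <- ape::read.tree(text = "(a,b,c,(d,e));")
  d <- dolloReconstruct(tr, c(a = 0, b = 1, c = 1, d = 1, e = 0))
  expect_identical(gainNode(d), ape::Ntip(tr) + 1L)
  expect_setequal(lossEdges(d)$child_label, c("a", "e"))
  st <- nodeStates(d)
  expect_identical(st[seq_len(5)],
                   unname(c(a = 0L, b = 1L, c = 1L, d = 1L,
                            e = 0L)[tr$tip.label]))
})

test_that("sankoffCounts handles simple hand-checked cases", {
  tr <- ape::read.tree(text = "((a,b),c);")
  s <- sankoffCounts(tr, c(a = 1, b = 1, c = 1))
  expect_identical(unname(s@totalCost), 0)
  expect_true(all(nodeStates(s) == 1L))
  expect_identical(nrow(countEvents(s)), 0L)
  # ties break toward the smaller ancestral count
  s2 <- sankoffCounts(tr, c(a = 0, b = 2, c = 0))
  root <- ape::Ntip(tr) + 1L
  expect_identical(nodeStates(s2)[root], 0L)
  expect_identical(unname(s2@totalCost), 2)
  # expansions are increases from a non-zero ancestor
  tr2 <- ape::read.tree(text = "((a,b),(c,d));")
  s3 <- sankoffCounts(tr2, c(a = 1, b = 6, c = 1, d = 1))
  ex <- detectExpansions(s3)
  expect_identical(ex$child_label, "b")
  expect_identical(ex$from, 1L)
  expect_identical(ex$to, 6L)
  # errors
  expect_error(sankoffCounts(tr, c(a = -1, b = 0, c = 0)), "non-negative")
  expect_error(sankoffCounts(tr, c(a = 5, b = 0, c = 0), maxCount = 3),
               "maxCount")
})

test_that("Dollo agrees with exhaustive search on all small trees", {
  for (n in 4:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE)
    set.seed(n)
    for (k in seq_along(trees)) {
      tr <- trees[[k]]
      tr$edge.length <- NULL
      states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
      if (sum(states) == 0L) states[sample(n, 1)] <- 1L
      d <- dolloReconstruct(tr, states)
      o <- oracleDollo(tr, states)
      expect_identical(nrow(lossEdges(d)), o$losses,
                       info = ape::write.tree(tr))
      expect_identical(gainNode(d), o$gain, info = ape::write.tree(tr))
      # reconstructed states reproduce the tips
      expect_identical(nodeStates(d)[seq_len(n)], unname(states[tr$tip.label]))
    }
  }
})

test_that("Dollo agrees with exhaustive search on random larger trees", {
  for (i in 1:20) {
    n <- 6L + (i %% 3L)
    tr <- randomRootedTree(n, seed = 100 + i)
    set.seed(200 + i)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (sum(states) == 0L) states[1] <- 1L
    d <- dolloReconstruct(tr, states)
    o <- oracleDollo(tr, states)
    expect_identical(nrow(lossEdges(d)), o$losses)
    expect_identical(gainNode(d), o$gain)
  }
})

test_that("Sankoff agrees with exhaustive enumeration on small trees", {
  for (i in 1:20) {
    n <- 4L + (i %% 3L)
    tr <- randomRootedTree(n, seed = 300 + i)
    set.seed(400 + i)
    counts <- stats::setNames(sample(0:3, n, replace = TRUE), tr$tip.label)
    s <- sankoffCounts(tr, counts)
    o <- oracleSankoff(tr, counts)
    expect_identical(unname(s@totalCost), as.numeric(o$cost))
    root <- ape::Ntip(tr) + 1L
    expect_identical(nodeStates(s)[root], o$root)
    # the reported assignment realizes the reported cost
    st <- nodeStates(s)
    realized <- sum(abs(st[tr$edge[, 1]] - st[tr$edge[, 2]]))
    expect_identical(as.numeric(realized), unname(s@totalCost))
  }
})

test_that("Sankoff honours a custom cost matrix", {
  tr <- ape::read.tree(text = "((a,b),c);")
  # make gains free and losses expensive: root prefers the larger count
  cm <- matrix(0, 3, 3)
  for (p in 0:2) for (k in 0:2)
    cm[p + 1, k + 1] <- if (k >= p) 0 else 10 * (p - k)
  s <- sankoffCounts(tr, c(a = 0, b = 2, c = 0), maxCount = 2,
                     costMatrix = cm)
  expect_identical(unname(s@totalCost), 0)
  root <- ape::Ntip(tr) + 1L
  expect_identical(nodeStates(s)[root], 0L)
})

test_that("scenarioReport recovers the published ancestral scenario", {
  tree <- bundledSpeciesTree()
  chm <- characterMatrixFromComplements(combineComplements())
  scen <- scenarioReport(tree, chm)
  rc <- scen$rootComplement
  expect_identical(rc$node, c("Metazoa", "Bilateria"))
  expect_identical(rc$egfr_count, c(1L, 1L))
  expect_identical(rc$egf_type_count, c(1L, 1L))
  expect_identical(rc$nrg_type_count, c(0L, 1L))
  ev <- scen$events
  nrgGain <- ev[ev$character == "NRG_TYPE_PRESENT" & ev$type == "gain", ]
  expect_identical(nrgGain$node, "Bilateria")
  egfrLoss <- ev[ev$character == "EGFR_PRESENT" & ev$type == "loss", ]
  expect_setequal(egfrLoss$node, c("T_adhaerens", "Cnidaria", "L_squamata"))
  ex <- ev[ev$type == "expansion" & ev$character == "EGFR_COUNT", ]
  expect_true(any(ex$node == "H_robusta" & ex$from == 1L & ex$to == 6L))
  expect_true(any(ex$node == "M_lignano" & ex$from == 3L & ex$to == 8L))
})
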