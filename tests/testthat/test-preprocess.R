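# Pruning to shared accessions, collapsing coalescent allele groups,
# and leaf-set harmonization.

test_that("sharedAccessions intersects and rejects disjoint trees", {
  a <- parseNewick("((A|0,B|s),C|d);")
  b <- parseNewick("((B|0,C|s),D|d);")
  expect_equal(sharedAccessions(a, b), c("B", "C"))
  expect_equal(sharedAccessions(a, a), c("A", "B", "C"))
  d <- parseNewick("(X|0,Y|0);")
  expect_error(sharedAccessions(a, d), class = "amNoOverlapError")
})

test_that("pruning suppresses degree-2 nodes and sums their lengths", {
  t <- parseNewick("((A|0:0.1,B|s:0.1)90:0.2,C|d:0.3);")
  p <- pruneToAccessions(t, c("A", "C"))
  expect_equal(writeNewick(p), "(A|0:0.3,C|d:0.3);")
  expect_true(all(is.na(nodeSupport(p))))  # the 90% node no longer exists
  # pruning nothing is the identity
  q <- pruneToAccessions(t, c("A", "B", "C"))
  expect_equal(writeNewick(q), writeNewick(t))
  # pruning to one single-allele accession gives a single-leaf tree
  s <- pruneToAccessions(t, "C")
  expect_equal(tipLabels(s), "C|d")
  expect_equal(treePhylo(s)$edge.length, 0.3 + 0.2 * 0)  # pendant only
})

test_that("collapse replaces mono-accession clades by one branch", {
  c1 <- collapseMonoaccessionClades(
    parseNewick("((A|0:0.1,A|1:0.3):0.2,B|s:0.4);"))
  expect_equal(writeNewick(c1$tree), "(A|g1:0.3,B|s:0.4);")
  expect_equal(c1$report$members, "0,1")
  expect_equal(c1$report$representative, "0")  # depth tie broken by code
  expect_equal(c1$report$length, 0.3)

  # maximality: a nested three-allele clade collapses at once, the basal
  # member being the allele attached at the clade root
  c2 <- collapseMonoaccessionClades(
    parseNewick("(((A|0.0:0.1,A|0.1:0.1):0.1,A|1:0.2):0.3,B|s:0.1);"))
  expect_equal(writeNewick(c2$tree), "(A|g1:0.5,B|s:0.1);")
  expect_equal(c2$report$representative, "1")
  expect_equal(c2$report$length, 0.5)

  # no mono-accession clade: unchanged, empty report
  t <- parseNewick("((A|0:1,B|0:1):1,(A|1:1,B|1:1):1);")
  c3 <- collapseMonoaccessionClades(t)
  expect_equal(nrow(c3$report), 0L)
  expect_equal(writeNewick(c3$tree), writeNewick(t))
})

test_that("collapse is idempotent and confluent with pruning", {
  nwk <- "(((A|0:0.1,A|1:0.2)0.9:0.1,(B|0:0.3,(B|1.0:0.1,B|1.1:0.1)0.8:0.2)0.7:0.2)0.6:0.3,(C|s:0.5,D|d:0.5)0.5:0.1);"
  t <- parseNewick(nwk)
  once <- collapseMonoaccessionClades(t)
  twice <- collapseMonoaccessionClades(once$tree)
  expect_equal(writeNewick(twice$tree), writeNewick(once$tree))
  expect_equal(nrow(twice$report), 0L)

  keep <- c("A", "B", "C")
  viaPruneFirst <- collapseMonoaccessionClades(pruneToAccessions(t, keep))$tree
  viaCollapseFirst <- collapseMonoaccessionClades(
    pruneToAccessions(once$tree, keep))$tree
  expect_equal(rfDistance(viaPruneFirst, viaCollapseFirst), 0)
  expect_setequal(tipLabels(viaPruneFirst), tipLabels(viaCollapseFirst))
})

test_that("harmonization relabels matched pairs and equalizes leaf sets", {
  a <- parseNewick("((A|0:1,B|0:1):1,(A|1:1,B|1:1):1);")
  b <- parseNewick("((A|0:1,B|0:1):1,(A|1:1,B|1:1):1);")
  comb <- list(A = identityPairing("A", c("0", "1"), c("0", "1")),
               B = identityPairing("B", c("0", "1"), c("0", "1")))
  h <- harmonizeLeafSets(a, b, comb)
  expect_setequal(tipLabels(h$treeA), c("A#1", "A#2", "B#1", "B#2"))
  expect_setequal(tipLabels(h$treeA), tipLabels(h$treeB))
  expect_equal(rfDistance(h$treeA, h$treeB), 0)
})

test_that("duplicate mode expands a single allele into a zero-length cherry", {
  a <- parseNewick("((A|s:1,B|0:1):1,(C|0:1,B|1:1):1);")
  b <- parseNewick("((A|0:1,B|0:1):1,((A|1:1,C|0:1):1,B|1:1):1);")
  comb <- list(A = pairing("A", "s", "0", "A"),
               B = identityPairing("B", c("0", "1"), c("0", "1")),
               C = identityPairing("C", "0", "0"))
  h <- harmonizeLeafSets(a, b, comb, mode = "duplicate")
  expect_setequal(tipLabels(h$treeA), tipLabels(h$treeB))
  expect_true(all(c("A#1", "A#2") %in% tipLabels(h$treeA)))
  # the duplicated leaves form a zero-length cherry in tree A
  phy <- treePhylo(h$treeA)
  ia <- match(c("A#1", "A#2"), phy$tip.label)
  pend <- phy$edge.length[match(ia, phy$edge[, 2])]
  expect_equal(pend, c(0, 0))

  # prune mode instead drops the unmatched partner
  hp <- harmonizeLeafSets(a, b, comb, mode = "prune")
  expect_setequal(tipLabels(hp$treeA), tipLabels(hp$treeB))
  expect_false("A#2" %in% tipLabels(hp$treeA))
  expect_equal(length(tipLabels(hp$treeB)), 4L)
})

test_that("harmonization rejects combinations referencing unknown alleles", {
  a <- parseNewick("(A|0,B|0);")
  b <- parseNewick("(A|0,B|0);")
  comb <- list(A = pairing("A", "7", "0", "A"),
               B = identityPairing("B", "0", "0"))
  expect_error(harmonizeLeafSets(a, b, comb), class = "amMappingError")
  expect_error(harmonizeLeafSets(a, b, comb["A"]), class = "amMappingError")
})

test_that("prune+collapse leaves both trees on identical accession sets", {
  set.seed(4711)
  for (i in 1:5) {
    pair <- makePairedInstance(simConfig(nAccessions = 6, nNni = 2,
      lengthJitterSigma = 0.2, seed = 300 + i))
    shared <- sharedAccessions(pair$treeA, pair$treeB)
    a <- collapseMonoaccessionClades(
      pruneToAccessions(pair$treeA, shared))$tree
    b <- collapseMonoaccessionClades(
      pruneToAccessions(pair$treeB, shared))$tree
    expect_setequal(unique(tipAccession(a)), unique(tipAccession(b)))
  }
})
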