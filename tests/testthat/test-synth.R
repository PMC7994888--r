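# Synthetic paired-tree generator.

test_that("accession trees are binary, ultrametric and deterministic", {
  t2 <- simulateAccessionTree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  t5 <- simulateAccessionTree(5, seed = 1)
  expect_equal(length(t5$tip.label), 5L)
  expect_equal(t5$Nnode, 4L)
  expect_true(ape::is.binary(t5))
  expect_true(ape::is.ultrametric(t5))
  expect_true(all(t5$edge.length > 0))
  expect_identical(ape::write.tree(t5),
    ape::write.tree(simulateAccessionTree(5, seed = 1)))
  expect_error(simulateAccessionTree(1, seed = 1), class = "amConfigError")
})

test_that("allele expansion follows the hierarchical phasing nomenclature", {
  t <- simulateAccessionTree(5, seed = 2)
  force2 <- simConfig(nAccessions = 5, alleleCountProbs = c(0, 1, 0, 0),
    seed = 2)
  e2 <- expandAlleles(t, force2, "A")
  expect_length(tipLabels(e2$tree), 10L)
  expect_true(all(table(tipAccession(e2$tree)) == 2L))

  force1 <- simConfig(nAccessions = 5, alleleCountProbs = c(1, 0, 0, 0),
    seed = 2)
  e1 <- expandAlleles(t, force1, "A")
  expect_true(all(tipAllele(e1$tree) == "s"))

  force4 <- simConfig(nAccessions = 5, alleleCountProbs = c(0, 0, 0, 1),
    seed = 2)
  e4 <- expandAlleles(t, force4, "A")
  expect_true(all(table(tipAccession(e4$tree)) == 4L))
  for (acc in unique(tipAccession(e4$tree)))
    expect_setequal(tipAllele(e4$tree)[tipAccession(e4$tree) == acc],
      c("0.0", "0.1", "1.0", "1.1"))

  force3 <- simConfig(nAccessions = 5, alleleCountProbs = c(0, 0, 1, 0),
    seed = 2)
  e3 <- expandAlleles(t, force3, "A")
  for (acc in unique(tipAccession(e3$tree)))
    expect_setequal(tipAllele(e3$tree)[tipAccession(e3$tree) == acc],
      c("0", "1.0", "1.1"))
})

test_that("allele counts per accession and marker never exceed four", {
  for (s in 1:5) {
    pair <- makePairedInstance(simConfig(nAccessions = 7,
      alleleCountProbs = c(0.1, 0.2, 0.3, 0.4), seed = 900 + s))
    expect_lte(max(table(tipAccession(pair$treeA))), 4L)
    expect_lte(max(table(tipAccession(pair$treeB))), 4L)
  }
})

test_that("perturbation is a no-op at zero noise and local under one NNI", {
  pair <- makePairedInstance(simConfig(nAccessions = 6, seed = 31))
  base <- pair$treeA
  quiet <- simConfig(nAccessions = 6, nNni = 0, lengthJitterSigma = 0,
    seed = 31)
  p0 <- perturbTree(base, quiet, seed = 8)
  expect_equal(rfDistance(base, p0), 0)
  expect_equal(treePhylo(p0)$edge.length, treePhylo(base)$edge.length)

  one <- simConfig(nAccessions = 6, nNni = 1, seed = 31)
  for (s in 1:10) {
    p1 <- perturbTree(base, one, seed = s)
    expect_true(rfDistance(base, p1) %in% c(0, 2))
  }

  jit <- simConfig(nAccessions = 6, nNni = 0, lengthJitterSigma = 0.5,
    seed = 31)
  pj <- perturbTree(base, jit, seed = 3)
  expect_equal(rfDistance(base, pj), 0)
  expect_false(any(treePhylo(pj)$edge.length ==
    treePhylo(base)$edge.length))
})

test_that("paired instances are deterministic and carry coherent truth", {
  cfg <- simConfig(nAccessions = 6, nNni = 2, lengthJitterSigma = 0.2,
    plantedSwapFraction = 0.5, seed = 99)
  p1 <- makePairedInstance(cfg)
  p2 <- makePairedInstance(cfg)
  expect_identical(writeNewick(p1$treeA), writeNewick(p2$treeA))
  expect_identical(writeNewick(p1$treeB), writeNewick(p2$treeB))
  expect_identical(p1$truth, p2$truth)
  expect_setequal(p1$truth$accession,
    intersect(unique(tipAccession(p1$treeA)),
      unique(tipAccession(p1$treeB))))
  expect_true(all(p1$truth$swapped[p1$truth$truthVerdict == "swap"]))
  # swaps are only planted where they are observable
  expect_true(all(p1$truth$informative[p1$truth$swapped]))
})

test_that("no noise and no swaps means label-isomorphic trees", {
  pair <- makePairedInstance(simConfig(nAccessions = 6,
    plantedSwapFraction = 0, nNni = 0, lengthJitterSigma = 0, seed = 55))
  res <- linkAlleles(pair$treeA, pair$treeB, searchConfig(seed = 1))
  expect_equal(matchScore(res), 0)
  expect_true(all(verdicts(res)$verdict %in% c("keep", "equivocal")))
  # under the ground-truth (identity) combination the trees coincide
  expect_equal(bruteScan(pair$treeA, pair$treeB)$score, 0)
})
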