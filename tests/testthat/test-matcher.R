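# Pairing enumeration, the two optimization phases, and result reporting.

test_that("enumeratePairings counts and orders injective maps", {
  p2 <- enumeratePairings(c("0", "1"), c("0", "1"))
  expect_length(p2, 2L)
  expect_equal(vapply(p2, function(p) paste(p$to, collapse = ""),
    character(1)), c("01", "10"))
  expect_length(enumeratePairings("s", c("0", "1")), 2L)
  expect_length(enumeratePairings(c("0", "1"),
    c("0.0", "0.1", "1.0", "1.1")), 12L)
  # count = |larger|!/(|larger|-|smaller|)!, direction recorded
  p34 <- enumeratePairings(c("a", "b", "c", "x"), c("0", "1", "2"))
  expect_length(p34, 24L)
  expect_true(all(vapply(p34, function(p) p$smallerIn, character(1)) == "B"))
  expect_error(enumeratePairings(character(0), "0"), class = "amConfigError")
})

test_that("identityPairing maps equal codes to themselves, rest in order", {
  p <- identityPairing("X", c("0", "1"), c("0", "1"))
  expect_equal(p$to, c("0", "1"))
  p2 <- identityPairing("X", "s", c("0", "1"))
  expect_equal(p2$from, "s")
  expect_equal(p2$to, "0")
  p3 <- identityPairing("X", c("0", "1"), c("0", "1.0", "1.1"))
  expect_equal(p3$to, c("0", "1.0"))
})

test_that("applyCombination swaps exactly the focal accession's labels", {
  a <- parseNewick("((A|0:1,B|0:1)0.9:1,(A|1:1,B|1:1)0.9:1);")
  b <- parseNewick("((A|0:1,B|0:1)0.9:1,(A|1:1,B|1:1)0.9:1);")
  ident <- list(A = identityPairing("A", c("0", "1"), c("0", "1")),
                B = identityPairing("B", c("0", "1"), c("0", "1")))
  swapA <- ident
  swapA$A <- pairing("A", c("0", "1"), c("1", "0"), "A")
  h0 <- applyCombination(a, b, ident)
  h1 <- applyCombination(a, b, swapA)
  expect_equal(rfDistance(h0$treeA, h0$treeB), 0)
  # under the swap only A's two leaves exchange identity in tree B
  expect_equal(sort(tipLabels(h1$treeB)), sort(tipLabels(h0$treeB)))
  expect_gt(rfDistance(h1$treeA, h1$treeB), 0)
  # inputs are not modified
  expect_equal(tipLabels(a)[1], "A|0")
})

test_that("local phase retains the planted swap and identity elsewhere", {
  # tree B equals tree A with accession X's allele labels exchanged;
  # an anchor accession W breaks the global symmetry
  a <- parseNewick(paste0("(((W|s:1,X|0:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
    "(X|1:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
  b <- parseNewick(paste0("(((W|s:1,X|1:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
    "(X|0:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
  retained <- localOptimize(a, b, searchConfig(seed = 5))
  keyOf <- function(p) paste(p$to, collapse = "")
  expect_true("10" %in% vapply(retained$X, keyOf, character(1)))
  expect_true("01" %in% vapply(retained$Y, keyOf, character(1)))
  res <- globalOptimize(a, b, retained, searchConfig(seed = 5))
  v <- verdicts(res)
  expect_equal(v$verdict[v$accession == "X"], "swap")
  expect_equal(v$verdict[v$accession == "Y"], "keep")
  expect_equal(v$verdict[v$accession == "Z"], "keep")
  expect_equal(matchScore(res), 0)
})

test_that("ties in a fully symmetric instance are reported as equivocal", {
  a <- parseNewick("((X|0:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,(X|1:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);")
  b <- parseNewick("((X|1:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,(X|0:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);")
  res <- linkAlleles(a, b, searchConfig(seed = 1))
  expect_equal(matchScore(res), 0)
  expect_true(all(verdicts(res)$verdict == "equivocal"))
  expect_gte(length(combinations(res)), 2L)
  # the brute-force scan confirms the co-optima
  bs <- bruteScan(a, b)
  expect_equal(bs$score, 0)
  expect_true(all(lengths(bs$optKeys) >= 2L))
})

test_that("identical trees give score zero and keep everywhere", {
  pair <- makePairedInstance(simConfig(nAccessions = 5, seed = 11))
  res <- linkAlleles(pair$treeA, pair$treeA, searchConfig(seed = 2))
  expect_equal(matchScore(res), 0)
  expect_true(all(verdicts(res)$verdict %in% c("keep", "equivocal")))
  dj <- parseNewick("(Q|0,R|0);")
  expect_error(linkAlleles(pair$treeA, dj), class = "amNoOverlapError")
})

test_that("the optimum never scores worse than the identity combination", {
  for (s in 1:5) {
    pair <- makePairedInstance(simConfig(nAccessions = 6, nNni = 3,
      lengthJitterSigma = 0.3, plantedSwapFraction = 0.5, seed = 4000 + s))
    res <- linkAlleles(pair$treeA, pair$treeB, searchConfig(seed = s))
    shared <- sharedAccessions(pair$treeA, pair$treeB)
    cA <- collapseMonoaccessionClades(
      pruneToAccessions(pair$treeA, shared))$tree
    cB <- collapseMonoaccessionClades(
      pruneToAccessions(pair$treeB, shared))$tree
    accs <- sort(unique(tipAccession(cA)))
    ident <- setNames(lapply(accs, function(acc) identityPairing(acc,
      sort(tipAllele(cA)[tipAccession(cA) == acc]),
      sort(tipAllele(cB)[tipAccession(cB) == acc]))), accs)
    h <- applyCombination(cA, cB, ident)
    expect_lte(matchScore(res),
      weightedRfDistance(h$treeA, h$treeB) + 1e-9)
  }
})

test_that("the score is symmetric in the two input trees", {
  for (s in 1:3) {
    pair <- makePairedInstance(simConfig(nAccessions = 5, nNni = 2,
      lengthJitterSigma = 0.2, seed = 600 + s))
    r1 <- linkAlleles(pair$treeA, pair$treeB, searchConfig(seed = s))
    r2 <- linkAlleles(pair$treeB, pair$treeA, searchConfig(seed = s))
    expect_equal(matchScore(r1), matchScore(r2), tolerance = 1e-9)
  }
})

test_that("the mask-based scorer agrees with explicit tree surgery", {
  # mixed allele counts force per-combination pruning in the fast path
  for (s in 1:6) {
    pair <- makePairedInstance(simConfig(nAccessions = 5,
      alleleCountProbs = c(0.3, 0.4, 0.15, 0.15), nNni = 1,
      lengthJitterSigma = 0.2, seed = 5000 + s))
    res <- linkAlleles(pair$treeA, pair$treeB,
      searchConfig(seed = s, restarts = 15))
    expect_true(searchStats(res)$fastPath)
    expect_equal(matchScore(res), bruteScan(pair$treeA, pair$treeB)$score,
      tolerance = 1e-9)
  }
})

test_that("the global phase respects its capacity cap", {
  pair <- makePairedInstance(simConfig(nAccessions = 6,
    alleleCountProbs = c(0, 0, 0, 1), pDivergent = 1, seed = 13))
  expect_error(
    bruteForceMatch(pair$treeA, pair$treeB,
      searchConfig(globalCap = 10)),
    class = "amCapacityError")
})

test_that("concatenationPlan expands groups and duplicates singles", {
  # swap rows
  a <- parseNewick(paste0("(((W|s:1,X|0:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
    "(X|1:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
  b <- parseNewick(paste0("(((W|s:1,X|1:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
    "(X|0:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
  plan <- concatenationPlan(linkAlleles(a, b, searchConfig(seed = 3)))
  px <- plan[plan$accession == "X", ]
  expect_equal(nrow(px), 2L)
  expect_setequal(paste(px$alleleA, px$alleleB), c("0 1", "1 0"))

  # a single allele concatenated with both variants of the other marker
  a2 <- parseNewick("((A|s:1,B|0:1)0.9:1,(C|0:1,B|1:1)0.9:1);")
  b2 <- parseNewick("((A|0:1,B|0:1)0.9:1,((A|1:1,C|0:1)0.9:1,B|1:1)0.9:1);")
  res2 <- linkAlleles(a2, b2, searchConfig(seed = 1, mode = "duplicate"))
  p2 <- concatenationPlan(res2)
  pa <- p2[p2$accession == "A", ]
  expect_equal(nrow(pa), 2L)
  expect_equal(pa$alleleA, c("s", "s"))
  expect_setequal(pa$alleleB, c("0", "1"))

  # collapsed groups come back with their members listed
  a3 <- parseNewick("(((A|0:0.1,A|1:0.1)0.9:1,B|0:1)0.9:1,(C|s:1,B|1:1)0.9:1);")
  b3 <- parseNewick("((A|s:1,B|0:1)0.9:1,(C|s:1,B|1:1)0.9:1);")
  res3 <- linkAlleles(a3, b3, searchConfig(seed = 1))
  p3 <- concatenationPlan(res3)
  pa3 <- p3[p3$accession == "A", ]
  expect_equal(pa3$alleleA, "0")        # representative of the group
  expect_equal(pa3$membersA, "0,1")
  expect_equal(pa3$alleleB, "s")
})

test_that("identical inputs and seed give byte-identical serialization", {
  pair <- makePairedInstance(simConfig(nAccessions = 6, nNni = 2,
    lengthJitterSigma = 0.2, plantedSwapFraction = 0.5, seed = 77))
  j1 <- writeMatchResult(linkAlleles(pair$treeA, pair$treeB,
    searchConfig(seed = 9)))
  j2 <- writeMatchResult(linkAlleles(pair$treeA, pair$treeB,
    searchConfig(seed = 9)))
  expect_identical(j1, j2)
  j3 <- writeMatchResult(linkAlleles(pair$treeA, pair$treeB,
    searchConfig(seed = 10)))
  expect_type(j3, "character")
})
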