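# Independent oracles and fixture builders shared across the test files.
# The clade oracle enumerates rooted clades by leaf-set bitmask through its
# own recursion over the edge matrix, sharing no code with the package's
# clade machinery.

# All non-trivial rooted clades of a LabeledTree as bitmasks over `labels`,
# with stem length and child-node support.
oracleCladeTable <- function(tree, labels) {
  phy <- treePhylo(tree)
  sup <- nodeSupport(tree)
  n <- length(phy$tip.label)
  bit <- 2^(match(phy$tip.label, labels) - 1)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  stem <- rep(NA_real_, n + phy$Nnode)
  if (!is.null(phy$edge.length)) stem[phy$edge[, 2]] <- phy$edge.length
  rows <- list()
  rec <- function(v) {
    if (v <= n) return(list(mask = bit[v], size = 1L))
    ms <- lapply(kids[[as.character(v)]], rec)
    mask <- sum(vapply(ms, `[[`, numeric(1), "mask"))
    size <- sum(vapply(ms, `[[`, integer(1), "size"))
    if (size >= 2L && size < n)
      rows[[length(rows) + 1L]] <<- data.frame(mask = mask, size = size,
        length = stem[v], support = sup[v - n])
    list(mask = mask, size = size)
  }
  rec(n + 1L)
  if (!length(rows))
    return(data.frame(mask = numeric(), size = integer(),
      length = numeric(), support = numeric()))
  do.call(rbind, rows)
}

oracleRf <- function(treeA, treeB) {
  labels <- sort(tipLabels(treeA))
  a <- oracleCladeTable(treeA, labels)$mask
  b <- oracleCladeTable(treeB, labels)$mask
  sum(!(a %in% b)) + sum(!(b %in% a))
}

oracleWrf <- function(treeA, treeB, threshold = 0.5) {
  labels <- sort(tipLabels(treeA))
  eff <- function(tab) {
    data.frame(mask = tab$mask,
      sup = ifelse(is.na(tab$support), 1, tab$support),
      w = ifelse(is.na(tab$length), 0, tab$length) *
        ifelse(is.na(tab$support), 1, tab$support))
  }
  a <- eff(oracleCladeTable(treeA, labels))
  b <- eff(oracleCladeTable(treeB, labels))
  da <- !(a$mask %in% b$mask) & a$sup >= threshold
  db <- !(b$mask %in% a$mask) & b$sup >= threshold
  sum(a$w[da]) + sum(b$w[db])
}

# Random binary LabeledTree on shared leaf labels, with lengths in (0, 1)
# and supports in (0, 1); uses the current RNG stream.
randomLabeledTree <- function(nTips) {
  phy <- ape::rtree(nTips, tip.label = paste0("t", seq_len(nTips), "|d"))
  phy$node.label <- c("", sprintf("%.4f", runif(phy$Nnode - 1L)))
  parseNewick(ape::write.tree(phy))
}

# Exhaustive scan over ALL combinations through the public tree-surgery
# route; skips the local phase entirely. Returns the minimal weighted RF
# score and, per accession, the set of pairing keys found among the exact
# co-optima.
bruteScan <- function(treeA, treeB, mode = "prune",
                      metric = metricConfig()) {
  shared <- sharedAccessions(treeA, treeB)
  pA <- pruneToAccessions(treeA, shared)
  pB <- pruneToAccessions(treeB, shared)
  cA <- collapseMonoaccessionClades(pA)$tree
  cB <- collapseMonoaccessionClades(pB)$tree
  accOf <- function(t) tipAccession(t)
  accs <- sort(unique(accOf(cA)))
  pr <- lapply(accs, function(a) enumeratePairings(
    sort(tipAllele(cA)[accOf(cA) == a]),
    sort(tipAllele(cB)[accOf(cB) == a]), a))
  names(pr) <- accs
  grid <- expand.grid(lapply(pr, seq_along), KEEP.OUT.ATTRS = FALSE)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    comb <- setNames(lapply(accs, function(a) pr[[a]][[grid[i, a]]]), accs)
    h <- applyCombination(cA, cB, comb, mode)
    weightedRfDistance(h$treeA, h$treeB, metric)
  }, numeric(1))
  mn <- min(scores)
  opt <- which(scores <= mn + 1e-9)
  keys <- lapply(accs, function(a) unique(vapply(opt, function(i)
    format(pr[[a]][[grid[i, a]]]), character(1))))
  names(keys) <- accs
  list(score = mn, optKeys = keys)
}
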