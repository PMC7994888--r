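# Synthetic paired allele trees with known ground-truth pairings.

#' Configuration of the synthetic paired-tree generator
#'
#' The generator emulates the data situation of phased rDNA markers: a
#' shared accession history (a Yule tree), per-accession allele counts of
#' 1 to 4 per marker following the hierarchical phasing nomenclature
#' (`"s"`; `"0"`,`"1"`; `"0"`,`"1.0"`,`"1.1"`; `"0.0"`,`"0.1"`,`"1.0"`,
#' `"1.1"`), a per-accession choice between coalescent allele groups
#' (attached as shallow clades at the accession's position) and divergent
#' second lineages (grafted elsewhere on the tree, at the same point for
#' both markers, as concerted evolution leaves some accessions with
#' variants more similar to other species than to each other), and
#' controllable topological (NNI) and branch-length noise on tree B.
#'
#' @param nAccessions number of accessions (Yule tree leaves), at least 2.
#' @param alleleCountProbs probabilities of drawing 1, 2, 3 or 4 alleles
#'   per accession per marker (alleles are capped at 4 by the two-round
#'   phasing design).
#' @param pDivergent probability that an accession's second main allele
#'   lineage is divergent rather than coalescent.
#' @param nNni number of random rooted nearest-neighbor interchanges
#'   applied to tree B.
#' @param lengthJitterSigma sigma of the lognormal multiplier applied to
#'   tree B's branch lengths (0 = none).
#' @param supportModel either `list(type = "fixed", value = v)` or
#'   `list(type = "uniform", min = a, max = b)` on the `[0, 1]` scale.
#' @param plantedSwapFraction fraction of eligible (divergent, two-allele
#'   in both markers) accessions whose tree-B allele labels are permuted;
#'   the permutation is recorded as ground truth.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return list of class `"amSimConfig"`.
#' @export
simConfig <- function(nAccessions = 8L,
                      alleleCountProbs = c(0.35, 0.45, 0.10, 0.10),
                      pDivergent = 0.5, nNni = 0L, lengthJitterSigma = 0,
                      supportModel = list(type = "uniform", min = 0.5, max = 1),
                      plantedSwapFraction = 0.25, seed = 1L) {
  if (nAccessions < 2L)
    .amStop("amConfigError", "nAccessions must be at least 2")
  if (length(alleleCountProbs) != 4L || any(alleleCountProbs < 0) ||
      abs(sum(alleleCountProbs) - 1) > 1e-8)
    .amStop("amConfigError",
      "alleleCountProbs must be 4 non-negative probabilities summing to 1")
  if (nNni < 0L || lengthJitterSigma < 0 ||
      plantedSwapFraction < 0 || plantedSwapFraction > 1 ||
      pDivergent < 0 || pDivergent > 1)
    .amStop("amConfigError", "invalid noise/fraction parameter")
  if (!supportModel$type %in% c("fixed", "uniform"))
    .amStop("amConfigError", "supportModel$type must be 'fixed' or 'uniform'")
  structure(list(nAccessions = as.integer(nAccessions),
    alleleCountProbs = alleleCountProbs, pDivergent = pDivergent,
    nNni = as.integer(nNni), lengthJitterSigma = lengthJitterSigma,
    supportModel = supportModel,
    plantedSwapFraction = plantedSwapFraction, seed = as.integer(seed)),
    class = "amSimConfig")
}

.drawSupports <- function(k, model) {
  if (model$type == "fixed") rep(model$value, k)
  else stats::runif(k, model$min, model$max)
}

.simYule <- function(n) {
  phy <- ape::rphylo(n, birth = 1, death = 0)
  phy$tip.label <- sprintf("a%02d", seq_len(n))
  phy$node.label <- NULL
  phy
}

#' Simulate a pure-birth accession tree
#'
#' Yule-type rooted binary ultrametric tree with one leaf per accession
#' (labeled `a01`, `a02`, ...), exponential waiting times, strictly
#' positive branch lengths; deterministic per seed.
#'
#' @param n number of accessions, at least 2.
#' @param seed integer seed (optional; if `NULL` the current RNG is used).
#' @return an [ape::phylo] object.
#' @export
simulateAccessionTree <- function(n, seed = NULL) {
  if (n < 2L) .amStop("amConfigError", "need at least 2 accessions")
  .withSeed(seed, .simYule(as.integer(n)))
}

# Hierarchical allele codes for k alleles per the two-round phasing scheme.
# Returns a data.frame: code, lineage (0/1), sub (0/1).
.alleleScheme <- function(k) {
  switch(as.character(k),
    "1" = data.frame(code = "s", lineage = 0L, sub = 0L),
    "2" = data.frame(code = c("0", "1"), lineage = c(0L, 1L), sub = 0L),
    "3" = data.frame(code = c("0", "1.0", "1.1"), lineage = c(0L, 1L, 1L),
      sub = c(0L, 0L, 1L)),
    "4" = data.frame(code = c("0.0", "0.1", "1.0", "1.1"),
      lineage = c(0L, 0L, 1L, 1L), sub = c(0L, 1L, 0L, 1L)),
    .amStop("amConfigError", "allele count must be in 1..4"))
}

# Draw the shared allelic history: per-accession counts for both markers,
# divergent flag, and the (shared) graft location of the second lineage.
.makePlan <- function(T, config) {
  accs <- sort(T$tip.label)
  desc <- .descTips(T)
  below <- lapply(seq_len(nrow(T$edge)), function(e) {
    child <- T$edge[e, 2L]
    T$tip.label[desc[[child]]]
  })
  plan <- list()
  for (acc in accs) {
    kA <- sample.int(4L, 1L, prob = config$alleleCountProbs)
    kB <- sample.int(4L, 1L, prob = config$alleleCountProbs)
    divergent <- FALSE; graft <- NULL
    if (max(kA, kB) >= 2L) {
      divergent <- stats::runif(1) < config$pDivergent
      if (divergent) {
        # grafting on the accession's own pendant edge would just rebuild
        # a coalescent cherry, so that edge is never a divergence target
        cand <- which(!vapply(below, function(b) identical(b, acc), logical(1)))
        e <- if (length(cand) == 1L) cand else sample(cand, 1L)
        graft <- list(belowAccs = below[[e]],
          frac = stats::runif(1, 0.1, 0.9), origLen = T$edge.length[e])
      }
    }
    plan[[acc]] <- list(kA = kA, kB = kB, divergent = divergent,
      graft = graft)
  }
  plan
}

# Find the node carrying the clade of the given accessions in the current
# (partially expanded) tree. Only lineage-0 allele tips mark an
# accession's original position; divergent lineage-1 tips grafted
# elsewhere (codes "1", "1.0", "1.1") must not drag the MRCA away.
.findAttachNode <- function(phy, belowAccs) {
  lab <- .splitCanonical(phy$tip.label)
  tips <- which(lab$accession %in% belowAccs &
    !startsWith(lab$allele, "1"))
  if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
}

.stemOf <- function(phy, node) {
  e <- match(node, phy$edge[, 2L])
  if (is.na(e)) NA_real_ else phy$edge.length[e]
}

# Expand each accession leaf into its allele leaves for one marker, under a
# shared plan. Allele clades attach near the accession's position; a
# divergent second lineage is grafted at the plan's shared location with a
# pendant reaching the present (the tree is ultrametric before noise).
.expandWithPlan <- function(T, plan, marker) {
  phy <- T
  H <- max(ape::node.depth.edgelength(T)[seq_along(T$tip.label)])
  for (acc in sort(names(plan))) {
    p <- plan[[acc]]
    k <- if (marker == "A") p$kA else p$kB
    sch <- .alleleScheme(k)
    l0 <- sch$code[sch$lineage == 0L]
    l1 <- sch$code[sch$lineage == 1L]
    tipIdx <- which(phy$tip.label == acc)
    phy$tip.label[tipIdx] <- .canonicalLabel(acc, l0[1L])
    if (length(l1)) {
      lab1 <- .canonicalLabel(acc, l1[1L])
      if (p$divergent) {
        node <- .findAttachNode(phy, p$graft$belowAccs)
        stemLen <- .stemOf(phy, node)
        pos <- min(p$graft$frac * p$graft$origLen, 0.95 * stemLen)
        h <- ape::node.depth.edgelength(phy)[node]
        phy <- phytools::bind.tip(phy, lab1,
          edge.length = max(H - (h - pos), 1e-8), where = node,
          position = pos)
      } else {
        tip <- which(phy$tip.label == .canonicalLabel(acc, l0[1L]))
        d1 <- stats::runif(1, 0.02, 0.10) * H
        pos <- min(d1, 0.95 * .stemOf(phy, tip))
        phy <- phytools::bind.tip(phy, lab1, edge.length = pos,
          where = tip, position = pos)
      }
      if (length(l1) > 1L) {
        tip <- which(phy$tip.label == lab1)
        d2 <- stats::runif(1, 0.002, 0.02) * H
        pos <- min(d2, 0.5 * .stemOf(phy, tip))
        phy <- phytools::bind.tip(phy, .canonicalLabel(acc, l1[2L]),
          edge.length = pos, where = tip, position = pos)
      }
    }
    if (length(l0) > 1L) {
      tip <- which(phy$tip.label == .canonicalLabel(acc, l0[1L]))
      d2 <- stats::runif(1, 0.002, 0.02) * H
      pos <- min(d2, 0.5 * .stemOf(phy, tip))
      phy <- phytools::bind.tip(phy, .canonicalLabel(acc, l0[2L]),
        edge.length = pos, where = tip, position = pos)
    }
  }
  phy$node.label <- NULL
  phy
}

#' Expand accession leaves into allele leaves
#'
#' Replaces every leaf of a bare accession tree by 1 to 4 allele leaves
#' drawn per `config`, using the hierarchical phasing nomenclature.  The
#' allelic history (divergent-lineage placement) is derived
#' deterministically from `config$seed`, so calling this for markers
#' `"A"` and `"B"` on the same tree yields a shared history; only the
#' counts and the small attachment depths are marker-specific.
#'
#' @param tree an accession tree ([ape::phylo], e.g. from
#'   [simulateAccessionTree()]).
#' @param config an [simConfig()].
#' @param marker `"A"` or `"B"`.
#' @return list with `tree` (a [LabeledTree-class], supports unannotated)
#'   and `registry` (`data.frame`: accession, count, codes).
#' @export
expandAlleles <- function(tree, config, marker = c("A", "B")) {
  marker <- match.arg(marker)
  stopifnot(inherits(tree, "phylo"))
  plan <- .withSeed(config$seed, .makePlan(tree, config))
  phy <- .withSeed(config$seed + if (marker == "A") 101L else 202L,
    .expandWithPlan(tree, plan, marker))
  reg <- do.call(rbind, lapply(sort(names(plan)), function(acc) {
    k <- if (marker == "A") plan[[acc]]$kA else plan[[acc]]$kB
    data.frame(accession = acc, count = k,
      codes = paste(.alleleScheme(k)$code, collapse = ","),
      divergent = plan[[acc]]$divergent, stringsAsFactors = FALSE)
  }))
  list(tree = .lt(phy), registry = reg)
}

# One random rooted NNI: pick an internal non-root node v with parent u,
# exchange a random child of v with a random other child of u. Branch
# lengths travel with their subtrees; node numbering is unchanged.
.rootedNNI <- function(phy) {
  n <- length(phy$tip.label)
  root <- n + 1L
  internal <- setdiff(unique(phy$edge[, 1L]), root)
  cand <- internal[internal %in% phy$edge[, 2L]]
  if (!length(cand)) return(phy)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  u <- phy$edge[match(v, phy$edge[, 2L]), 1L]
  chRows <- which(phy$edge[, 1L] == v)
  sibRows <- setdiff(which(phy$edge[, 1L] == u), match(v, phy$edge[, 2L]))
  if (!length(sibRows)) return(phy)
  rc <- if (length(chRows) == 1L) chRows else sample(chRows, 1L)
  rs <- if (length(sibRows) == 1L) sibRows else sample(sibRows, 1L)
  phy$edge[rc, 1L] <- u
  phy$edge[rs, 1L] <- v
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Apply topological and branch-length noise to a tree
#'
#' Applies `nNni` random rooted nearest-neighbor interchanges, multiplies
#' every branch length by an independent lognormal(0, sigma) factor, and
#' (re)assigns internal-node supports from the support model.  With
#' `nNni = 0` and `lengthJitterSigma = 0` the topology and branch lengths
#' are returned unchanged.
#'
#' @param tree a [LabeledTree-class].
#' @param config an [simConfig()].
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return the perturbed [LabeledTree-class].
#' @export
perturbTree <- function(tree, config, seed = NULL) {
  stopifnot(is(tree, "LabeledTree"))
  .withSeed(seed, {
    phy <- tree@phy
    if (config$nNni > 0L)
      for (i in seq_len(config$nNni)) phy <- .rootedNNI(phy)
    if (config$lengthJitterSigma > 0 && !is.null(phy$edge.length))
      phy$edge.length <- phy$edge.length *
        exp(stats::rnorm(length(phy$edge.length), 0, config$lengthJitterSigma))
    .lt(phy, .drawSupports(phy$Nnode, config$supportModel))
  })
}

#' Generate a paired synthetic instance with known ground truth
#'
#' Builds one accession tree, expands alleles for markers A and B under a
#' shared allelic history, assigns supports to both trees, plants label
#' swaps on a fraction of the eligible (divergent, two-allele in both
#' markers) accessions of tree B, records them as ground truth, and
#' finally perturbs tree B with NNI moves and branch-length jitter.
#' Deterministic per `config$seed`.
#'
#' @param config an [simConfig()].
#' @return list of class `"amSyntheticPair"`: `treeA`, `treeB`
#'   ([LabeledTree-class]), `truth` (`data.frame`: accession, kA, kB,
#'   divergent, swapped, informative, truthVerdict, truthPairing), `plan`,
#'   `config`.
#' @export
makePairedInstance <- function(config = simConfig()) {
  .withSeed(config$seed, {
    T <- .simYule(config$nAccessions)
    plan <- .makePlan(T, config)
    phyA <- .expandWithPlan(T, plan, "A")
    ltA <- .lt(phyA, .drawSupports(phyA$Nnode, config$supportModel))
    phyB <- .expandWithPlan(T, plan, "B")

    eligible <- names(plan)[vapply(plan, function(p)
      p$divergent && p$kA == 2L && p$kB == 2L, logical(1))]
    nSwap <- round(config$plantedSwapFraction * length(eligible))
    swapped <- if (nSwap > 0L) sort(sample(eligible, nSwap)) else character(0)
    for (acc in swapped) {
      i0 <- which(phyB$tip.label == .canonicalLabel(acc, "0"))
      i1 <- which(phyB$tip.label == .canonicalLabel(acc, "1"))
      phyB$tip.label[c(i0, i1)] <- phyB$tip.label[c(i1, i0)]
    }
    ltB <- perturbTree(.lt(phyB), config, seed = NULL)

    truth <- do.call(rbind, lapply(sort(names(plan)), function(acc) {
      p <- plan[[acc]]
      tp <- .truthPairing(acc, p$kA, p$kB, acc %in% swapped)
      data.frame(accession = acc, kA = p$kA, kB = p$kB,
        divergent = p$divergent, swapped = acc %in% swapped,
        informative = p$divergent && p$kA == 2L && p$kB == 2L,
        truthVerdict = if (acc %in% swapped) "swap" else "keep",
        truthPairing = format(tp), stringsAsFactors = FALSE)
    }))
    structure(list(treeA = ltA, treeB = ltB, truth = truth, plan = plan,
      config = config), class = "amSyntheticPair")
  })
}

# Ground-truth pairing by lineage ancestry: a smaller-side allele maps to
# the larger-side allele sharing its (lineage, sub) slot, falling back to
# sub 0 when the other marker did not split that lineage.
.truthPairing <- function(acc, kA, kB, swapped) {
  sa <- .alleleScheme(kA); sb <- .alleleScheme(kB)
  if (kA <= kB) { sm <- sa; lg <- sb; smallerIn <- "A" }
  else { sm <- sb; lg <- sa; smallerIn <- "B" }
  img <- vapply(seq_len(nrow(sm)), function(i) {
    lin <- sm$lineage[i]
    if (swapped) lin <- 1L - lin
    hit <- which(lg$lineage == lin & lg$sub == sm$sub[i])
    if (!length(hit)) hit <- which(lg$lineage == lin & lg$sub == 0L)
    lg$code[hit[1L]]
  }, character(1))
  pairing(acc, sm$code, img, smallerIn)
}

#' @export
print.amSyntheticPair <- function(x, ...) {
  cat(sprintf("Synthetic allele-tree pair: %d accessions, seed %d\n",
    x$config$nAccessions, x$config$seed))
  cat(sprintf("  tree A: %d leaves; tree B: %d leaves\n",
    length(tipLabels(x$treeA)), length(tipLabels(x$treeB))))
  cat(sprintf("  noise: %d NNI, jitter sigma %.3g; planted swaps: %d\n",
    x$config$nNni, x$config$lengthJitterSigma, sum(x$truth$swapped)))
  invisible(x)
}

#' Fraction of informative planted verdicts recovered
#'
#' Compares the verdicts of a [MatchResult-class] with the planted ground
#' truth of a synthetic pair, over the informative accessions (divergent,
#' two alleles in both markers — the only accessions where a swap is
#' observable in principle).  Equivocal verdicts count as not recovered.
#'
#' @param result a [MatchResult-class] from [linkAlleles()] on the pair.
#' @param pair an `"amSyntheticPair"` from [makePairedInstance()].
#' @return recovery rate in `[0, 1]`, or `NA` if no accession is
#'   informative.
#' @export
verdictRecovery <- function(result, pair) {
  tr <- pair$truth[pair$truth$informative, , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  v <- verdicts(result)
  got <- v$verdict[match(tr$accession, v$accession)]
  mean(got == tr$truthVerdict)
}
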