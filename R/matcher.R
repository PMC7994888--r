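# Two-phase search for the per-accession allele pairings that make two
# gene trees most similar: local coordinate descent under plain rooted RF,
# then exhaustive global optimization under the weighted rooted RF metric.

#' Construct an allele pairing for one accession
#'
#' A pairing is an injective map from the complete allele set of the
#' smaller side into the allele set of the larger side.
#'
#' @param accession accession identifier.
#' @param from allele codes of the smaller side (complete set).
#' @param to their images on the larger side (same length, no repeats).
#' @param smallerIn which tree holds the smaller set, `"A"` or `"B"`.
#' @return a list of class `"amPairing"`.
#' @export
pairing <- function(accession, from, to, smallerIn = c("A", "B")) {
  smallerIn <- match.arg(smallerIn)
  if (length(from) != length(to) || anyDuplicated(to) || anyDuplicated(from))
    .amStop("amMappingError", "pairing must be an injective map")
  o <- order(from, method = "radix")
  structure(list(accession = accession, from = from[o], to = to[o],
    smallerIn = smallerIn), class = "amPairing")
}

#' @export
format.amPairing <- function(x, ...) {
  arrow <- if (x$smallerIn == "A") ">" else "<"
  paste0(x$accession, "[", x$smallerIn, "]:",
    paste(paste0(x$from, arrow, x$to), collapse = ","))
}

#' @export
print.amPairing <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Canonical key of a pairing; equal keys <=> same mapping.
.pairingKey <- function(p)
  paste0(p$smallerIn, "|", paste(paste0(p$from, ">", p$to), collapse = ","))

#' The identity pairing between two allele sets
#'
#' Maps each smaller-side allele to the equally named allele of the larger
#' side where one exists; remaining alleles are matched in sorted order.
#' For equal code sets this is the code-identity map, the "no swap"
#' reference against which swap verdicts are defined.
#'
#' @param accession accession identifier.
#' @param codesA,codesB allele code sets of the accession in the two trees.
#' @return an `"amPairing"`.
#' @export
identityPairing <- function(accession, codesA, codesB) {
  if (length(codesA) <= length(codesB)) {
    from <- sort(codesA); pool <- sort(codesB); smallerIn <- "A"
  } else {
    from <- sort(codesB); pool <- sort(codesA); smallerIn <- "B"
  }
  to <- rep(NA_character_, length(from))
  direct <- from %in% pool
  to[direct] <- from[direct]
  left <- setdiff(pool, to[direct])
  to[!direct] <- left[seq_len(sum(!direct))]
  pairing(accession, from, to, smallerIn)
}

# All injective maps of size k from `pool` (sorted), lexicographic order.
.injMaps <- function(pool, k) {
  if (k == 0L) return(list(character(0)))
  out <- list()
  for (i in seq_along(pool)) {
    rest <- .injMaps(pool[-i], k - 1L)
    out <- c(out, lapply(rest, function(r) c(pool[i], r)))
  }
  out
}

#' Enumerate all pairings between two allele sets
#'
#' All injective maps from the smaller of the two sets into the larger, in
#' deterministic lexicographic order of the image tuple; their number is
#' `|larger|! / (|larger| - |smaller|)!`.
#'
#' @param allelesA,allelesB non-empty allele code sets.
#' @param accession accession identifier attached to the pairings.
#' @return list of `"amPairing"` objects.
#' @examples
#' length(enumeratePairings(c("0", "1"), c("0", "1")))            # 2
#' length(enumeratePairings("s", c("0", "1")))                    # 2
#' length(enumeratePairings(c("0", "1"), c("0.0", "0.1", "1.0", "1.1"))) # 12
#' @export
enumeratePairings <- function(allelesA, allelesB, accession = "?") {
  if (!length(allelesA) || !length(allelesB))
    .amStop("amConfigError", "allele sets must be non-empty")
  if (length(allelesA) <= length(allelesB)) {
    from <- sort(allelesA); pool <- sort(allelesB); smallerIn <- "A"
  } else {
    from <- sort(allelesB); pool <- sort(allelesA); smallerIn <- "B"
  }
  lapply(.injMaps(pool, length(from)),
    function(img) pairing(accession, from, img, smallerIn))
}

#' Search configuration for allele matching
#'
#' @param seed integer seed controlling every random draw of the search.
#' @param restarts number of random restarts of the local phase; each
#'   restart draws a fresh random combination (1 reproduces a single
#'   random assignment).
#' @param maxSweeps cap on coordinate-descent sweeps per restart.
#' @param globalCap maximum number of combinations the exhaustive global
#'   phase may evaluate.
#' @param mode leaf-set harmonization for unbalanced accessions:
#'   `"prune"` (default) or `"duplicate"`, see [harmonizeLeafSets()].
#' @param metric a [metricConfig()] for the weighted global objective.
#' @return list of class `"amSearchConfig"`.
#' @export
searchConfig <- function(seed = 1L, restarts = 10L, maxSweeps = 20L,
                         globalCap = 1e6, mode = c("prune", "duplicate"),
                         metric = metricConfig()) {
  mode <- match.arg(mode)
  if (restarts < 1L || maxSweeps < 1L || globalCap < 1)
    .amStop("amConfigError", "restarts, maxSweeps and globalCap must be positive")
  structure(list(seed = as.integer(seed), restarts = as.integer(restarts),
    maxSweeps = as.integer(maxSweeps), globalCap = globalCap, mode = mode,
    metric = metric), class = "amSearchConfig")
}

#' Relabel two trees under a combination
#'
#' Pure wrapper around [harmonizeLeafSets()]: returns the two trees with
#' the shared canonical labels implied by `combination`, ready for a
#' distance computation; the inputs are not modified.
#'
#' @inheritParams harmonizeLeafSets
#' @return list with elements `treeA` and `treeB`.
#' @export
applyCombination <- function(treeA, treeB, combination,
                             mode = c("prune", "duplicate")) {
  harmonizeLeafSets(treeA, treeB, combination, match.arg(mode))
}

# ---------------------------------------------------------------------------
# Evaluation context: per-instance precomputation shared by both phases.
#
# When harmonization is `prune` and the number of matched pairs is at most
# 52, combinations are scored without rebuilding trees: every canonical
# pair gets a power of two, clade identity is the sum over matched descend-
# ant tips, and per-combination pruning reduces to zeroing the unmatched
# tips' contributions.  Chains of nodes that would be suppressed by real
# pruning collapse to one clade (lengths summed, support of the lowest
# node), reproducing the explicit tree-surgery result exactly.
# ---------------------------------------------------------------------------

.treeSide <- function(tree, accs, config) {
  phy <- tree@phy
  n <- length(phy$tip.label)
  lab <- .splitCanonical(phy$tip.label)
  desc <- .descTips(phy)
  stem <- .stemLengths(phy)
  nodesAll <- (n + 1L):(n + phy$Nnode)
  M <- matrix(0, length(nodesAll), n)
  for (i in seq_along(nodesAll)) M[i, desc[[nodesAll[i]]]] <- 1
  len <- stem[nodesAll]
  effLen <- ifelse(is.na(len), if (config$metric$missingLength == "as-0") 0 else 1, len)
  sup <- tree@support
  effSup <- ifelse(is.na(sup),
    if (config$metric$missingSupport == "retain-as-1") 1 else -1, sup)
  list(tree = tree, phy = phy, n = n, lab = lab, M = M,
    effLen = effLen, effSup = effSup, origSize = lengths(desc[nodesAll]),
    tipsIdx = lapply(accs, function(a) which(lab$accession == a)))
}

.evalContext <- function(treeA, treeB, config) {
  accsA <- sort(unique(.splitCanonical(treeA@phy$tip.label)$accession))
  accsB <- sort(unique(.splitCanonical(treeB@phy$tip.label)$accession))
  if (!identical(accsA, accsB))
    stop("internal error: trees must be restricted to shared accessions")
  accs <- accsA
  A <- .treeSide(treeA, accs, config)
  B <- .treeSide(treeB, accs, config)
  names(A$tipsIdx) <- names(B$tipsIdx) <- accs

  codesA <- lapply(accs, function(a) sort(A$lab$allele[A$tipsIdx[[a]]]))
  codesB <- lapply(accs, function(a) sort(B$lab$allele[B$tipsIdx[[a]]]))
  names(codesA) <- names(codesB) <- accs
  pairings <- lapply(accs, function(a)
    enumeratePairings(codesA[[a]], codesB[[a]], a))
  names(pairings) <- accs
  np <- vapply(pairings, length, integer(1))
  m <- vapply(accs, function(a)
    min(length(codesA[[a]]), length(codesB[[a]])), integer(1))
  off <- c(0L, cumsum(m))[seq_along(accs)]
  names(off) <- accs
  nPairs <- sum(m)
  fast <- config$mode == "prune" && nPairs <= 52L

  # per accession x pairing: global pair id for each tip (0 = unmatched)
  assignFor <- function(side, a) {
    codes <- if (side == "A") A$lab$allele[A$tipsIdx[[a]]] else
      B$lab$allele[B$tipsIdx[[a]]]
    lapply(pairings[[a]], function(p) {
      own <- if (side == "A") {
        if (p$smallerIn == "A") p$from else p$to
      } else {
        if (p$smallerIn == "A") p$to else p$from
      }
      k <- match(codes, own, nomatch = 0L)
      ifelse(k > 0L, off[[a]] + k, 0L)
    })
  }
  assignA <- lapply(accs, function(a) assignFor("A", a))
  assignB <- lapply(accs, function(a) assignFor("B", a))
  names(assignA) <- names(assignB) <- accs

  posA <- unlist(A$tipsIdx[accs], use.names = FALSE)
  posB <- unlist(B$tipsIdx[accs], use.names = FALSE)
  pw <- c(0, 2^(seq_len(nPairs) - 1))

  maskStats <- function(side, idx) {
    ids <- unlist(lapply(accs, function(a)
      (if (side == "A") assignA else assignB)[[a]][[idx[[a]]]]),
      use.names = FALSE)
    S <- if (side == "A") A else B
    id <- integer(S$n)
    id[if (side == "A") posA else posB] <- ids
    x <- pw[id + 1L]
    v <- drop(S$M %*% x)
    cnt <- drop(S$M %*% as.numeric(id > 0L))
    keep <- cnt >= 2 & cnt < nPairs
    list(mask = v[keep], effLen = S$effLen[keep], effSup = S$effSup[keep],
      origSize = S$origSize[keep])
  }

  dedupe <- function(st) {
    if (!anyDuplicated(st$mask)) return(st)
    o <- order(st$mask, st$origSize, method = "radix")
    mk <- st$mask[o]
    newGrp <- c(TRUE, mk[-1] != mk[-length(mk)])
    gid <- cumsum(newGrp)
    list(mask = mk[newGrp],
      effLen = as.vector(rowsum(st$effLen[o], gid)),
      effSup = st$effSup[o][newGrp],
      origSize = st$origSize[o][newGrp])
  }

  evalFast <- function(idx, weighted) {
    sa <- dedupe(maskStats("A", idx))
    sb <- dedupe(maskStats("B", idx))
    if (!weighted) {
      return(sum(is.na(match(sa$mask, sb$mask))) +
             sum(is.na(match(sb$mask, sa$mask))))
    }
    thr <- config$metric$supportThreshold
    da <- is.na(match(sa$mask, sb$mask)) & sa$effSup >= thr
    db <- is.na(match(sb$mask, sa$mask)) & sb$effSup >= thr
    sum((sa$effLen * sa$effSup)[da]) + sum((sb$effLen * sb$effSup)[db])
  }

  evalGeneral <- function(idx, weighted) {
    comb <- stats::setNames(lapply(accs, function(a)
      pairings[[a]][[idx[[a]]]]), accs)
    h <- harmonizeLeafSets(treeA, treeB, comb, config$mode)
    if (weighted) weightedRfDistance(h$treeA, h$treeB, config$metric)
    else rfDistance(h$treeA, h$treeB)
  }

  evalFun <- if (fast) evalFast else evalGeneral
  list(accs = accs, codesA = codesA, codesB = codesB,
    pairings = pairings, np = np, fast = fast,
    identityIdx = vapply(accs, function(a)
      match(.pairingKey(identityPairing(a, codesA[[a]], codesB[[a]])),
        vapply(pairings[[a]], .pairingKey, character(1))), integer(1)),
    eval = function(idx, weighted = FALSE) evalFun(idx, weighted),
    combinationOf = function(idx) stats::setNames(lapply(accs, function(a)
      pairings[[a]][[idx[[a]]]]), accs))
}

# ---------------------------------------------------------------------------

.localOpt <- function(ctx, config) {
  accs <- ctx$accs
  np <- ctx$np
  retained <- stats::setNames(lapply(np, function(k)
    if (k == 1L) 1L else integer(0)), accs)
  evals <- 0L; sweepsUsed <- 0L
  .withSeed(config$seed, {
    for (r in seq_len(config$restarts)) {
      cur <- vapply(accs, function(a) sample.int(np[[a]], 1L), integer(1))
      names(cur) <- accs
      for (sw in seq_len(config$maxSweeps)) {
        changed <- FALSE
        for (a in sample(accs)) {
          if (np[[a]] == 1L) next
          d <- numeric(np[[a]])
          for (i in seq_len(np[[a]])) {
            cur2 <- cur; cur2[[a]] <- i
            d[i] <- ctx$eval(cur2, weighted = FALSE)
          }
          evals <- evals + np[[a]]
          mins <- which(d <= min(d))
          retained[[a]] <- union(retained[[a]], mins)
          if (!(cur[[a]] %in% mins)) {
            cur[[a]] <- mins[1L]
            changed <- TRUE
          }
        }
        sweepsUsed <- sweepsUsed + 1L
        if (!changed) break
      }
    }
  })
  # identity is always expressible: inject it into every retained set
  for (a in accs)
    retained[[a]] <- sort(union(retained[[a]], ctx$identityIdx[[a]]))
  list(retained = retained, evals = evals, sweeps = sweepsUsed)
}

.globalOpt <- function(ctx, retained, config) {
  accs <- ctx$accs
  sizes <- vapply(retained, length, integer(1))
  total <- prod(sizes)
  if (total > config$globalCap)
    .amStop("amCapacityError", sprintf(
      "global phase would evaluate %.3g combinations (cap %.3g); tighten the local phase or restrict accessions",
      total, config$globalCap))
  grid <- as.matrix(expand.grid(retained, KEEP.OUT.ATTRS = FALSE))
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- stats::setNames(as.integer(grid[i, ]), accs)
    scores[i] <- ctx$eval(idx, weighted = TRUE)
  }
  mn <- min(scores)
  optRows <- which(scores <= mn + 1e-9)
  combos <- lapply(optRows, function(i)
    ctx$combinationOf(stats::setNames(as.integer(grid[i, ]), accs)))

  verd <- lapply(accs, function(a) {
    keys <- unique(vapply(combos, function(cb) .pairingKey(cb[[a]]),
      character(1)))
    idKey <- .pairingKey(ctx$pairings[[a]][[ctx$identityIdx[[a]]]])
    v <- if (length(keys) > 1L) "equivocal"
      else if (keys == idKey) "keep" else "swap"
    data.frame(accession = a, verdict = v,
      bestPairing = format(combos[[1L]][[a]]),
      nOptimalPairings = length(keys), stringsAsFactors = FALSE)
  })
  list(combos = combos, score = mn, verdicts = do.call(rbind, verd),
    evals = nrow(grid), retainedSizes = sizes)
}

#' Local optimization phase: retained pairing sets per accession
#'
#' Multi-restart coordinate descent under the plain rooted RF distance:
#' each restart draws a seeded random combination, then repeatedly sweeps
#' the accessions in random order, evaluating every pairing of the focal
#' accession with the others held fixed, moving to a minimizer and
#' recording every minimizer encountered.  Minimizer sets are unioned over
#' sweeps and restarts and the identity pairing is always included.
#'
#' @param treeA,treeB preprocessed trees (pruned to shared accessions,
#'   mono-accession clades collapsed).
#' @param config a [searchConfig()].
#' @return named list (by accession) of lists of `"amPairing"` objects,
#'   with attribute `"stats"`.
#' @export
localOptimize <- function(treeA, treeB, config = searchConfig()) {
  ctx <- .evalContext(treeA, treeB, config)
  loc <- .localOpt(ctx, config)
  out <- stats::setNames(lapply(ctx$accs, function(a)
    ctx$pairings[[a]][loc$retained[[a]]]), ctx$accs)
  attr(out, "stats") <- list(evals = loc$evals, sweeps = loc$sweeps)
  out
}

#' Global optimization phase: exhaustive scan of retained combinations
#'
#' Evaluates every combination in the Cartesian product of the retained
#' pairing sets under the weighted rooted RF objective (with the support
#' cutoff) and reports all minimizers, the minimal score, and per-accession
#' verdicts: `"swap"` if every optimum uses a non-identity pairing,
#' `"keep"` if every optimum uses the identity, `"equivocal"` if both
#' occur.
#'
#' @inheritParams localOptimize
#' @param retained named list of pairing lists as returned by
#'   [localOptimize()].
#' @return a [MatchResult-class].
#' @export
globalOptimize <- function(treeA, treeB, retained, config = searchConfig()) {
  ctx <- .evalContext(treeA, treeB, config)
  idx <- lapply(ctx$accs, function(a) {
    keys <- vapply(ctx$pairings[[a]], .pairingKey, character(1))
    i <- match(vapply(retained[[a]], .pairingKey, character(1)), keys)
    if (anyNA(i))
      .amStop("amMappingError",
        sprintf("retained pairing for '%s' not enumerable from the trees", a))
    sort(unique(i))
  })
  names(idx) <- ctx$accs
  glob <- .globalOpt(ctx, idx, config)
  .matchResult(ctx, glob, local = NULL, config = config)
}

.matchResult <- function(ctx, glob, local, config,
                         collapseA = NULL, collapseB = NULL) {
  emptyRep <- data.frame(accession = character(), group = character(),
    members = character(), representative = character(), length = numeric(),
    stringsAsFactors = FALSE)
  new("MatchResult",
    combinations = glob$combos,
    score = glob$score,
    verdicts = glob$verdicts,
    collapseA = if (is.null(collapseA)) emptyRep else collapseA,
    collapseB = if (is.null(collapseB)) emptyRep else collapseB,
    stats = list(
      evaluated = glob$evals + (if (is.null(local)) 0L else local$evals),
      localEvals = if (is.null(local)) NA_integer_ else local$evals,
      globalEvals = glob$evals,
      sweeps = if (is.null(local)) NA_integer_ else local$sweeps,
      retainedSizes = glob$retainedSizes,
      restarts = config$restarts,
      seed = config$seed,
      fastPath = ctx$fast,
      alleleCodes = stats::setNames(lapply(ctx$accs, function(a)
        list(A = ctx$codesA[[a]], B = ctx$codesB[[a]])), ctx$accs)),
    config = unclass(config))
}

#' Match alleles between two gene trees
#'
#' The full pipeline: restrict both trees to their shared accessions,
#' collapse mono-accession (coalescent) allele clades, run the local
#' optimization under plain rooted RF, then exhaustively score the product
#' of the retained pairing sets under the weighted rooted RF objective.
#' Deterministic given the seed in `config`.
#'
#' @param treeA,treeB [LabeledTree-class] objects sharing at least one
#'   accession (e.g. the ITS and ETS trees of the same samples).
#' @param config a [searchConfig()].
#' @return a [MatchResult-class].
#' @examples
#' a <- parseNewick("((X|0:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,(X|1:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);")
#' b <- parseNewick("((X|1:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,(X|0:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);")
#' res <- linkAlleles(a, b)
#' verdicts(res)  # accession X must be swapped
#' @export
linkAlleles <- function(treeA, treeB, config = searchConfig()) {
  shared <- sharedAccessions(treeA, treeB)
  pA <- pruneToAccessions(treeA, shared)
  pB <- pruneToAccessions(treeB, shared)
  cA <- collapseMonoaccessionClades(pA)
  cB <- collapseMonoaccessionClades(pB)
  ctx <- .evalContext(cA$tree, cB$tree, config)
  loc <- .localOpt(ctx, config)
  glob <- .globalOpt(ctx, loc$retained, config)
  .matchResult(ctx, glob, loc, config, cA$report, cB$report)
}

#' Exhaustive brute-force allele matching
#'
#' Skips the local phase entirely: preprocesses exactly like
#' [linkAlleles()], then scores every combination of every pairing under
#' the weighted rooted RF objective through the explicit tree-surgery
#' route ([applyCombination()] + [weightedRfDistance()]).  Exponential in
#' the number of accessions; intended for validating the heuristic on
#' small instances.
#'
#' @inheritParams linkAlleles
#' @return a [MatchResult-class].
#' @export
bruteForceMatch <- function(treeA, treeB, config = searchConfig()) {
  shared <- sharedAccessions(treeA, treeB)
  pA <- pruneToAccessions(treeA, shared)
  pB <- pruneToAccessions(treeB, shared)
  cA <- collapseMonoaccessionClades(pA)
  cB <- collapseMonoaccessionClades(pB)
  labA <- .splitCanonical(cA$tree@phy$tip.label)
  labB <- .splitCanonical(cB$tree@phy$tip.label)
  accs <- sort(unique(labA$accession))
  pairings <- stats::setNames(lapply(accs, function(a) enumeratePairings(
    sort(labA$allele[labA$accession == a]),
    sort(labB$allele[labB$accession == a]), a)), accs)
  sizes <- vapply(pairings, length, integer(1))
  if (prod(sizes) > config$globalCap)
    .amStop("amCapacityError", "full enumeration exceeds globalCap")
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len),
    KEEP.OUT.ATTRS = FALSE))
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    comb <- stats::setNames(lapply(seq_along(accs), function(j)
      pairings[[j]][[grid[i, j]]]), accs)
    h <- applyCombination(cA$tree, cB$tree, comb, config$mode)
    scores[i] <- weightedRfDistance(h$treeA, h$treeB, config$metric)
  }
  mn <- min(scores)
  optRows <- which(scores <= mn + 1e-9)
  combos <- lapply(optRows, function(i)
    stats::setNames(lapply(seq_along(accs), function(j)
      pairings[[j]][[grid[i, j]]]), accs))
  verd <- do.call(rbind, lapply(accs, function(a) {
    keys <- unique(vapply(combos, function(cb) .pairingKey(cb[[a]]),
      character(1)))
    idKey <- .pairingKey(identityPairing(a,
      sort(labA$allele[labA$accession == a]),
      sort(labB$allele[labB$accession == a])))
    data.frame(accession = a,
      verdict = if (length(keys) > 1L) "equivocal"
        else if (keys == idKey) "keep" else "swap",
      bestPairing = format(combos[[1L]][[a]]),
      nOptimalPairings = length(keys), stringsAsFactors = FALSE)
  }))
  new("MatchResult", combinations = combos, score = mn, verdicts = verd,
    collapseA = cA$report, collapseB = cB$report,
    stats = list(evaluated = nrow(grid), localEvals = 0L,
      globalEvals = nrow(grid), sweeps = 0L,
      retainedSizes = sizes, restarts = 0L, seed = config$seed,
      fastPath = FALSE, method = "brute-force",
      alleleCodes = stats::setNames(lapply(accs, function(a) list(
        A = sort(labA$allele[labA$accession == a]),
        B = sort(labB$allele[labB$accession == a]))), accs)),
    config = unclass(config))
}

#' Concatenation plan from a match result
#'
#' One row per matched allele pair under the first optimal combination (in
#' deterministic order).  In duplicate mode a single/unmatched-side allele
#' matched to several partners appears in that many rows, mirroring the
#' rule that a single sequence is concatenated with both variants of the
#' other region.  Collapsed allele groups are expanded back to their
#' representative allele with all members listed.  Equivocal accessions
#' are flagged.
#'
#' @param result a [MatchResult-class].
#' @return `data.frame` with columns `accession`, `alleleA`, `alleleB`,
#'   `membersA`, `membersB`, `verdict`.
#' @export
concatenationPlan <- function(result) {
  stopifnot(is(result, "MatchResult"))
  comb <- result@combinations[[1L]]
  codes <- result@stats$alleleCodes
  mode <- result@config$mode
  expand <- function(report, acc, code) {
    hit <- which(report$accession == acc & report$group == code)
    if (length(hit)) list(code = report$representative[hit[1L]],
      members = report$members[hit[1L]])
    else list(code = code, members = NA_character_)
  }
  rows <- lapply(names(comb), function(acc) {
    tb <- .pairTable(comb[[acc]], codes[[acc]]$A, codes[[acc]]$B, mode)
    v <- result@verdicts$verdict[result@verdicts$accession == acc]
    do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
      ea <- expand(result@collapseA, acc, tb$codeA[i])
      eb <- expand(result@collapseB, acc, tb$codeB[i])
      data.frame(accession = acc, alleleA = ea$code, alleleB = eb$code,
        membersA = ea$members, membersB = eb$members, verdict = v,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a MatchResult
#'
#' Writes the result as JSON (combinations, score, verdicts, statistics)
#' and/or as a flat TSV of per-accession verdicts.  Identical inputs and
#' seed yield byte-identical output.
#'
#' @param result a [MatchResult-class].
#' @param json,tsv optional output paths.
#' @return invisibly, the JSON string.
#' @export
writeMatchResult <- function(result, json = NULL, tsv = NULL) {
  stopifnot(is(result, "MatchResult"))
  payload <- list(
    score = result@score,
    combinations = lapply(result@combinations, function(cb)
      vapply(cb, format, character(1))),
    verdicts = result@verdicts,
    collapseA = result@collapseA,
    collapseB = result@collapseB,
    stats = result@stats[c("evaluated", "localEvals", "globalEvals",
      "sweeps", "restarts", "seed")],
    retainedSizes = as.list(result@stats$retainedSizes),
    config = list(seed = result@config$seed,
      restarts = result@config$restarts, mode = result@config$mode,
      supportThreshold = result@config$metric$supportThreshold))
  str <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  if (!is.null(json)) writeLines(str, json)
  if (!is.null(tsv))
    utils::write.table(result@verdicts, tsv, sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(as.character(str))
}
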