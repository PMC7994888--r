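# Preprocessing: reduce two allele trees to comparable form.

# Tip indices descending from every node (1..Ntip are the tips themselves).
.descTips <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Branch length of the edge subtending each node (NA for the root).
.stemLengths <- function(phy) {
  n <- length(phy$tip.label)
  out <- rep(NA_real_, n + phy$Nnode)
  if (!is.null(phy$edge.length))
    out[phy$edge[, 2]] <- phy$edge.length
  out
}

.parentOf <- function(phy) {
  n <- length(phy$tip.label)
  out <- rep(NA_integer_, n + phy$Nnode)
  out[phy$edge[, 2]] <- phy$edge[, 1]
  out
}

# drop.tip wrapper carrying the support vector through node renumbering.
# `tipIdx` are tip indices to REMOVE. Handles the 1-tip remainder that ape
# cannot represent through drop.tip.
.dropTips <- function(phy, support, tipIdx) {
  if (!length(tipIdx)) return(list(phy = phy, support = support))
  keepN <- length(phy$tip.label) - length(tipIdx)
  if (keepN < 1L)
    .amStop("amConfigError", "cannot drop every leaf of a tree")
  if (keepN == 1L) {
    keep <- setdiff(seq_along(phy$tip.label), tipIdx)
    len <- NA_real_
    if (!is.null(phy$edge.length)) {
      # pendant length = full root-to-tip path after suppressing everything
      par <- .parentOf(phy); stem <- .stemLengths(phy)
      node <- keep; len <- 0
      while (!is.na(par[node])) { len <- len + stem[node]; node <- par[node] }
    }
    out <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = phy$tip.label[keep], Nnode = 1L), class = "phylo")
    if (!is.na(len)) out$edge.length <- len
    return(list(phy = out, support = NA_real_))
  }
  phy$node.label <- paste0("S", seq_len(phy$Nnode))
  ph2 <- ape::drop.tip(phy, tipIdx, collapse.singles = TRUE)
  idx <- suppressWarnings(as.integer(sub("^S", "", ph2$node.label)))
  s2 <- rep(NA_real_, ph2$Nnode)
  ok <- !is.na(idx)
  s2[ok] <- support[idx[ok]]
  ph2$node.label <- NULL
  list(phy = ph2, support = s2)
}

#' Accessions shared by two trees
#'
#' @param treeA,treeB [LabeledTree-class] objects.
#' @return character vector of shared accession identifiers (sorted).
#' @export
sharedAccessions <- function(treeA, treeB) {
  shared <- intersect(accessions(treeA), accessions(treeB))
  if (!length(shared))
    .amStop("amNoOverlapError",
      "the two trees share no accession; allele matching is undefined")
  sort(shared)
}

#' Prune a tree to a set of accessions
#'
#' Leaves of accessions outside `keep` are removed; resulting degree-2
#' internal nodes are suppressed with their incident branch lengths summed,
#' and the supports of suppressed nodes are discarded.
#'
#' @param tree a [LabeledTree-class].
#' @param keep non-empty character vector of accessions to retain.
#' @return the pruned [LabeledTree-class].
#' @export
pruneToAccessions <- function(tree, keep) {
  stopifnot(is(tree, "LabeledTree"))
  if (!length(keep)) .amStop("amConfigError", "'keep' must be non-empty")
  acc <- tipAccession(tree)
  missing <- setdiff(keep, acc)
  if (length(missing))
    .amStop("amMappingError", sprintf("accession(s) not in tree: %s",
      paste(missing, collapse = ", ")))
  drop <- which(!(acc %in% keep))
  res <- .dropTips(tree@phy, tree@support, drop)
  .lt(res$phy, res$support)
}

#' Collapse clades made up exclusively of alleles from one accession
#'
#' Every maximal clade whose leaves all carry the same accession (a
#' coalescent allele group, uninformative for matching) is replaced by a
#' single leaf with synthetic allele code `"g<i>"`.  Its branch length is
#' the clade's stem branch plus the branch length of the most basal member
#' allele, i.e. the leaf attached topologically closest to the clade root
#' (ties broken lexicographically by allele code).
#'
#' @param tree a [LabeledTree-class].
#' @return list with elements `tree` (collapsed [LabeledTree-class]) and
#'   `report`, a `data.frame` with one row per collapsed clade: `accession`,
#'   `group` (assigned code), `members` (comma-joined allele codes ordered
#'   by attachment depth then lexicographically), `representative` (the
#'   basal allele), `length`.
#' @export
collapseMonoaccessionClades <- function(tree) {
  stopifnot(is(tree, "LabeledTree"))
  phy <- tree@phy
  n <- length(phy$tip.label)
  emptyReport <- data.frame(accession = character(), group = character(),
    members = character(), representative = character(), length = numeric(),
    stringsAsFactors = FALSE)
  if (n < 2L) return(list(tree = tree, report = emptyReport))

  lab <- .splitCanonical(phy$tip.label)
  desc <- .descTips(phy)
  stem <- .stemLengths(phy)
  par <- .parentOf(phy)
  nodes <- (n + 1L):(n + phy$Nnode)
  mono <- vapply(nodes, function(v)
    length(unique(lab$accession[desc[[v]]])) == 1L, logical(1))
  isMono <- function(v) v > n && mono[v - n]
  maximal <- nodes[mono & vapply(nodes, function(v)
    is.na(par[v]) || !isMono(par[v]), logical(1))]
  if (!length(maximal)) return(list(tree = tree, report = emptyReport))

  # depth (in edges) of every node below each collapse root
  depthBelow <- function(v) {
    d <- rep(NA_integer_, n + phy$Nnode); d[v] <- 0L
    co <- ape::reorder.phylo(phy, "cladewise")
    for (k in seq_len(nrow(co$edge))) {
      p <- co$edge[k, 1]; ch <- co$edge[k, 2]
      if (!is.na(d[p])) d[ch] <- d[p] + 1L
    }
    d
  }

  rows <- list(); dropAll <- integer(); keepTip <- integer()
  newLab <- character(); newLen <- numeric()
  for (i in seq_along(maximal)) {
    v <- maximal[i]
    tips <- desc[[v]]
    d <- depthBelow(v)
    ord <- order(d[tips], lab$allele[tips], method = "radix")
    tips <- tips[ord]
    basal <- tips[1L]
    stemLen <- if (is.na(par[v]) || is.na(stem[v])) 0 else stem[v]
    pend <- if (is.na(stem[basal])) 0 else stem[basal]
    acc <- lab$accession[basal]
    grp <- paste0("g", i)
    rows[[i]] <- data.frame(accession = acc, group = grp,
      members = paste(lab$allele[tips], collapse = ","),
      representative = lab$allele[basal],
      length = stemLen + pend, stringsAsFactors = FALSE)
    keepTip <- c(keepTip, tips[1L])
    newLab <- c(newLab, .canonicalLabel(acc, grp))
    newLen <- c(newLen, stemLen + pend)
    dropAll <- c(dropAll, tips[-1L])
  }
  keepLabels <- phy$tip.label[keepTip]
  res <- .dropTips(phy, tree@support, dropAll)
  ph2 <- res$phy
  idx <- match(keepLabels, ph2$tip.label)
  ph2$tip.label[idx] <- newLab
  if (!is.null(ph2$edge.length)) {
    tipEdge <- match(idx, ph2$edge[, 2])
    ph2$edge.length[tipEdge] <- newLen
  }
  list(tree = .lt(ph2, res$support), report = do.call(rbind, rows))
}

# Full pair table of a pairing, oriented as (codeA, codeB), one row per
# matched pair of leaves. In duplicate mode every unmatched allele on the
# larger side is assigned to the smaller-side allele with the fewest
# partners so far (ties broken by allele-code order), mirroring the
# single-sequence duplication rule used for marker concatenation.
.pairTable <- function(p, codesAFull, codesBFull, mode) {
  if (p$smallerIn == "A") {
    codeA <- p$from; codeB <- p$to
    largerFull <- codesBFull
  } else {
    codeB <- p$from; codeA <- p$to
    largerFull <- codesAFull
  }
  if (mode == "duplicate") {
    leftover <- sort(setdiff(largerFull, if (p$smallerIn == "A") codeB else codeA))
    for (lv in leftover) {
      counts <- table(factor(if (p$smallerIn == "A") codeA else codeB,
        levels = sort(p$from)))
      host <- names(counts)[which.min(counts)]
      if (p$smallerIn == "A") {
        codeA <- c(codeA, host); codeB <- c(codeB, lv)
      } else {
        codeB <- c(codeB, host); codeA <- c(codeA, lv)
      }
    }
  }
  data.frame(codeA = codeA, codeB = codeB, k = seq_along(codeA),
    stringsAsFactors = FALSE)
}

# Expand tips into zero-length multifurcations via Newick-string surgery.
# `expansions`: named list, tip label -> character vector of new labels.
.expandTips <- function(phy, support, expansions) {
  phy$node.label <- paste0("S", seq_len(phy$Nnode))
  hasLen <- !is.null(phy$edge.length)
  if (!hasLen) phy$edge.length <- rep(1, nrow(phy$edge))
  s <- ape::write.tree(phy, digits = 15)
  for (tip in names(expansions)) {
    labs <- expansions[[tip]]
    star <- paste0("(", paste0(labs, ":0", collapse = ","), ")")
    hit <- regexpr(paste0(tip, ":"), s, fixed = TRUE)
    if (hit < 0) .amStop("amMappingError", sprintf("tip '%s' not found", tip))
    s <- paste0(substr(s, 1L, hit - 1L), star,
      substring(s, hit + nchar(tip)))
  }
  ph2 <- ape::read.tree(text = s)
  idx <- suppressWarnings(as.integer(sub("^S", "", ph2$node.label)))
  s2 <- rep(NA_real_, ph2$Nnode)
  s2[!is.na(idx)] <- support[idx[!is.na(idx)]]
  ph2$node.label <- NULL
  if (!hasLen) ph2$edge.length <- NULL
  list(phy = ph2, support = s2)
}

# Core of harmonizeLeafSets for one tree. `side` is "A" or "B".
.relabelTree <- function(tree, side, tables) {
  phy <- tree@phy; support <- tree@support
  lab <- .splitCanonical(phy$tip.label)
  col <- if (side == "A") "codeA" else "codeB"
  newLabels <- phy$tip.label
  drop <- integer(); expansions <- list()
  for (acc in names(tables)) {
    tb <- tables[[acc]]
    tipIdx <- which(lab$accession == acc)
    for (t in tipIdx) {
      rows <- which(tb[[col]] == lab$allele[t])
      if (!length(rows)) {
        drop <- c(drop, t)
      } else {
        canon <- paste0(acc, "#", tb$k[rows])
        newLabels[t] <- canon[1L]
        if (length(rows) > 1L) expansions[[canon[1L]]] <- canon
      }
    }
  }
  phy$tip.label <- newLabels
  res <- list(phy = phy, support = support)
  if (length(drop)) res <- .dropTips(res$phy, res$support, drop)
  if (length(expansions)) res <- .expandTips(res$phy, res$support, expansions)
  .lt(res$phy, res$support)
}

#' Harmonize two trees' leaf sets under an allele combination
#'
#' Each matched pair of leaves receives one shared canonical label
#' `"accession#k"`.  In `mode = "prune"` (the default) alleles left
#' unmatched by the injective pairing are removed from their tree; in
#' `mode = "duplicate"` a smaller-side allele matched to several partners
#' is replaced by that many leaves on a zero-length polytomy at its
#' position, mirroring the rule that a single sequence is concatenated
#' with both variants of the other region.  On return both trees have
#' identical leaf-label sets, the precondition of any RF computation.
#'
#' @param treeA,treeB preprocessed [LabeledTree-class] objects restricted to
#'   their shared accessions.
#' @param combination named list with one [pairing()] per shared accession.
#' @param mode `"prune"` or `"duplicate"`.
#' @return list with elements `treeA` and `treeB`.
#' @export
harmonizeLeafSets <- function(treeA, treeB, combination,
                              mode = c("prune", "duplicate")) {
  mode <- match.arg(mode)
  stopifnot(is(treeA, "LabeledTree"), is(treeB, "LabeledTree"))
  labA <- .splitCanonical(treeA@phy$tip.label)
  labB <- .splitCanonical(treeB@phy$tip.label)
  accs <- sort(unique(c(labA$accession, labB$accession)))
  if (!setequal(names(combination), accs))
    .amStop("amMappingError",
      "combination must cover exactly the accessions present in the trees")
  tables <- list()
  for (acc in accs) {
    p <- combination[[acc]]
    cA <- sort(labA$allele[labA$accession == acc])
    cB <- sort(labB$allele[labB$accession == acc])
    pa <- if (p$smallerIn == "A") p$from else p$to
    pb <- if (p$smallerIn == "A") p$to else p$from
    if (!all(pa %in% cA) || !all(pb %in% cB))
      .amStop("amMappingError",
        sprintf("pairing for accession '%s' references unknown alleles", acc))
    tables[[acc]] <- .pairTable(p, cA, cB, mode)
  }
  outA <- .relabelTree(treeA, "A", tables)
  outB <- .relabelTree(treeB, "B", tables)
  if (!setequal(outA@phy$tip.label, outB@phy$tip.label))
    stop("internal error: harmonized leaf sets differ")
  list(treeA = outA, treeB = outB)
}
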