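#' @import methods
#' @importFrom ape read.tree write.tree drop.tip Ntip Nnode is.rooted rphylo
NULL

setOldClass("phylo")

#' Rooted gene tree with accession/allele-labeled leaves
#'
#' An S4 container wrapping an [ape::phylo] tree whose tip labels follow the
#' canonical `"accession|allele"` form, together with per-internal-node
#' support values normalized to `[0, 1]`.  Alleles of multi-copy markers
#' (ITS, ETS, 5S-NTS) phased from short reads are encoded as `"s"` (single
#' variant), `"0"`/`"1"` (first phasing round), `"0.0"`, `"0.1"`, `"1.0"`,
#' `"1.1"` (second round), `"d"` (direct/Sanger sequence), or arbitrary
#' tokens such as clone identifiers.
#'
#' @slot phy a rooted `phylo` object; tip labels are canonical
#'   `"accession|allele"` strings, unique within the tree.
#' @slot support numeric vector of length `phy$Nnode`; per-internal-node
#'   support in `[0, 1]`, `NA` where unannotated.  Node `i` of `phy`
#'   (number `Ntip + i`) has support `support[i]`.
#'
#' @seealso [parseNewick()], [writeNewick()], [cladeSet()], [linkAlleles()]
#' @export
setClass("LabeledTree",
  representation(phy = "phylo", support = "numeric"))

setValidity("LabeledTree", function(object) {
  phy <- object@phy
  msgs <- character()
  if (is.null(phy$tip.label) || length(phy$tip.label) < 1L)
    msgs <- c(msgs, "tree has no leaves")
  if (anyDuplicated(phy$tip.label))
    msgs <- c(msgs, sprintf("duplicate (accession, allele) leaf label(s): %s",
      paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", ")))
  if (length(object@support) != phy$Nnode)
    msgs <- c(msgs, "support vector length must equal the number of internal nodes")
  s <- object@support[!is.na(object@support)]
  if (length(s) && (any(s < 0) || any(s > 1)))
    msgs <- c(msgs, "supports must lie in [0, 1] after normalization")
  el <- phy$edge.length
  if (!is.null(el) && any(!is.na(el) & el < 0))
    msgs <- c(msgs, "branch lengths must be non-negative")
  if (length(msgs)) msgs else TRUE
})

# Internal constructor from a phylo + support vector.
.lt <- function(phy, support = rep(NA_real_, phy$Nnode)) {
  phy$node.label <- NULL
  new("LabeledTree", phy = phy, support = as.numeric(support))
}

#' Optimal allele-matching result
#'
#' Returned by [linkAlleles()] and [globalOptimize()].  Holds every
#' combination attaining the minimal weighted Robinson-Foulds score, the
#' score itself, per-accession swap/keep/equivocal verdicts, the collapse
#' reports needed to expand collapsed allele groups, and search statistics.
#'
#' @slot combinations list of optimal combinations; each combination is a
#'   named list (one [pairing()] per shared accession).
#' @slot score minimal weighted Robinson-Foulds distance attained.
#' @slot verdicts `data.frame` with columns `accession`, `verdict`
#'   (`"keep"`, `"swap"` or `"equivocal"`), `bestPairing` (the pairing used
#'   by the first optimal combination), `nOptimalPairings`.
#' @slot collapseA,collapseB collapse reports (see
#'   [collapseMonoaccessionClades()]) for the two preprocessed trees.
#' @slot stats list: combinations evaluated, retained-set sizes, restarts,
#'   sweeps used, seed.
#' @slot config the effective [searchConfig()] used.
#'
#' @seealso [matchScore()], [verdicts()], [concatenationPlan()]
#' @export
setClass("MatchResult",
  representation(combinations = "list", score = "numeric",
    verdicts = "data.frame", collapseA = "data.frame",
    collapseB = "data.frame", stats = "list", config = "list"))

setValidity("MatchResult", function(object) {
  if (length(object@score) != 1L || is.na(object@score) || object@score < 0)
    return("score must be a single non-negative number")
  if (!length(object@combinations))
    return("at least one optimal combination is required")
  TRUE
})
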