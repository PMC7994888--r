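#' Accessors for LabeledTree and MatchResult objects
#'
#' `tipLabels()` returns canonical `"accession|allele"` leaf labels;
#' `accessions()` the distinct accession identifiers; `tipAccession()` /
#' `tipAllele()` the per-leaf components; `nodeSupport()` the normalized
#' internal-node supports; `treePhylo()` the underlying [ape::phylo].
#' For [MatchResult-class]: `matchScore()` the minimal weighted RF score,
#' `verdicts()` the per-accession verdict table, `combinations()` the list
#' of optimal combinations, and `searchStats()` the search statistics.
#'
#' @param x a [LabeledTree-class] or [MatchResult-class] object.
#' @return see above, per generic.
#' @name accessors
#' @aliases tipLabels accessions tipAccession tipAllele nodeSupport treePhylo
#'   matchScore verdicts combinations searchStats
NULL

#' @rdname accessors
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))
#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname accessors
#' @export
setGeneric("tipAccession", function(x) standardGeneric("tipAccession"))
#' @rdname accessors
#' @export
setGeneric("tipAllele", function(x) standardGeneric("tipAllele"))
#' @rdname accessors
#' @export
setGeneric("nodeSupport", function(x) standardGeneric("nodeSupport"))
#' @rdname accessors
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))
#' @rdname accessors
#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("combinations", function(x) standardGeneric("combinations"))
#' @rdname accessors
#' @export
setGeneric("searchStats", function(x) standardGeneric("searchStats"))

#' @rdname accessors
setMethod("tipLabels", "LabeledTree", function(x) x@phy$tip.label)
#' @rdname accessors
setMethod("accessions", "LabeledTree",
  function(x) sort(unique(.splitCanonical(x@phy$tip.label)$accession)))
#' @rdname accessors
setMethod("tipAccession", "LabeledTree",
  function(x) .splitCanonical(x@phy$tip.label)$accession)
#' @rdname accessors
setMethod("tipAllele", "LabeledTree",
  function(x) .splitCanonical(x@phy$tip.label)$allele)
#' @rdname accessors
setMethod("nodeSupport", "LabeledTree", function(x) x@support)
#' @rdname accessors
setMethod("treePhylo", "LabeledTree", function(x) x@phy)

setMethod("show", "LabeledTree", function(object) {
  phy <- object@phy
  ns <- object@support
  cat(sprintf("LabeledTree: %d leaves, %d accessions, %d internal nodes\n",
    length(phy$tip.label), length(accessions(object)), phy$Nnode))
  cat(sprintf("  branch lengths: %s; supports: %d/%d annotated\n",
    if (is.null(phy$edge.length)) "absent" else "present",
    sum(!is.na(ns)), length(ns)))
  lab <- phy$tip.label
  if (length(lab) > 6L) lab <- c(lab[1:6], "...")
  cat("  leaves: ", paste(lab, collapse = ", "), "\n", sep = "")
})

#' @rdname accessors
setMethod("matchScore", "MatchResult", function(x) x@score)
#' @rdname accessors
setMethod("verdicts", "MatchResult", function(x) x@verdicts)
#' @rdname accessors
setMethod("combinations", "MatchResult", function(x) x@combinations)
#' @rdname accessors
setMethod("searchStats", "MatchResult", function(x) x@stats)

setMethod("show", "MatchResult", function(object) {
  v <- object@verdicts
  cat(sprintf("MatchResult: %d accession(s), %d optimal combination(s)\n",
    nrow(v), length(object@combinations)))
  cat(sprintf("  weighted RF score: %.6g\n", object@score))
  tab <- table(factor(v$verdict, levels = c("keep", "swap", "equivocal")))
  cat(sprintf("  verdicts: %d keep, %d swap, %d equivocal\n",
    tab[["keep"]], tab[["swap"]], tab[["equivocal"]]))
  cat(sprintf("  combinations evaluated: %d (seed %s)\n",
    object@stats$evaluated,
    if (is.null(object@stats$seed)) "NA" else object@stats$seed))
})
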