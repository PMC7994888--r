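# Plain and branch-length/support weighted rooted Robinson-Foulds distances.

#' Configuration of the weighted rooted RF metric
#'
#' @param supportThreshold clades with effective support strictly below this
#'   value are removed from the weighted distance (default 0.5, the "less
#'   than 50 percent" rule; support exactly at the threshold is retained).
#' @param missingSupport `"retain-as-1"` (default): clades without a support
#'   annotation, e.g. nodes created by collapsing, stay in the objective
#'   with effective support 1; `"drop"`: such clades are removed from the
#'   filtered set.
#' @param missingLength `"as-0"` (default): a clade without a stem branch
#'   length contributes weight 0 (with a warning); `"as-1"`: effective
#'   length 1, degenerating to support-only weighting.
#' @return a list of class `"amMetricConfig"`.
#' @export
metricConfig <- function(supportThreshold = 0.5,
                         missingSupport = c("retain-as-1", "drop"),
                         missingLength = c("as-0", "as-1")) {
  if (!is.numeric(supportThreshold) || length(supportThreshold) != 1L ||
      supportThreshold < 0 || supportThreshold > 1)
    .amStop("amConfigError", "supportThreshold must be in [0, 1]")
  structure(list(supportThreshold = supportThreshold,
    missingSupport = match.arg(missingSupport),
    missingLength = match.arg(missingLength)),
    class = "amMetricConfig")
}

# Internal clade table for a (phy, support) pair. One row per non-trivial
# rooted clade (2 <= size < ntips): key (sorted leaf labels joined by a
# separator), size, stem length, child-node support, effective length and
# support per the metric config, and multiplicative weight.
.cladeTable <- function(phy, support, config, warnMissingLength = TRUE) {
  n <- length(phy$tip.label)
  out0 <- data.frame(key = character(), size = integer(), length = numeric(),
    support = numeric(), effLength = numeric(), effSupport = numeric(),
    weight = numeric(), stringsAsFactors = FALSE)
  if (n < 3L) return(out0)
  desc <- .descTips(phy)
  stem <- .stemLengths(phy)
  nodes <- (n + 1L):(n + phy$Nnode)
  size <- lengths(desc[nodes])
  keep <- size >= 2L & size < n
  nodes <- nodes[keep]; size <- size[keep]
  if (!length(nodes)) return(out0)
  key <- vapply(nodes, function(v)
    paste(sort(phy$tip.label[desc[[v]]]), collapse = "\t"), character(1))
  len <- stem[nodes]
  sup <- support[nodes - n]
  if (warnMissingLength && any(is.na(len)) && config$missingLength == "as-0")
    warning("clade(s) without stem branch length contribute weight 0",
      call. = FALSE)
  effLength <- ifelse(is.na(len),
    if (config$missingLength == "as-0") 0 else 1, len)
  effSupport <- ifelse(is.na(sup),
    if (config$missingSupport == "retain-as-1") 1 else NA_real_, sup)
  data.frame(key = key, size = as.integer(size), length = len, support = sup,
    effLength = effLength, effSupport = effSupport,
    weight = effLength * ifelse(is.na(effSupport), 0, effSupport),
    stringsAsFactors = FALSE)
}

.filterClades <- function(tab, config) {
  keep <- !is.na(tab$effSupport) & tab$effSupport >= config$supportThreshold
  tab[keep, , drop = FALSE]
}

#' Non-trivial rooted clades of a tree, with weights
#'
#' Enumerates every rooted clade of size at least 2 and smaller than the
#' full leaf set, together with its stem branch length, the support of the
#' child node the stem connects to, and the multiplicative weight
#' `effective length x effective support`.  With `filtered = TRUE`, clades
#' whose effective support falls strictly below the configured threshold
#' are excluded (the weighted metric's support-removal rule).
#'
#' @param tree a [LabeledTree-class].
#' @param config a [metricConfig()].
#' @param filtered apply the support threshold?
#' @return `data.frame` with columns `key` (tab-joined sorted leaf labels),
#'   `size`, `length`, `support`, `effLength`, `effSupport`, `weight`.
#' @examples
#' t <- parseNewick("((a|d:1,b|d:1)0.9:0.1,(c|d:1,d|d:1)0.4:0.1);")
#' cladeSet(t, filtered = TRUE)  # only the 90%-supported cherry remains
#' @export
cladeSet <- function(tree, config = metricConfig(), filtered = FALSE) {
  stopifnot(is(tree, "LabeledTree"))
  tab <- .cladeTable(tree@phy, tree@support, config,
    warnMissingLength = filtered)
  if (filtered) tab <- .filterClades(tab, config)
  rownames(tab) <- NULL
  tab
}

.checkLeafSets <- function(phyA, phyB) {
  a <- phyA$tip.label; b <- phyB$tip.label
  if (!setequal(a, b)) {
    onlyA <- setdiff(a, b); onlyB <- setdiff(b, a)
    .amStop("amLeafSetError", sprintf(
      "leaf sets differ; only in first tree: {%s}; only in second: {%s}",
      paste(onlyA, collapse = ", "), paste(onlyB, collapse = ", ")))
  }
}

#' Plain rooted Robinson-Foulds distance
#'
#' The size of the symmetric difference between the two trees' sets of
#' non-trivial rooted clades: topology only, no branch lengths, no
#' supports, no filtering.
#'
#' @param treeA,treeB [LabeledTree-class] objects on identical leaf sets.
#' @return non-negative integer.
#' @examples
#' a <- parseNewick("((a|d,b|d),(c|d,d|d));")
#' b <- parseNewick("((a|d,c|d),(b|d,d|d));")
#' rfDistance(a, b)  # 4: the clade sets {ab},{cd} and {ac},{bd} are disjoint
#' @export
rfDistance <- function(treeA, treeB) {
  stopifnot(is(treeA, "LabeledTree"), is(treeB, "LabeledTree"))
  .checkLeafSets(treeA@phy, treeB@phy)
  cfg <- metricConfig()
  ka <- .cladeTable(treeA@phy, treeA@support, cfg, FALSE)$key
  kb <- .cladeTable(treeB@phy, treeB@support, cfg, FALSE)$key
  sum(!(ka %in% kb)) + sum(!(kb %in% ka))
}

#' Weighted rooted Robinson-Foulds distance
#'
#' Modified rooted RF objective: every clade in the symmetric difference
#' of the two trees' clade sets contributes its own tree's weight,
#' `effective stem length x effective support` — unless its own support
#' falls strictly below the threshold, which removes that term from the
#' calculation.  Clades present in both trees never contribute, whatever
#' their supports, so the distance is non-increasing in the threshold.
#' Identical trees score 0; with all lengths and supports equal to 1 the
#' value coincides with [rfDistance()].
#'
#' @param treeA,treeB [LabeledTree-class] objects on identical leaf sets.
#' @param config a [metricConfig()].
#' @return non-negative numeric.
#' @examples
#' a <- parseNewick("((a|d:1,b|d:1)0.9:0.1,(c|d:1,d|d:1)1.0:0.1);")
#' b <- parseNewick("((a|d:1,c|d:1)1.0:0.1,(b|d:1,d|d:1)1.0:0.1);")
#' weightedRfDistance(a, b)  # 0.09 + 0.1 + 0.1 + 0.1 = 0.39
#' @export
weightedRfDistance <- function(treeA, treeB, config = metricConfig()) {
  stopifnot(is(treeA, "LabeledTree"), is(treeB, "LabeledTree"))
  .checkLeafSets(treeA@phy, treeB@phy)
  ta <- .cladeTable(treeA@phy, treeA@support, config)
  tb <- .cladeTable(treeB@phy, treeB@support, config)
  da <- .filterClades(ta[!(ta$key %in% tb$key), , drop = FALSE], config)
  db <- .filterClades(tb[!(tb$key %in% ta$key), , drop = FALSE], config)
  sum(da$weight) + sum(db$weight)
}
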