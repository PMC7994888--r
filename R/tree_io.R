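# Newick I/O with support-value handling and accession|allele leaf labels.

#' Parse accession + allele identity from raw leaf labels
#'
#' The default grammar splits at the LAST occurrence of `delimiter`
#' (accessions routinely contain `"."`, `"-"` and `"/"`, so a reserved
#' delimiter is the safe convention).  A label with no delimiter is taken to
#' be a direct (unphased, typically Sanger) sequence and receives allele
#' code `"d"`.  Alternatively a Perl regular expression with named capture
#' groups `accession` and `allele` may be supplied.
#'
#' @param raw character vector of leaf labels.
#' @param delimiter single string separating accession from allele code.
#' @param regex optional Perl regex with named groups `accession`, `allele`;
#'   overrides `delimiter`.
#' @return `data.frame` with columns `accession` and `allele`.
#' @examples
#' parseLeafLabel("H63-15-15|0.0")
#' parseLeafLabel("His.his.2|s")
#' parseLeafLabel("caeb.Jbo.2")   # no delimiter -> direct sequence "d"
#' @export
parseLeafLabel <- function(raw, delimiter = "|", regex = NULL) {
  if (!length(raw) || any(!nzchar(raw)))
    .amStop("amParseError", "empty leaf label")
  if (!is.null(regex)) {
    if (!grepl("\\(\\?<accession>", regex) || !grepl("\\(\\?<allele>", regex))
      .amStop("amConfigError",
        "label regex must define named capture groups 'accession' and 'allele'")
    m <- regexpr(regex, raw, perl = TRUE)
    if (any(m < 0))
      .amStop("amParseError", sprintf("leaf label(s) not matching grammar: %s",
        paste(raw[m < 0], collapse = ", ")))
    st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
    acc <- substr(raw, st[, "accession"], st[, "accession"] + len[, "accession"] - 1L)
    code <- substr(raw, st[, "allele"], st[, "allele"] + len[, "allele"] - 1L)
  } else {
    pat <- paste0("\\", delimiter, "(?!.*\\", delimiter, ")")
    pos <- regexpr(pat, raw, perl = TRUE)
    acc <- ifelse(pos > 0, substr(raw, 1L, pos - 1L), raw)
    code <- ifelse(pos > 0, substring(raw, pos + nchar(delimiter)), "d")
  }
  bad <- !nzchar(acc) | !nzchar(code)
  if (any(bad))
    .amStop("amParseError", sprintf("label(s) with empty accession or allele: %s",
      paste(raw[bad], collapse = ", ")))
  data.frame(accession = acc, allele = code, stringsAsFactors = FALSE)
}

# Normalize supports: values > 1 anywhere mean the whole tree is annotated in
# percent; divide by 100.  Idempotent. Values outside [0, 100] are an error.
.normalizeSupport <- function(x) {
  v <- x[!is.na(x)]
  if (!length(v)) return(x)
  if (any(v < 0) || any(v > 100))
    .amStop("amRangeError", "support value outside [0, 100]")
  if (any(v > 1)) {
    if (any(v > 0 & v <= 1))
      warning("mixed support scales (values both in (0,1] and >1); ",
        "treating the whole tree as percentages", call. = FALSE)
    x <- x / 100
  }
  x
}

# Detect and convert ")[0.9]"-style bracketed support comments into internal
# node labels so ape can parse them (ape silently discards comments).
.commentsToLabels <- function(text) {
  gsub("\\)\\s*\\[([-+0-9.eE]+)\\]", ")\\1", text)
}

.checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        .amStop("amParseError",
          sprintf("malformed Newick: unbalanced ')' at character %d", i),
          offset = i)
    }
  }
  if (depth != 0L)
    .amStop("amParseError",
      sprintf("malformed Newick: %d unclosed '(' at end of string", depth),
      offset = nchar(text))
  if (!grepl(";\\s*$", text))
    .amStop("amParseError", "malformed Newick: missing terminal ';'",
      offset = nchar(text))
  invisible(TRUE)
}

#' Read a rooted Newick tree with supports and allele-labeled leaves
#'
#' Internal-node supports are accepted either as node labels (IQ-TREE /
#' MrBayes consensus style, e.g. `")90:0.2"`) or as bracketed comments
#' immediately after the closing parenthesis (`")[0.9]:0.2"`); `"auto"`
#' prefers node labels and falls back to comments.  Any support value
#' greater than 1 switches the whole tree to the percentage convention
#' (divided by 100).  Leaf labels are parsed with [parseLeafLabel()] and
#' rewritten to the canonical `"accession|allele"` form.
#'
#' @param text Newick string (one tree).  Exactly one of `text`/`file`.
#' @param file path to a Newick file.
#' @param supportConvention `"auto"`, `"node-label"` or `"comment"`.
#' @param delimiter,regex leaf-label grammar, see [parseLeafLabel()].
#' @return a [LabeledTree-class].
#' @examples
#' parseNewick("((A|0:0.1,A|1:0.1)90:0.2,B|s:0.3);")
#' @export
parseNewick <- function(text = NULL, file = NULL,
                        supportConvention = c("auto", "node-label", "comment"),
                        delimiter = "|", regex = NULL) {
  supportConvention <- match.arg(supportConvention)
  if (is.null(text)) {
    if (is.null(file)) .amStop("amConfigError", "supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .checkNewickSyntax(text)

  useComments <- switch(supportConvention,
    "comment" = TRUE,
    "node-label" = FALSE,
    "auto" = grepl("\\)\\s*\\[", text) && !grepl("\\)[0-9]", text))
  if (useComments) text <- .commentsToLabels(text)

  # single-leaf degenerate tree: "label;" or "label:0.3;" (ape cannot parse it)
  if (!grepl("\\(", text)) {
    body <- sub(";\\s*$", "", text)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    lab <- parts[1]
    len <- if (length(parts) > 1L) as.numeric(parts[2]) else NA_real_
    al <- parseLeafLabel(lab, delimiter = delimiter, regex = regex)
    phy <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = .canonicalLabel(al$accession, al$allele),
      Nnode = 1L), class = "phylo")
    if (!is.na(len)) phy$edge.length <- len
    return(.lt(phy, NA_real_))
  }

  phy <- tryCatch(ape::read.tree(text = text),
    error = function(e) .amStop("amParseError",
      paste0("malformed Newick: ", conditionMessage(e))))
  if (is.null(phy))
    .amStop("amParseError", "malformed Newick: ape could not parse the string")
  if (inherits(phy, "multiPhylo"))
    .amStop("amParseError", "expected exactly one tree")

  support <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    raw <- phy$node.label
    raw[!nzchar(raw)] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    support <- .normalizeSupport(num)
  }

  al <- parseLeafLabel(phy$tip.label, delimiter = delimiter, regex = regex)
  canon <- .canonicalLabel(al$accession, al$allele)
  if (anyDuplicated(canon))
    .amStop("amDuplicateLeafError",
      sprintf("duplicate (accession, allele) leaf label(s): %s",
        paste(unique(canon[duplicated(canon)]), collapse = ", ")))
  phy$tip.label <- canon
  .lt(phy, support)
}

#' Serialize a LabeledTree to Newick
#'
#' Supports are written as internal-node labels, either on the normalized
#' `[0, 1]` scale (`supportAs = "fraction"`) or multiplied by 100
#' (`"percent"`, e.g. support 0.9 becomes `"90"`).  Branch lengths are kept
#' to 15 significant digits so that parse/write round-trips are exact at
#' that precision.
#'
#' @param tree a [LabeledTree-class].
#' @param file optional path; if given the string is also written there.
#' @param supportAs `"fraction"` or `"percent"`.
#' @return the Newick string, invisibly when `file` is given.
#' @export
writeNewick <- function(tree, file = NULL, supportAs = c("fraction", "percent")) {
  stopifnot(is(tree, "LabeledTree"))
  supportAs <- match.arg(supportAs)
  phy <- tree@phy
  if (length(phy$tip.label) == 1L) {
    out <- phy$tip.label
    if (!is.null(phy$edge.length) && !is.na(phy$edge.length[1]))
      out <- paste0(out, ":", .fmtNum(phy$edge.length[1]))
    out <- paste0(out, ";")
  } else {
    s <- tree@support
    if (supportAs == "percent") s <- s * 100
    lab <- ifelse(is.na(s), "", .fmtNum(s))
    phy$node.label <- lab
    out <- ape::write.tree(phy, digits = 15)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
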