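# Internal helpers: structured conditions, seeded evaluation, label handling.

.amStop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "amError")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split canonical tip labels "accession|code" at the LAST "|".
.splitCanonical <- function(labels) {
  pos <- regexpr("\\|[^|]*$", labels)
  acc <- ifelse(pos > 0, substr(labels, 1L, pos - 1L), labels)
  code <- ifelse(pos > 0, substring(labels, pos + 1L), "d")
  list(accession = acc, allele = code)
}

.canonicalLabel <- function(accession, allele) paste(accession, allele, sep = "|")

# Format a non-negative real for Newick output, 15 significant digits.
.fmtNum <- function(x) formatC(x, digits = 15, format = "g", width = 1)
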