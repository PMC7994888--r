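Package: alleleMatcher
Title: Matching Phased rDNA Alleles Between Gene Trees of Two Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking phased alleles of multi-copy nuclear markers
    (e.g. ITS and ETS of the 45S rDNA cistron) across two rooted gene trees
    of the same accessions. Given two Newick trees whose leaves encode
    accession plus allele identity, the package searches for the
    per-accession allele pairing that makes the two trees most similar,
    using a seeded multi-restart local optimization under the plain rooted
    Robinson-Foulds distance followed by an exhaustive global optimization
    under a branch-length and support weighted rooted Robinson-Foulds
    objective with a 50 percent support cutoff. Includes preprocessing
    (pruning to shared accessions, collapsing within-accession allele
    clades), both tree distances, a synthetic paired-tree generator with
    known ground truth for validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
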