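---
title: "Matching phased rDNA alleles between two gene trees"
author: "alleleMatcher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching phased rDNA alleles between two gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleMatcher)
```

## The problem

Multi-copy nuclear markers such as the ITS and ETS spacers of the 45S rDNA
cistron evolve under concerted evolution: the tandem repeats of one genome
are homogenized towards one or a few variants, and read-based phasing of
low-coverage genome skims recovers those variants ("alleles" in a loose
sense — each may be a majority consensus of many repeat units) separately
for each marker. Because the conserved 18S region between ITS and ETS
carries no polymorphism, nothing physically links an ITS allele of an
accession to an ETS allele of the same accession, and naive pairing can
produce *in silico* recombinants. The number of recovered alleles per
accession also routinely differs between the markers.

Given the two rooted single-marker trees, this package searches for the
per-accession allele pairing (a *combination*) that makes the trees most
similar. The premise is phylogenetic: alleles that share a history should
occupy corresponding positions in the two trees, so the correct pairing
minimizes a tree distance after the leaves are relabeled according to it.

## Objective functions

Both objectives operate on *rooted clades* — the trees are rooted and a
rooted comparison retains the direction of ancestry that an unrooted
bipartition distance would discard.

* **Plain rooted Robinson–Foulds distance** `rfDistance()`: the number of
  non-trivial clades (size at least 2, smaller than the full leaf set)
  present in exactly one of the two trees. Topology only.
* **Weighted rooted RF** `weightedRfDistance()`: every discordant clade
  contributes the product of its stem branch length and the support of
  the node it subtends; a discordant clade whose support is strictly
  below the threshold (default 0.5) is removed from the calculation.
  Clades present in both trees never contribute.

The multiplicative combination of length and support is the only
symmetric, scale-sensible composition of the two factors: a conflict on a
long, well-supported branch should cost more than one on a short or
weakly supported branch, and either factor near zero should annihilate
the term. Two boundary policies are configurable in `metricConfig()`:
clades without a support annotation (for example, nodes created by
collapsing) are retained with effective support 1 by default, so that
unannotated structure does not silently vanish from the objective; clades
without a stem length contribute weight 0 with a warning (`"as-1"`
degenerates to support-only weighting for length-free trees). Support
exactly at the threshold is retained, mirroring a strict "less than 50%"
removal rule. Internally, values above 1 anywhere in a tree switch the
whole tree to the percentage convention.

One design point deserves emphasis because it is easy to get wrong: the
support filter applies to each discordant clade's *own* support, after
the symmetric difference is formed. Filtering the two clade sets *before*
comparing them looks equivalent but is not — a weakly supported clade in
one tree would then un-match the identical, strongly supported clade of
the other tree and *add* a distance term as the cutoff rises, so the
distance would not be monotone in the threshold. Under the semantics used
here, raising the threshold can only remove terms.

## Preprocessing

`linkAlleles()` first prunes both trees to their shared accessions
(degree-2 nodes are suppressed, their branch lengths summed, their
supports discarded — the clades those supports described no longer
exist). It then collapses every *maximal* clade whose leaves all belong
to one accession into a single leaf (`collapseMonoaccessionClades()`).
Such coalescent allele groups carry no information for choosing between
pairings — any within-group assignment produces isomorphic trees — so
removing them shrinks the combinatorial space without changing the
optimum. The collapsed branch receives the length of the clade's stem
plus the pendant length of its most basal member, read as the leaf
attached topologically closest to the clade root, ties broken
lexicographically by allele code. (The wording "the length of one of the
alleles" admits several readings; this one preserves the depth of the
group, and the collapse report records every member so nothing is lost.)
The collapse is idempotent and commutes with pruning.

## The two-phase search

Exhausting all combinations is exponential: an accession with allele sets
of sizes $m \le n$ admits $n!/(n-m)!$ injective pairings, and the
combinations multiply across accessions. The search therefore runs in two
phases.

**Local phase** (`localOptimize()`, plain RF). A random combination is
drawn; accessions are then swept in random order, and for the focal
accession every pairing is evaluated with all other accessions held
fixed. The focal accession moves to a minimizing pairing; *all*
minimizers encountered are recorded. Sweeps repeat to a fixed point
(capped at `maxSweeps`), and the whole procedure restarts from a fresh
random combination `restarts` times (default 10), the recorded minimizer
sets being unioned across sweeps and restarts. A single restart
reproduces a one-shot random assignment; the default of 10 exists because
coordinate descent from one random start can stall in a local optimum —
restarts can only enlarge the candidate pool. The identity pairing is
force-included in every retained set, which makes "keep" always
expressible and bounds the final score by the score of not swapping
anything.

**Global phase** (`globalOptimize()`, weighted RF). Every combination in
the Cartesian product of the retained sets is scored; the product is
capped (`globalCap`, default $10^6$) with a clear capacity error beyond
it. All co-optima within an absolute tolerance of $10^{-9}$ are kept and
condensed into per-accession verdicts: **keep** if every optimum uses the
identity pairing, **swap** if none does, **equivocal** if both occur.
Equivocal accessions are genuinely undecidable from the trees (symmetric
placements, fully collapsed groups with several pairings); the package
reports them and never auto-resolves.

Accessions with unequal allele counts are handled by an injective map
from the smaller set into the larger; the unmatched alleles are either
pruned before the distance computation (default — plain RF is defined on
equal leaf sets and pruning introduces no artificial structure) or, with
`mode = "duplicate"`, the smaller side's allele is duplicated onto a
zero-length polytomy, mirroring the convention that a single sequence of
one region is concatenated with both variants of the other region.
`concatenationPlan()` emits that table, expanding collapsed groups back
to their members.

Ties between floating-point scores use an absolute tolerance of $10^{-9}$,
far below any realistic branch-length resolution and far above the
$10^{-12}$-level noise of the arithmetic.

## A worked example

```{r example}
a <- parseNewick(paste0("(((W|s:1,X|0:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
  "(X|1:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
b <- parseNewick(paste0("(((W|s:1,X|1:1)0.9:1,(Y|0:1,Z|0:1)0.9:1)0.9:1,",
  "(X|0:1,(Y|1:1,Z|1:1)0.9:1)0.9:1);"))
res <- linkAlleles(a, b, searchConfig(seed = 1))
res
verdicts(res)
concatenationPlan(res)
```

Tree `b` equals tree `a` with accession X's allele labels exchanged, and
the anchor accession W breaks the symmetry: the optimum swaps X, keeps
everything else, and attains distance 0.

## The synthetic generator

`makePairedInstance()` produces paired trees with known truth so that
every property of the matcher is testable without any external data. It
emulates, feature by feature, the situation the matcher is built for:

* a shared accession history — a Yule pure-birth tree (`ape::rphylo`,
  birth rate 1), the standard neutral null for species-level trees;
* 1–4 alleles per accession per marker (four is the hard cap of two
  phasing rounds), named by the hierarchical scheme `s` / `0`,`1` /
  `0`,`1.0`,`1.1` / `0.0`,`0.1`,`1.0`,`1.1`, with default count
  probabilities (0.35, 0.45, 0.10, 0.10) reflecting that one or two
  variants per accession are the common outcome of concerted evolution;
* per accession, a *coalescent* or *divergent* second main lineage
  (default probability 0.5 each). Coalescent lineages attach as shallow
  clades at the accession's position (depths at most 10% of tree height,
  second-round splits at most 2%); divergent lineages are grafted
  elsewhere on the accession tree — at the same point for both markers,
  since the allelic history is shared — with the grafted tip reaching
  the present. Divergence is what gives the matching problem its signal:
  alleles of a coalescent group are interchangeable by construction, and
  the generator never grafts a "divergent" lineage onto the accession's
  own pendant edge, which would only rebuild a cherry;
* planted swaps: a configurable fraction of the *eligible* accessions
  (divergent, two alleles in both markers) has its tree-B labels
  permuted, recorded as truth. Swapping a coalescent pair would be
  unobservable in principle — the relabeled trees are isomorphic — so
  truth is only planted where it is recoverable, and `verdictRecovery()`
  scores exactly those accessions;
* noise on tree B only (the distance is symmetric, one fixed reference
  simplifies the bookkeeping): random *rooted* nearest-neighbor
  interchanges, each changing at most one clade per tree, and a
  lognormal multiplier on branch lengths. Supports are drawn uniformly
  on [0.5, 1] by default, so that support weighting is active but the
  cutoff does not remove signal at random.

What the generator does *not* emulate: incomplete lineage sorting or any
coalescent process (noise is phenomenological NNI/jitter), sequence-level
error, alignment artifacts, or recombination *within* a marker. Passing
tests therefore certify the search and the metrics, not the biological
correctness of phasing on real data.

## Validation, problem sizes, numerical choices

The test suite and `scripts/acceptance.R` recompute, from scratch:

1. agreement of the two-phase search with an exhaustive brute-force scan
   (which skips the local phase and scores through explicit tree
   surgery) on 100 instances of 4–6 accessions, two alleles each, 0–2
   NNI moves, at 10 and at 50 restarts;
2. perfect recovery of noise-free planted swaps on 100 six-accession
   instances, equivocal verdicts accepted only where the brute-force
   scan proves exact co-optima;
3. the metric axioms (identity, symmetry, non-negativity, even parity of
   plain RF on binary trees, threshold monotonicity, reduction of the
   weighted metric to plain RF at unit lengths and supports) against an
   independent bitmask clade oracle on 200 random pairs of up to 12
   leaves;
4. the hand-computed 4-leaf example: weighted distance
   $0.09 + 0.1 + 0.1 + 0.1 = 0.39$, and exactly 0 when every support
   drops below the cutoff;
5. mean recovery over 50 seeds at 0, 2, 4 and 8 NNI moves, which must be
   non-increasing (a 0.05 allowance absorbs sampling noise);
6. byte-identical reruns at a fixed seed and exact Newick round-trips.

These sizes keep the whole validation within a couple of minutes on one
CPU while exercising every code path, including per-combination pruning
for unbalanced allele counts. The matcher scores combinations through a
bitmask fast path (each matched pair is a power of two; a clade's
identity is the sum over its matched descendants) whenever harmonization
is by pruning and at most 52 pairs are in play — the mask then fits a
double exactly; larger or duplicate-mode problems fall back to explicit
tree surgery, and a dedicated test pins the two routes to each other.

## Known limitations

* Exactly two markers; matching three or more trees simultaneously is a
  different (harder) problem.
* The local phase is a heuristic: with pathological symmetry it can in
  principle miss a global optimum that none of its restarts approaches,
  which is why the brute-force agreement is monitored and why `restarts`
  is cheap to raise.
* Branch lengths are taken as given; nothing is re-estimated.
* The tool reports equivocal accessions; deciding them requires evidence
  outside the two trees (morphology, ploidy, geography) and is left to
  the user.
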