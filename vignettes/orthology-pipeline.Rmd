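---
title: "Models and design of the orthology / identity pipeline"
author: "orthopipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the orthology / identity pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopipe)
```

# Scope

`orthopipe` implements a comparative-genomics workflow for multi-species
protein sets: ortholog clustering, orthology categorisation,
conserved-block-restricted sequence identity, closest-relative
classification with a lowess smoother, and a bootstrapped
neighbor-joining supermatrix phylogeny. A ground-truthed proteome
simulator is a first-class component: it defines the synthetic study
conditions under which every stage is validated.

This vignette explains the models, the tunable parameters and their
defaults, the numerical conventions, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The proteome evolution simulator

## Replacement model

Sequences evolve along a rooted species tree with branch lengths in
expected replacements per site. Along a branch of length $d$, each site
is hit by at least one replacement event with probability $1 - e^{-d}$
(Poisson events of unit rate); a hit site is redrawn from the stationary
amino-acid frequencies $\pi$ — *possibly to the same residue*. Because
redraws are independent of the previous state and $\pi$ is stationary,
two sequences whose connecting path has total length $D$ match at a site
with probability

$$P(\text{match}) = e^{-D} + \left(1 - e^{-D}\right)\sum_a \pi_a^2 .$$

This "draw from $\pi$ including identity" model was chosen over an
empirical rate matrix (WAG, LG, …) deliberately: it admits an exact
closed-form identity expectation, which the tests use as an oracle with
known binomial sampling error. Verifiability beats realism here. The
model is stationary and reversible, identity is monotone decreasing in
$D$ in expectation, and the per-ortholog identity ordering therefore
reflects the tree — the property the downstream comparisons rely on.

Defaults: root sequence length 300 residues, uniform $\pi$; both
configurable. There is no indel process (simulated families are
gap-free by construction), no rate heterogeneity across sites, and no
codon level — all declared non-goals; the gap-handling code paths are
exercised by hand-constructed alignments instead.

## Families, categories, duplications

`sampleFamilies()` draws a mixture of family categories and realises a
per-species copy-count vector for each family; every generated vector is
re-checked against the category classifier, so generator and classifier
cannot drift apart. Two constructive conventions:

* **Duplication placement.** A species with copy count $c > 1$
  duplicates at the *midpoint of its terminal branch*: the lineage
  evolves once to the midpoint, then $c$ copies evolve independently
  over the remaining half. One unambiguous convention instead of a
  birth–death process.
* **Species-specific families have at least two copies.** A single gene
  with no homologs anywhere can never form a cluster, so a one-copy
  "specific" family would be unrecoverable by construction; requiring a
  duplication makes the category observable downstream (a lone
  unclustered gene is instead surfaced as `homology-only`/`none`).
* **`homology-only` cannot be sampled.** It is a property of the
  clustering outcome (a gene with retained hits but no group), not of a
  family's copy structure; the generator rejects it.

Some categories are unrealisable for small species universes
(`patchy` needs $\lceil S/2\rceil > 2$, `lineage-only` needs a lineage
of at least three species); the generator fails loudly rather than
silently mislabelling.

Randomness: one master seed; each family derives a substream by a stable
31-bit string hash of its identifier, so a family's sequences are
reproducible regardless of how many other families are drawn, and the
whole set is reproducible under reordering. Gene identifiers follow the
pipe dialect `<species>|<family>|g<k>`; splice isoforms in real input
use a trailing `iso<k>` field.

# Similarity search and E-values

The built-in backend computes optimal Smith–Waterman/Gotoh local
alignments (affine gaps: a gap of length $k$ costs
$\mathrm{open} + k\cdot\mathrm{ext}$) through Biostrings, with BLOSUM62,
open 11, extend 1 — the standard protein defaults. Raw scores are
converted with the Karlin–Altschul form $E = K m n e^{-\lambda S}$ using
the standard gapped BLOSUM62 constants $K = 0.041$, $\lambda = 0.267$,
with effective lengths equal to actual lengths. Only the ordering of
E-values and the $E < 10^{-5}$ cut matter downstream, so no edge-effect
or composition corrections are applied. Hits are kept when
$E < 10^{-5}$; within-species hits are retained (they carry inparalog
edges), self-hits are dropped; duplicate (query, subject) rows collapse
to the best by E-value, ties by bit score; imported E-values of exactly
zero are floored at $10^{-200}$ before log transforms.

Exhaustive pairwise DP is quadratic in the number of genes and meant for
desk-scale inputs; for larger sets the package either shells out to
BLAST+ (`method = "blast"`) or ingests externally computed hits in the
standard 12-column tabular layout (`readHits()`). All downstream stages
are agnostic to the backend.

# Ortholog clustering

The similarity graph has an edge only where *both* directed hits passed
the threshold; the weight is the mean of the two $-\log_{10} E$ values,
capped at 200. The full OrthoMCL inparalog weight normalisation is not
reproduced — plain reciprocal averaging is fully specifiable and
preserves the cluster structure the analysis needs.

Markov clustering runs per connected component (components cannot
interact, and dense per-component matrices are faster and exactly
equivalent): self-loops at each node's maximum incident weight, column
normalisation, then alternating expansion (matrix squaring) and
inflation (elementwise power, renormalisation), pruning entries below
`pruneEps`, until the matrix changes by less than $10^{-8}$ or `maxIter`
is reached (then: current interpretation plus a warning and a
`converged = FALSE` flag). Clusters are read off attractor rows.
Defaults: inflation 1.5, `pruneEps` $10^{-5}$, `maxIter` 100 — common
Markov-clustering conventions. Everything is deterministic; nodes are
processed in sorted gene-id order.

# Orthology categories

Copy-count vectors over the declared species universe ($S$ species) are
labelled with a fixed precedence, because the category definitions
overlap and no precedence is canonical:

1. **species-specific** — all members in one species;
2. **universal-single** — exactly one copy everywhere, tolerating
   absence *or* duplication in at most one genome;
3. **universal-multi** — presence in at least $S - 1$ genomes;
4. **lineage-only** — presence confined to the configured lineage
   subset, in at least three genomes;
5. **present-at-half** — presence in at least $\lceil S/2 \rceil$
   genomes (the generalisation of "at least six of twelve");
6. **patchy** — everything else.

The lineage set is configuration, never inferred. Restricting
"specific" to groups whose members all come from one species resolves
the ambiguity with families that are universal but duplicated in a
single genome (those read as universal here). The classifier is
validated against an independently coded brute-force rule table on
random vectors; the rules are exhaustive and mutually exclusive by
construction of the precedence.

Single-copy selection for the supermatrix supports a *strict* mode
(exactly one copy in every species of the subset — the concatenation
contract requires it) and a *tolerant* mode (the universal-single rule
on the subset). Projection onto a species subset simply ignores copies
outside the subset; re-clustering a subset from scratch is also
possible by rerunning the pipeline on fewer proteomes.

# Alignment and conserved blocks

The built-in progressive aligner exists so the pipeline runs with no
external binary: guide tree by average-linkage clustering of pairwise
global-alignment distances ($1 - $ identity), then profile–profile
global alignment with sum-of-pairs scoring and affine gaps (penalties
scaled by the number of crossing sequence pairs), columns never
reordered. The DP kernel is compiled (Rcpp). An imported alignment
always takes precedence when supplied (`readAlignment()`); reproducing
any specific external aligner's output is a non-goal.

Conserved-block extraction classifies columns by the count of rows
sharing the majority residue (most frequent non-gap residue, ties by
alphabetical residue — the tie only affects the recorded residue, not
the count): *nonconserved* below `b1`, *conserved* from `b1`, *highly
conserved* from `b2`. Runs of more than `b3` contiguous nonconserved
columns are rejected and break blocks; candidate segments are trimmed
from both ends until flanked by highly conserved columns; blocks
retaining fewer than `b4` columns are dropped. Defaults for $n$ rows:
`b1` $= \lfloor n/2\rfloor + 1$, `b2` $= \max(b1, \lceil 0.85
n\rceil)$, `b3` $= 8$, `b4` $= 10$ — the classic conserved-block
defaults; they are recorded in each result's parameters. Gap policy:
by default any column containing a gap is nonconserved and can never be
retained (`"half"` and `"all"` are available). Retained columns are
stored 1-based internally (R convention) and reported 0-based,
half-open in tabular output.

Identity for a species pair is computed *within the commonly aligned
blocks*: the retained set is extracted once per group from the
alignment containing all analyzed species, so every pair is compared on
the same columns; the denominator counts only retained columns where
both rows are non-gap, and a pair with zero comparable columns yields
no record (logged). Whether to restrict to blocks at all is a flag
(`restrictBlocks`), since distribution-style summaries can also be run
on whole alignments.

# Distribution summaries, three-way comparison, lowess

Boxplot summaries use linear-interpolation (type-7) quartiles and the
standard notch $1.58\,\mathrm{IQR}/\sqrt{n}$ — conventional choices
where no convention is forced. The three-way comparison labels a group
"closer" to comparator A when $\mathrm{id}(f,A) - \mathrm{id}(f,B) >
\varepsilon$; the tie tolerance defaults to 0 (exact ties only) and
ties are reported separately rather than folded into either side.

The smoother is the classic lowess: local linear regression with
tricube weights over the $\lceil \mathrm{frac}\cdot n\rceil$ nearest
neighbours and bisquare robustness re-weighting, defaults
$\mathrm{frac} = 2/3$ and 3 robust passes, computed by `stats::lowess`
with `delta = 0` so every point is fitted exactly; the test suite holds
it against a from-scratch reimplementation. A coefficient of
determination for a smoother is not standard, so the definition is
declared explicitly: $R^2 = 1 - SS_{res}/SS_{tot}$ with fitted values
taken at the observed x. Degenerate inputs: all-equal x fits
$\bar{y}$ everywhere ($R^2 = 1$ iff y constant); constant y gives
$R^2 = 1$ when the residuals are numerically zero.

# Supermatrix and tree

Retained blocks concatenate per species in lexicographic group order
(canonical, hence order-invariant), with partition offsets recorded;
empty retained sets contribute zero columns. Distances are p-distances
($1 -$ identical/comparable columns). The tree method is neighbor
joining rather than maximum likelihood: NJ on p-distances is exact on
additive matrices, fully specifiable, and fast enough to bootstrap
densely; ML remains pluggable by importing a newick tree. Negative NJ
branch lengths are clamped to zero with a warning. Output trees are
unrooted; rooting by outgroup is a presentation choice left to the
caller.

Bootstrap: supermatrix columns are resampled with replacement, NJ is
rebuilt per replicate, and each internal bipartition of the full-data
tree is scored by the percentage of replicates containing it (default
100 replicates). Because p-distances depend only on the *multiset* of
columns, the implementation first sorts columns by site pattern; this
makes supports exactly invariant to supermatrix column order without
changing their distribution.

# Pipeline, reproducibility, formats

`runPipeline()` executes the twelve stages in order and writes one
artifact per stage plus a JSON manifest (all parameters, the master
seed, input checksums, per-stage in/out counts — genes removed by the
isoform filter, groups dropped for missing species, and so on). Every
tabular output is tab-separated with a single `#`-prefixed header line
and sorted on a documented key, so runs are diffable; identical
configurations give byte-identical outputs. Stochastic stages draw
named substreams from the master seed, so any stage can be re-run in
isolation. A stage failure halts the run with the stage name and a
machine-readable `status.json`.

This is an R package driven from R: the exported per-stage functions
plus `runPipeline()` are the command surface, and
`scripts/acceptance.R` is the only shell entry point (it regenerates
the synthetic study conditions and recomputes the headline numbers).

# What the synthetic conditions do and do not show

The simulator emulates: a fixed species tree with branch lengths, the
category mixture of gene families, and stationary sequence divergence
in which identity ordering follows the tree. It does not emulate
indels, alignment error, rate heterogeneity, domain shuffling, lateral
transfer, or annotation noise — so passing tests demonstrate the
correctness of the implemented procedures under their stated model, not
robustness to every artefact of real proteomes. Multi-copy families
have no closed-form identity guarantee (duplication timing interacts
with the path structure); the identity oracle is therefore stated for
single-copy families only.

Problem sizes used by the validation runs — 100 families × 300 residues
per path-distance point for the identity oracle, 10,000 random vectors
for the classifier, 50 random graphs (≤ 15 nodes) for the clustering
reference, a 4-species × 500-family set for end-to-end recovery, and a
6-species × 500-family set with 100 bootstrap replicates for the
ordering/topology checks — were chosen so that expected sampling error
is far smaller than the effects being verified (for example, at the
0.4 vs 0.8 path-distance contrast the closed-form identities differ by
about twelve percentage points, two orders of magnitude above the
per-ortholog standard error at 300 residues).
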