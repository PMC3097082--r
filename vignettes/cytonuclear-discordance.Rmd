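---
title: "Detecting cytonuclear discordance and reconstructing ancestral states with phyloconflict"
author: "phyloconflict authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cytonuclear discordance and reconstructing ancestral states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

Hybridization followed by genome doubling (allopolyploidy) leaves a
characteristic molecular signature: the nuclear genome records one
parental history and the maternally inherited chloroplast genome the
other, so gene trees estimated from the two genomes place the hybrid in
contradictory, well-supported positions. In groups such as
*Potentilla* (Rosaceae), where many species carry several ploidal
levels (2x up to 13x), comparing a nuclear and a plastid phylogeny and
asking *which contradictions coincide with elevated ploidy* is the
standard first screen for allopolyploid speciation. Incomplete lineage
sorting and chloroplast capture can produce the same topological
signal, so the package flags *candidates*; it does not claim to
separate these processes.

`phyloconflict` implements that screen as a reusable, tested pipeline:

1. **Tree handling** — Newick I/O with posterior probabilities as
   internal node labels, split extraction above a support threshold,
   majority-rule consensus from posterior tree samples, pruning,
   deterministic polytomy resolution.
2. **Matrix preparation** — end truncation, reference-coordinate
   column exclusion, concatenation with missing-data fill, and simple
   indel coding of gaps as a binary partition.
3. **Conflict detection** — well-supported incompatible split pairs
   between two trees, clustered into discrete *incongruence events* by
   iterative rogue-clade removal.
4. **Ploidy flagging** — parsing of cytological ploidy reports and
   flagging of events whose implicated taxa are polyploid.
5. **Mk ancestral-state reconstruction** — maximum-likelihood ER, SYM
   and ARD model fits for discrete morphological characters,
   likelihood-ratio model selection and per-node scaled marginal state
   likelihoods.

## Conflict model

All comparisons are made on unrooted bipartitions (splits) of the
shared taxon set, after pruning both trees to their leaf-set
intersection; outgroup composition and rooting therefore cannot create
spurious conflicts. Two splits conflict iff all four pairwise side
intersections are non-empty — equivalently, no single tree can display
both. A split counts as *supported* only when its node carries a
numeric support ≥ the threshold (default 0.95 in both trees, following
the convention that a clade is contradicted only by an opposing clade
with posterior probability ≥ 0.95); unlabelled edges are conservatively
treated as unsupported.

### Clustering conflicts into events

A single taxon movement between the two trees typically produces many
pairwise split conflicts, so raw pairs are clustered: at each step we
consider as candidates the leaf-descendant sets of nodes (including
single leaves, excluding the root) of either restricted tree, and
remove the candidate whose deletion from both trees reconciles at
least one remaining conflicting pair, preferring the **smallest**
candidate, breaking ties by the number of pairs reconciled and then by
lexicographically smallest taxon. Each removal is one event; removals
accumulate until no conflicts remain, so the events partition the pair
list and the loop always terminates (deleting one side of a conflicting
split always reconciles it).

Preferring the smallest adequate explanation is the design decision
that makes the procedure behave like a systematist's reading of a
tanglegram: a "most pairs reconciled first" rule would always pick a
near-root clade (deleting half the tree reconciles everything at once)
and collapse distinct events into one. The minimality preference
instead attributes each conflict to the smallest clade whose movement
explains it, which is also the natural parallel of rogue-taxon removal
in consensus analysis.

The taxa *involved* in an event are the rogue clade plus, for each
attributed pair, the union of that pair's minimum-cardinality conflict
cells (the four intersections of the two split sides): these are
exactly the taxa whose removal would reconcile the pair, i.e. the taxa
whose placement generates the contradiction. Larger cells — typically
whole background clades — are deliberately not implicated, so an event
is not flagged as polyploid merely because a large clade on the other
side of the conflict happens to contain polyploids.

### Ploidy rule

Ploidy reports are parsed from strings as printed in cytological
compilations (`"8x, 10x"`, `"8x?"`, `"(2x), 4x, (6x)"`,
`"...aneuploids"`, empty = unknown). A taxon is polyploid when any
reported level is ≥ 3x. Uncertain (`?`) and parenthesized reports count
by default — a strict mode excludes them — and unknown ploidy is
conservatively non-polyploid. An event is an allopolyploidy candidate
iff any involved taxon is polyploid; the flagged evidence lists those
taxa and their levels.

## Matrix preparation

Simple indel coding treats every distinct interior gap (identical
start and end columns) observed in at least one taxon as one binary
presence/absence character: 1 for exactly that gap, 0 for no
overlapping gap, `?` for an overlapping gap of different extent or
missing data in the range. Terminal gap runs are missing data (leading
and trailing incompleteness), never coded. Coordinates are 1-based and
inclusive throughout the interface, and reference-anchored exclusions
(e.g. "positions 599–671 of accession X") are mapped through the
reference taxon's gapped sequence, gaps not consuming positions. The
coded gap characters are emitted as their own partition (binary type)
so downstream inference can apply a binary model; tree inference
itself is out of scope.

## The Mk model and ancestral-state reconstruction

A discrete character with k states evolves along the tree as a
continuous-time Markov chain with generator Q: **ER** one shared rate
(1 parameter), **SYM** one rate per unordered state pair (k(k−1)/2;
upper-triangle row-major parameter order), **ARD** one rate per ordered
pair (k(k−1); row-major). Units: expected state changes per unit
branch length. The likelihood is computed by Felsenstein pruning with
per-site rescaling; the root prior is uniform over states by default
(`root_prior = "stationary"` is available; for ER/SYM the stationary
distribution *is* uniform). Missing states enter as all-ones partial
vectors, and zero-length branches contribute identity transitions, so
resolving a polytomy with zero-length branches (`resolve_polytomies()`,
deterministic left-to-right order) leaves the likelihood unchanged —
an invariant the test suite checks against an independent resolution
order.

`fit_mk()` maximises the log-likelihood over log-rates with bounded
L-BFGS-B (bounds 1e-8 to 1e3 per rate) from five fixed starting points
(all-equal rates at 0.05, 0.5, 0.01, 2 and 10, with a 2% deterministic
stagger to separate parameters); `n_starts` can be lowered for large
simulation studies. Nested fits are compared with `anova()`/`mk_lrt()`:
statistic 2·(logL_general − logL_nested) clamped at zero, chi-square
reference with df equal to the parameter-count difference. ER is nested
in SYM is nested in ARD. Note that for k = 2, ER and SYM coincide, so
calibration studies of the ER-vs-SYM test need k ≥ 3.

`ancestral_states()` (or `predict()` on the fit) returns, for every
internal node, the marginal likelihood of each state given all tip
data, normalised to sum to one — the "scaled likelihoods" drawn as
pies at nodes in reconstruction figures. They are computed by
combining the node's subtree partial likelihoods with a preorder
"rest-of-tree" pass, and are verified against explicit enumeration
over all internal-node state assignments on small trees (tolerance
1e-10) and against an independent implementation (`ape::ace`).

## What the simulators emulate — and what they do not

`sim_tree()` grows random binary trees by sequential random leaf
attachment with exponential branch lengths (mean 0.1 substitutions per
site, a typical scale for plant spacer data). `sim_hybrid_pair()`
builds a nuclear/chloroplast pair that agree except for a controlled
set of planted moves: the chloroplast tree is the species tree, and
each moved clade is pruned and re-grafted at topological distance ≥ 3
from its origin, redrawing (within the seed) any draw in which a moved
leaf lands locally adjacent to another moved leaf in either tree. The
distance floor exists because a one- or two-edge move is inherently
confoundable with a move of the old or new neighbour — no method could
attribute it uniquely — and adjacent planted moves merge into a single
event by construction. Supports default to 1.0 on all true splits.
`sim_mk_characters()` evolves characters edge-wise from a uniform root
state with the model's exact transition kernel; `sim_indel_alignment()`
plants gap runs with known sharing patterns. All generators are
byte-identical per seed and return truth tables sufficient to score
the detectors without manual labels.

These simulations emulate *topological* discordance and *clock-free*
character evolution. They do not emulate alignment error, saturation,
model misspecification in the underlying Bayesian tree inference,
rate heterogeneity among characters, or supports below 1.0 on true
clades — so passing recovery tests demonstrate correctness of the
detection machinery, not robustness of the upstream phylogenetics on
real data.

Problem sizes used by the test-suite and acceptance studies (chosen as
comfortable desk-scale studies): enumeration cross-checks on ≤ 5-leaf
trees with k ≤ 3 over 100 parameter draws; SYM recovery with k = 4,
1000 characters on one 64-leaf tree over 50 replicates (single
optimiser start, which matched the 5-start results on this design);
ER-vs-SYM type-I calibration with k = 3, 100 characters on one 16-leaf
tree over 1000 replicates; rogue recovery on 200 scenarios of five
single-leaf moves in 64-leaf trees.

## The bundled Potentilla example

`potentilla_fixture()` ships a worked example for *Potentilla*: a
table of published ploidal levels, clade assignments (A Anserina,
B Alba, C Fragarioides, D Reptans, E ivesioid, F Argentea, plus seven
Fragariinae outgroups) and two floral characters (style shape L/N/G/C,
anther shape A–D) for 72 taxa, together with schematic nuclear and
chloroplast consensus topologies encoding the published clade
structure and its five between-genome contradictions. The trees are
*synthetic encodings* (filenames say so): supports are as printed
where a posterior probability is printed, 0.99 where a placement is
described only as well-supported, and branch lengths are set to 1
because the original consensus trees' branch lengths are not bundled.
Ancestral-state reconstruction on these trees is therefore
qualitative — state identities at nodes, not trustworthy
probabilities. Within-clade structure that the source describes as
unresolved is encoded as polytomies without supports, so it can never
generate supported conflicts. One taxon appears in the table but not
the trees (*P. clusiana*, excluded from the molecular analyses after a
recombination screen), and the clade column spells each clade's name
on its first row exactly as tabulated.

Running the pipeline on the fixture:

```{r fixture}
fx <- potentilla_fixture()
pairs <- find_conflicting_pairs(fx$nuclear, fx$chloroplast, 0.95, 0.95)
events <- flag_events(cluster_events(pairs, fx$nuclear, fx$chloroplast),
                      fx$ploidy)
events
summary(events)
```

Five incongruence events are found, and exactly three involve
polyploid taxa (the Anserina-internal switch, the
Reptans/Fragarioides switch and the *P. norvegica* move); the
*P. articulata* and *P. dickinsii* events implicate only diploid or
unknown-ploidy taxa. The same five events are found at a stricter
0.98/0.98 threshold, because every conflicting placement in the
fixture carries support ≥ 0.98.

```{r asr}
x <- fx$characters[, "style"]
x <- x[names(x) %in% fx$nuclear$tip.label]
tr <- resolve_polytomies(fx$nuclear)
f_er <- fit_mk(tr, x[tr$tip.label], "ER")
f_sym <- fit_mk(tr, x[tr$tip.label], "SYM")
anova(f_er, f_sym)
```

## Numerical choices and degenerate inputs

* Consensus inclusion is strictly `frequency > cutoff`, except that
  unanimous clades (frequency 1) are always retained — otherwise a
  cutoff of 1 would return a star tree even for identical input trees.
* Splits are canonicalised to the side containing the
  lexicographically smallest taxon, so a split and its complement are
  one object; when two nodes of one tree induce the same unrooted
  split (the two root children), the larger support is kept.
* Pruning sums branch lengths across suppressed unifurcations and
  keeps the support of the edge closest to the leaves (the label that
  describes the surviving clade's content).
* Rate MLEs at the search bounds (e.g. a constant character driving
  the rate to 1e-8) are returned as-is with convergence status; the
  LRT statistic is clamped at zero so finite-sample optimiser noise
  cannot produce negative statistics.
* Excluding every alignment column is allowed (zero-length alignment,
  with a message); fewer than 4 shared taxa between trees is an error
  since no non-trivial conflict is possible.
* Ties in event clustering (equal size and pairs reconciled) are
  broken by lexicographically smallest taxon: deterministic, at the
  cost that a genuinely symmetric two-taxon swap attributes the event
  to the alphabetically first mover.

## Known limitations

* Event clustering is greedy; a pathological nest of overlapping
  moves could in principle be explained more parsimoniously by a
  different removal order. On the simulated benchmark (five
  independent moves, 64 leaves) recovery is exact in ≥ 95% of seeded
  scenarios.
* The method cannot distinguish hybridization from incomplete lineage
  sorting or chloroplast capture; flags are candidates for targeted
  follow-up with low-copy nuclear markers.
* Concerted evolution of ribosomal repeats can erase the nuclear
  signal of a hybrid entirely, so absence of conflict is not evidence
  of absence of hybridization.
* NEXUS input is not parsed; convert to Newick first. Bayesian tree
  inference, alignment and recombination screening are out of scope.
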