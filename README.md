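# phyloconflict

Detecting cytonuclear discordance, flagging allopolyploidy candidates,
preparing concatenated matrices with simple indel coding, and
reconstructing ancestral states of discrete characters under Mk models.

## The problem

Allopolyploid speciation — interspecific hybridization followed by
genome doubling — is common in plants. Because the chloroplast genome
is maternally inherited while nuclear markers track both parents, an
allopolyploid tends to occupy *contradictory, well-supported positions*
in chloroplast versus nuclear gene trees. Screening a genus for such
contradictions, and asking which of them involve taxa with elevated
ploidal levels (≥ 3x), is the standard first pass in groups like
*Potentilla* where ploidy ranges from 2x to 13x. `phyloconflict`
implements this screen, plus the surrounding matrix-preparation and
character-evolution analyses, as a tested R package for systematists
working with Bayesian consensus trees and cytological ploidy tables.

## What it computes

* **Splits and consensus.** A clade with posterior probability *p* on a
  consensus tree is a split with support *p*. Two splits A1|B1 and
  A2|B2 of one taxon set **conflict** iff all four intersections
  A1∩A2, A1∩B2, B1∩A2, B1∩B2 are non-empty (no tree can display both).
  A conflict is *well-supported* when both splits have support ≥ 0.95
  (both thresholds adjustable). Majority-rule consensus trees are
  built from posterior samples with support = empirical clade
  frequency.
* **Incongruence events.** Conflicting split pairs are clustered by
  iterative rogue-clade removal (smallest clade whose deletion
  reconciles remaining pairs, ties by pairs reconciled then
  alphabetically), giving one event per underlying taxon movement,
  with the implicated taxa attached.
* **Allopolyploidy candidates.** Ploidy strings ("8x, 10x", "8x?",
  "(2x), 4x, (6x)", "aneuploids") are parsed; an event is flagged when
  any implicated taxon has a reported level ≥ 3x.
* **Simple indel coding.** Each distinct interior gap becomes one
  binary character: 1 = exactly that gap, 0 = no overlapping gap,
  ? = overlapping gap of different extent or missing data; terminal
  gaps are missing data. Plus end truncation, reference-coordinate
  exclusion (e.g. "positions 599–671 of the reference accession") and
  concatenation with per-block partition records.
* **Mk ancestral states.** Maximum-likelihood fits of the k-state Mk
  model with equal (ER), symmetric (SYM) or all-distinct (ARD) rates;
  likelihood-ratio tests between nested models (2ΔlogL ~ χ², df =
  parameter difference); per-node scaled marginal state likelihoods
  (each node's state probabilities, summing to 1).

## Worked example

The package ships a worked *Potentilla* data set: schematic nuclear
(ITS+ETS) and chloroplast (trnL/F + trnS/G) consensus topologies with
posterior supports, and the published ploidal levels and floral
characters for 72 taxa (see the vignette for what "schematic" means).

```r
library(phyloconflict)
fx <- potentilla_fixture()
pairs  <- find_conflicting_pairs(fx$nuclear, fx$chloroplast, 0.95, 0.95)
events <- flag_events(cluster_events(pairs, fx$nuclear, fx$chloroplast),
                      fx$ploidy)
summary(events)
#> 5 incongruence event(s), 3 flagged as allopolyploidy candidates
events
#> 5 incongruence event(s)
#> 1) <event> rogue: Potentilla_articulata | 1 conflicting pair(s) | involved: Potentilla_articulata, Potentilla_biflora, Potentilla_micrantha
#> 2) <event> rogue: Potentilla_dickinsii | 1 conflicting pair(s) | involved: Potentilla_dickinsii
#> 3) <event> rogue: Potentilla_microphylla | 1 conflicting pair(s) | involved: Potentilla_microphylla, Potentilla_peduncularis, Potentilla_stenophylla | ALLOPOLYPLOIDY CANDIDATE
#> 4) <event> rogue: Potentilla_norvegica | 1 conflicting pair(s) | involved: Potentilla_norvegica | ALLOPOLYPLOIDY CANDIDATE
#> 5) <event> rogue: Potentilla_fragarioides, Potentilla_stolonifera | 2 conflicting pair(s) | involved: Potentilla_dickinsii, Potentilla_erecta, Potentilla_fragarioides, Potentilla_indica, Potentilla_reptans, Potentilla_stolonifera | ALLOPOLYPLOIDY CANDIDATE
```

Reading the output: five contradictions between the two genomes
survive the 0.95 support threshold. Three involve polyploids — the
*P. microphylla*/*P. peduncularis*/*P. stenophylla* switch inside the
Anserina clade (2n up to 4x), octo- to decaploid *P. norvegica*
jumping between the Argentea clade (chloroplast) and the ivesioid
clade (nuclear), and the Reptans/Fragarioides clade switch (Reptans
contains 10–12x *P. indica*) — so those three are candidate
allopolyploidization events. The *P. articulata* and *P. dickinsii*
events involve only diploid or unknown-ploidy taxa, where lineage
sorting or chloroplast capture are likelier explanations.

Ancestral states of the style-shape character on the nuclear tree:

```r
x  <- fx$characters[, "style"]; x <- x[names(x) %in% fx$nuclear$tip.label]
tr <- resolve_polytomies(fx$nuclear)
anova(fit_mk(tr, x[tr$tip.label], "ER"), fit_mk(tr, x[tr$tip.label], "SYM"))
#> Likelihood-ratio test: ER vs SYM
#>   chi-square = 14.0190, df = 5, p = 0.01549
```

The symmetric-rates model is preferred; `predict()` on a fit returns
the per-node scaled likelihoods (pie-chart values), and `plot()` draws
them on the tree.

An end-to-end run with machine-readable reports:

```r
cfg <- pipeline_config(fx$nuclear, fx$chloroplast, ploidy = fx$ploidy,
                       characters = fx$characters, asr_character = "style",
                       out_dir = "out")
run_pipeline(cfg)   # writes out/report.json, out/events.tsv, out/summary.txt
```

A thin command-line wrapper with the same stages lives in
`exec/phyloconflict` (subcommands: `prep`, `consensus`, `conflicts`,
`asr`, `simulate`, `fixture`, `run`).

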