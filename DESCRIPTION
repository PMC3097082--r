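Package: phyloconflict
Title: Cytonuclear Discordance Detection, Allopolyploidy Candidate
    Flagging, Indel Coding and Mk Ancestral State Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing nuclear and chloroplast gene trees in
    polyploid plant groups. Reads and writes Newick trees with
    posterior-probability node supports, computes majority-rule consensus
    trees from posterior samples, detects well-supported topological
    conflicts between two trees and clusters them into discrete
    incongruence events, and flags events involving polyploid taxa as
    allopolyploidy candidates using parsed ploidal-level tables. Also
    prepares concatenated character matrices with simple indel coding,
    and fits equal-rates, symmetric and all-rates-different Mk models of
    discrete character evolution with likelihood-ratio model selection
    and per-node scaled marginal ancestral-state likelihoods. Includes
    seeded simulators for gene-tree pairs with planted rogue taxa, Mk
    characters and gapped alignments, plus a worked Potentilla example
    data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
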