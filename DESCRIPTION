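Package: paralogon
Title: Paralogon Detection and Duplication-Scenario Analysis for Gene
    Family Expansion by Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether a gene family expanded through the two
    early vertebrate whole-genome duplications (2R) plus local (tandem)
    duplication, modelled on the comparative analysis of the opioid
    prepropeptide genes (PENK, PDYN, PNOC, POMC). Includes a genome
    evolution simulator with a replayable event log (whole-genome and
    tandem duplication, gene loss, translocation, sequence divergence),
    neuropeptide precursor motif annotation with dibasic-cleavage mature
    peptide prediction, self-contained progressive multiple alignment with
    affine gap costs, neighbor-joining tree building with bootstrap
    supports, outgroup rooting, species-overlap duplication annotation and
    relative dating, conserved-synteny paralogon tables with full-quartet
    summaries, and exhaustive parsimony ranking of duplication-event
    orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
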