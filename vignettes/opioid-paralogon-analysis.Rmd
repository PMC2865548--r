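---
title: "Detecting 2R paralogons and dating a tandem duplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 2R paralogons and dating a tandem duplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The question and the model

The four vertebrate opioid prepropeptide genes — preproenkephalin (*PENK*),
preprodynorphin (*PDYN*), prepronociceptin (*PNOC*) and
proopiomelanocortin (*POMC*) — sit in chromosomal regions that share many
neighboring gene families across four chromosomes. That pattern (a
*paralogon*) is the classic signature of the two early-vertebrate
whole-genome duplications (2R): one ancestral chromosome block was
quadrupled, and each resident gene family independently kept or lost its
four copies. Because only three of the four chromosomes carry an opioid
peptide gene while two of the genes (*PNOC*, *POMC*) sit adjacently on one
chromosome, the repertoire is best explained by 2R plus one local (tandem)
duplication — and the central analytical question becomes *when* that local
duplication happened relative to the two genome doublings.

`paralogon` implements that comparative analysis as four cooperating
layers:

1. **Annotation** identifies the family members by their diagnostic
   peptide motifs (the opioid core anchor Y/FGGF, the melanocortin HFRW).
2. **Alignment + phylogenetics** reconstructs the family tree
   (neighbor joining with bootstrap), annotates duplication nodes by the
   species-overlap rule, and dates them relative to speciation splits.
3. **Synteny** selects neighboring families with members on at least three
   of the candidate chromosomes and counts complete quartets.
4. **Scenario parsimony** enumerates the three possible orderings of the
   local duplication relative to the WGDs and ranks them by the minimum
   number of gene losses needed to explain the observed layout, under
   relative-dating feasibility constraints.

Genome-wide gene lists from the original archival database release cannot
be reproduced offline, so the package carries a **genome-evolution
simulator** that generates inputs with exactly the evolutionary structure
the analysis assumes, plus a truth log, so that every stage is tested
against planted ground truth rather than against irreproducible downloads.

## The simulator and what it does (not) emulate

`make_ancestral_genome()` lays out single-copy families at regular spacing;
`apply_wgd()` copies every chromosome wholesale under a label suffix;
`apply_local_duplication()` inserts an adjacent same-family copy;
`apply_losses()` deletes each gene independently with probability
`1 - retention`; `apply_translocation()` moves a coordinate block between
chromosomes; `evolve_sequences()` applies residue substitutions.
`simulate_history()` walks a configured species tree applying branch events
in order, and every operation appends to a lineage log which
`replay_log()` can re-execute to byte-identical genomes — the simulator's
core invariant, property-tested over random configurations.

Deliberate simplifications, and what they imply for the tests:

* **Substitution model.** Events per sequence are Poisson with mean
  `branch_length × length`; positions are uniform over unprotected sites
  and the replacement residue is uniform over the 19 alternatives — a
  single fixed symmetric exchangeability table, no rate heterogeneity.
  This is intentionally simpler than the JTT+Γ models used for inference
  on real data; it suffices for recovery tests because the tree-building
  layer only needs distances to grow monotonically with branch length.
  Passing recovery tests therefore demonstrates correctness of the
  *algorithms*, not robustness to realistic among-site rate variation.
* **No indels, no intron evolution, no codon level.** Simulated homologs
  stay equal-length; alignment correctness is instead exercised by
  planting explicit insertions in tests.
* **WGD without fractionation mixing.** A duplication copies chromosomes
  wholesale; all loss happens through the explicit loss operation. Real
  post-WGD genomes interleave these processes.
* **Protected cassettes.** Motif cassettes (e.g. seven YGGFM copies) can
  be excluded from substitution so motif-recovery tests have exact planted
  truth. Real motifs degrade; the annotation layer's degeneracy
  classification is tested separately on constructed alignments.

The free parameters nowhere fixed by the source analysis — retention
probability, branch lengths, family counts — are set once in
`example_pipeline_config()` to values a simulation study would call
moderate: 60 families (3 ancestral chromosomes × 20), retention 0.75 on
the shared stem (within the 0.3–0.8 band the recovery tests sweep), branch
lengths 0.03–0.15 substitutions/site, 120-residue proteins. The focal
cassette family is exempted from stochastic loss in the bundled fixture:
the analysis conditions on the family's survival, as any real study of an
extant family does.

## Numerical and algorithmic choices

* **Coordinates** are 0-based half-open throughout; strand is recorded but
  ignored (the analysis never uses it). Alignment columns are 1-based, as
  R matrix indices.
* **Pairwise alignment** is global affine-gap (Gotoh, three states), with
  a gap of length L costing `gap_open + L × gap_extend`; defaults 10.0 and
  0.2 follow the Clustal parameterisation used for the original
  alignments. Terminal gaps are charged (switchable). Ties during
  traceback prefer substitution over a gap in the first profile over a gap
  in the second, making output deterministic. The substitution table is
  any matrix shipped with Biostrings; BLOSUM62 is the default — the table
  is configuration, not code, and no result in this package depends on the
  specific choice.
* **Profile merging** scores column pairs by average-of-pairs (gap/residue
  pairs contribute zero) and only ever inserts full gap columns into a
  profile, so within-profile columns are preserved as units.
* **Distances** use pairwise deletion (mutually ungapped columns) by
  default; complete deletion is a flag. The Kimura protein correction
  `d = -ln(1 - p - 0.2p²)` is singular at `p = (√1.8 - 1)/0.4 ≈ 0.854102`;
  a saturated pair is an error by default, but bootstrap resampling uses a
  cap at the `p = 0.85` value so occasional saturated replicates do not
  abort a run — a reporting choice, flagged in the API, not silent.
* **Neighbor joining** breaks Q-criterion ties by the lowest taxon-index
  pair and clamps negative branch estimates to zero without
  redistribution. For additive matrices the reconstruction is exact (path
  lengths within 1e-9), which the suite verifies against independently
  generated random additive trees.
* **Bootstrap supports** are mapped onto the full-alignment reference NJ
  tree (the convention of the original presentation), not onto a
  majority-rule consensus.
* **Outgroup rooting** requires the outgroup to be a genuine bipartition
  side and splits the divided edge at its midpoint; an invalid outgroup is
  an error, never a silent fallback.
* **Relative dating** labels a duplication `before_split` only when both
  child clades contain species from both sides of the split,
  `after_split` only when the whole clade is confined to one side, and
  `unresolved` otherwise; species absent from the split (outgroups) are
  ignored. Under gene loss the design degrades `before_split` to
  `unresolved`, never to `after_split` — the asymmetry the downstream
  scenario constraints rely on.
* **Synteny membership** is decided by gene start position only, in
  half-open windows, so boundary genes are never double-counted; both
  ±flank windows around anchors and whole-chromosome lists are first-class
  region kinds. Family assignment is input data — this module never
  clusters sequences.
* **Scenario search** is exhaustive: 3 orderings × at most 4! assignments
  of expected to observed chromosome classes. Chromosome classes are
  unlabeled because the analysis does not pin which post-2R chromosome
  lost its copy. One consequence worth stating: for any feasible
  assignment the loss count equals expected-minus-observed totals, so
  deleting an observed gene always raises the minimum by exactly one —
  the suite tests exactly that.

## Design decisions that were genuinely open

* **Degeneracy threshold.** The source analysis distinguishes intact,
  "degenerate" and "relic" core sequences without quantifying them. Here a
  core site with 1–2 mismatches (gaps counting as mismatches) is
  `degenerate` and beyond that `absent`; the threshold `max_degenerate` is
  an explicit argument, and the classification is alignment-contextual — a
  site is a core position because homologs are intact there.
* **Cleavage rule.** Mature-peptide prediction uses dibasic sites only
  (KK/KR/RK/RR), the simplest prohormone-convertase rule; monobasic
  cleavage is real but unspecifiable without per-peptide evidence.
* **Conserved special positions** (e.g. the six nocistatin residues) are
  supplied as configuration (`conservation_count()`), never hard-coded,
  because the positions are not enumerated in any machine-readable source.
* **Ortholog grouping in the bundled pipeline** uses the simulator's
  lineage-deterministic gene ids. With real data the groups would come
  from the gene trees; the table-building code is agnostic to the source.
* **The run log is excluded from the manifest** because it records
  wall-clock timings; the determinism contract (identical manifests for
  identical seeds) covers every result file.

## Problem sizes

The bundled fixture runs 60 families across 4 species with 100 bootstrap
replicates in roughly ten seconds; the full verification sweep uses 100
random additive matrices for NJ exactness, 500 random pairs against the
exhaustive alignment enumerator, 20 simulated 2R histories for paralogon
recovery, and 200 + 50 simulated gene trees for relative dating — sizes
chosen so the complete suite runs in a couple of minutes while still
estimating each rate from a three-digit sample.

## Known limitations

* No maximum-likelihood or Bayesian tree inference, no Γ rate
  heterogeneity, no model selection: neighbor joining is the in-package
  tree builder, and the quartet-puzzling cross-checks of the original
  analysis are out of scope.
* The simulator's sequence model cannot produce alignment-difficult data
  (long indels, domain shuffling); conclusions about the aligner on such
  data require external benchmarks.
* Genome-wide counts tied to a retired database release (how many real
  neighboring families, how many real full quartets) are not reproducible
  here and are not claimed; the package verifies the *machinery* on
  synthetic data with known truth.
* The scenario module counts peptide-gene losses only; receptor genes are
  not modeled as constraints beyond the user-supplied relative-dating
  constraint.
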