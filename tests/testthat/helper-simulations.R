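# Simulation harnesses shared between module tests and the acceptance suite.

# One duplication predating an A/B speciation, with an outgroup diverging
# before the duplication; optionally one post-speciation gene loss in B.
# Returns the annotated rooted NJ gene tree and its relative dating.
simulate_dating_case <- function(seed, with_loss = FALSE,
                                 sequence_length = 200L) {
  loss_events <- if (with_loss)
    list(list(type = "loss_genes", genes = "f01.1-D")) else list()
  tree <- tree_node("root", length = 0.05, children = list(
    tree_node("outgroup", length = 0.30),
    tree_node("ingroup", length = 0.20,
              events = list(list(type = "wgd", label = "D")),
              children = list(
                tree_node("speciesA", length = 0.10),
                tree_node("speciesB", length = 0.10,
                          events = loss_events)))))
  cfg <- simulation_config(seed, 1L, 1L, tree,
                           sequence_length = sequence_length)
  sim <- simulate_history(cfg)
  seqs <- character(0)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    s <- g$sequences
    names(s) <- make_leaf_labels(sp, g$genes$gene_id)
    seqs <- c(seqs, s)
  }
  aln <- protein_alignment(seqs)
  D <- protein_distance_matrix(aln, correction = "kimura",
                               saturation = "cap")
  tr <- neighbor_joining(D)
  og <- grep("^outgroup\\|", tr$tip.label, value = TRUE)
  rooted <- root_with_outgroup(tr, og)
  ann <- annotate_duplications(rooted)
  dating <- relative_dating(ann, split = list("speciesA", "speciesB"))
  list(tree = ann, dating = dating)
}

# A 2R history (no translocations) over 60 families in one species, with
# stochastic loss at the given retention probability. Returns the genome,
# the candidate (chr1-descended) chromosomes, and the truth-log-derived set
# of chr1 families with >= 3 retained post-2R copies.
simulate_paralogon_case <- function(seed, retention) {
  tree <- tree_node("sp", length = 0, events = list(
    list(type = "wgd", label = "R1"),
    list(type = "wgd", label = "R2"),
    list(type = "loss", retention = retention)))
  cfg <- simulation_config(seed, 3L, 20L, tree, sequence_length = 40L)
  sim <- simulate_history(cfg)
  g <- sim$genomes$sp
  candidates <- c("chr1", "chr1-R1", "chr1-R2", "chr1-R1-R2")
  lost <- unlist(lapply(g$log, function(e)
    if (e$kind == "LOSS") e$genes else NULL))
  chr1_fams <- sprintf("f%02d", 1:20)
  truth <- vapply(chr1_fams, function(f) {
    copies <- paste0(f, ".1", c("", "-R1", "-R2", "-R1-R2"))
    sum(!copies %in% lost) >= 3L
  }, logical(1))
  list(genome = g, candidates = candidates,
       truth_selected = sort(chr1_fams[truth]))
}

run_family_selection <- function(case, min_chromosomes = 3L) {
  regions <- lapply(case$candidates, function(ch)
    genomic_region(ch, whole_chromosome = TRUE))
  pres <- family_presence(case$genome$genes, regions,
                          chromosomes = names(case$genome$chromosome_lengths))
  list(presence = pres,
       selected = select_families(pres, min_chromosomes))
}
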