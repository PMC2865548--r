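## Pipeline orchestration: simulate -> annotate -> align -> tree -> synteny
## -> scenarios, as a configured, logged, deterministic run with
## standard-format outputs and a checksum manifest.

#' Pipeline run configuration
#'
#' Defaults follow the analysis' printed parameters: 1000 bootstrap
#' replicates, 10 Mb region flank, families selected on at least 3 of the
#' candidate chromosomes.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param outdir output directory (created if missing).
#' @param simulation a [simulation_config()] providing the inputs, or `NULL`
#'   when `gene_tables`/`sequences` paths are supplied.
#' @param gene_tables optional named character vector of per-species gene
#'   table TSV paths (alternative to simulation).
#' @param sequences optional FASTA path with the focal-family protein
#'   sequences (alternative to simulation).
#' @param bootstrap bootstrap replicate count (0 = no supports).
#' @param flank region flank in bp.
#' @param min_chromosomes family-selection threshold.
#' @param scoring a [scoring_scheme()].
#' @param reference_species reference species for synteny tables; default
#'   the first simulated/loaded species.
#' @param ancestral_chromosome ancestral chromosome whose post-WGD
#'   descendants form the candidate paralogon set.
#' @param observed an [observed_repertoire()] for scenario ranking.
#' @param constraints list of [scenario_constraint()]s.
#' @param max_mismatch motif-scan mismatch budget.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed, outdir, simulation = NULL,
                            gene_tables = NULL, sequences = NULL,
                            bootstrap = 1000L, flank = 1e7,
                            min_chromosomes = 3L,
                            scoring = scoring_scheme(),
                            reference_species = NULL,
                            ancestral_chromosome = "chr1",
                            observed = opioid_observed_repertoire(),
                            constraints = list(),
                            max_mismatch = 0L) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulation = simulation, gene_tables = gene_tables,
                 sequences = sequences, bootstrap = as.integer(bootstrap),
                 flank = flank, min_chromosomes = as.integer(min_chromosomes),
                 scoring = scoring, reference_species = reference_species,
                 ancestral_chromosome = ancestral_chromosome,
                 observed = observed, constraints = constraints,
                 max_mismatch = as.integer(max_mismatch)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields mirror [pipeline_config()]; a nested `simulation` map (with
#' `tree` given as nested `name`/`length`/`events`/`children` maps) builds a
#' [simulation_config()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    cass <- if (!is.null(s$cassette))
      cassette_spec(s$cassette$pattern, s$cassette$copies %||% 1L,
                    s$cassette$families,
                    s$cassette$protected %||% TRUE)
    as_node <- function(nd) {
      tree_node(nd$name, nd$length %||% 0, nd$events %||% list(),
                lapply(nd$children %||% list(), as_node))
    }
    sim <- simulation_config(s$seed %||% y$seed, s$n_chromosomes,
                             s$families_per_chromosome, as_node(s$tree),
                             cassette = cass,
                             sequence_length = s$sequence_length %||% 120L)
  }
  sc <- scoring_scheme(y$scoring$matrix %||% "BLOSUM62",
                       y$scoring$gap_open %||% 10,
                       y$scoring$gap_extend %||% 0.2)
  obs <- if (!is.null(y$observed))
    observed_repertoire(as.integer(y$observed$counts),
                        as.logical(y$observed$adjacent))
  else opioid_observed_repertoire()
  cons <- lapply(y$constraints %||% list(), function(cn)
    scenario_constraint(cn$before, cn$after, cn$note %||% ""))
  pipeline_config(seed = y$seed, outdir = y$outdir, simulation = sim,
                  gene_tables = unlist(y$gene_tables),
                  sequences = y$sequences,
                  bootstrap = y$bootstrap %||% 1000L,
                  flank = y$flank %||% 1e7,
                  min_chromosomes = y$min_chromosomes %||% 3L,
                  scoring = sc,
                  reference_species = y$reference_species,
                  ancestral_chromosome = y$ancestral_chromosome %||% "chr1",
                  observed = obs, constraints = cons,
                  max_mismatch = y$max_mismatch %||% 0L)
}

#' Bundled synthetic fixture configuration
#'
#' A two-round WGD history over 60 gene families (3 ancestral chromosomes x
#' 20 families) in four species (one teleost carrying an extra 3R
#' duplication), with a tandem duplication of the focal motif-cassette
#' family between the two WGDs and stochastic gene loss, mirroring the
#' evolutionary structure the opioid analysis assumes.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @param bootstrap bootstrap replicates for the focal tree (kept at 100 so
#'   the full fixture runs in seconds).
#' @return a [pipeline_config()].
#' @export
example_pipeline_config <- function(seed = 42L, outdir = tempfile("pipeline"),
                                    bootstrap = 100L) {
  focal <- "f01"
  tree <- tree_node("vertebrate_root", length = 0.05,
    events = list(
      list(type = "wgd", label = "R1"),
      list(type = "local_dup", family = focal),
      list(type = "wgd", label = "R2"),
      list(type = "loss", retention = 0.75, exclude_families = focal)),
    children = list(
      tree_node("fish", length = 0.15,
                events = list(list(type = "wgd", label = "3R"))),
      tree_node("tetrapod", length = 0.05, children = list(
        tree_node("frog", length = 0.10),
        tree_node("amniote", length = 0.03, children = list(
          tree_node("chicken", length = 0.08),
          tree_node("human", length = 0.08)))))))
  sim <- simulation_config(seed = seed, n_chromosomes = 3L,
                           families_per_chromosome = 20L, tree = tree,
                           cassette = cassette_spec("YGGFM", copies = 7L,
                                                    families = focal),
                           sequence_length = 120L)
  pipeline_config(seed = seed, outdir = outdir, simulation = sim,
                  bootstrap = bootstrap, reference_species = "chicken",
                  constraints = list(scenario_constraint(
                    "LOCAL", "WGD2",
                    note = "cyclostome duplicate melanocortin precursors predate the second genome doubling")))
}

#' Validate pipeline inputs
#'
#' Collects every problem (missing files, schema violations with row
#' numbers, bad alphabets, inconsistent regions) rather than failing at the
#' first.
#'
#' @param config a [pipeline_config()].
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validate_inputs <- function(config) {
  errors <- character(0)
  if (!inherits(config, "pipeline_config"))
    return(list(ok = FALSE, errors = "not a pipeline_config"))
  if (is.null(config$simulation)) {
    if (is.null(config$gene_tables))
      errors <- c(errors, "neither simulation nor gene_tables supplied")
    for (p in config$gene_tables) {
      if (!file.exists(p)) {
        errors <- c(errors, paste0("missing gene-table file: ", p))
        next
      }
      df <- tryCatch(utils::read.delim(p, colClasses = "character"),
                     error = function(e) NULL)
      if (is.null(df)) {
        errors <- c(errors, paste0("unreadable gene table: ", p)); next
      }
      miss <- setdiff(GENE_TABLE_COLUMNS, names(df))
      if (length(miss) > 0L) {
        errors <- c(errors, paste0(p, ": missing columns ",
                                   paste(miss, collapse = ",")))
        next
      }
      bad <- which(as.numeric(df$start) >= as.numeric(df$end))
      if (length(bad) > 0L)
        errors <- c(errors, paste0(p, ": start >= end at row ",
                                   paste(bad, collapse = ",")))
    }
    if (!is.null(config$sequences)) {
      if (!file.exists(config$sequences)) {
        errors <- c(errors, paste0("missing FASTA: ", config$sequences))
      } else {
        ok <- tryCatch({ read_fasta(config$sequences); TRUE },
                       error = function(e) conditionMessage(e))
        if (!isTRUE(ok))
          errors <- c(errors, paste0(config$sequences, ": ", ok))
      }
    }
  } else if (!inherits(config$simulation, "simulation_config")) {
    errors <- c(errors, "simulation is not a simulation_config")
  }
  if (config$bootstrap < 0L) errors <- c(errors, "negative bootstrap count")
  if (config$flank < 0) errors <- c(errors, "negative flank")
  if (config$min_chromosomes < 1L)
    errors <- c(errors, "min_chromosomes must be >= 1")
  list(ok = length(errors) == 0L, errors = errors)
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(paste0("[", format(Sys.time(), "%H:%M:%OS2"), "] ", msg), con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (`simulate`, `annotate`, `align`, `tree`,
#' `synteny`, `scenarios`), writing per-stage outputs as they complete so a
#' failed run preserves its upstream results; the failing stage is named in
#' the error. A `manifest.tsv` (file, md5) covers every result file; the
#' run log is excluded from the manifest because it records wall-clock
#' timings. Fully deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all, in order).
#' @return invisibly, a list with the outputs (`genomes`, `alignment`,
#'   `tree`, `selected_families`, `quartets`, `ranking`, `manifest`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "annotate", "align", "tree",
                                    "synteny", "scenarios")) {
  val <- validate_inputs(config)
  if (!val$ok) stop("invalid pipeline inputs: ",
                    paste(val$errors, collapse = "; "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logcon))
  marker <- file.path(config$outdir, "stages.done")
  res <- list()
  next_seed <- seed_stream(config$seed)
  boot_seed <- next_seed()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    .log_line(logcon, "stage ", name, " start")
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .log_line(logcon, "stage ", name, " done in ",
              format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
              "s")
    cat(name, "\n", file = marker, append = TRUE)
  }

  out <- function(...) file.path(config$outdir, ...)

  run_stage("simulate", function() {
    if (!is.null(config$simulation)) {
      sim <- simulate_history(config$simulation)
      res$genomes <<- sim$genomes
      res$ancestor <<- sim$ancestor
      for (sp in names(sim$genomes)) {
        write_gene_table(sim$genomes[[sp]]$genes,
                         out(paste0("genes_", sp, ".tsv")))
        write_truth_log(sim$genomes[[sp]]$log,
                        out(paste0("truthlog_", sp, ".tsv")))
      }
      cass <- config$simulation$cassette
      focal_fams <- if (!is.null(cass))
        (cass$families %||% "f01") else unique(sim$ancestor$genes$family_id)[1]
      seqs <- character(0)
      for (sp in names(sim$genomes)) {
        g <- sim$genomes[[sp]]
        sel <- g$genes[g$genes$family_id %in% focal_fams, , drop = FALSE]
        s <- g$sequences[sel$gene_id]
        names(s) <- make_leaf_labels(sp, sel$gene_id, sel$chromosome)
        seqs <- c(seqs, s)
      }
      res$focal_sequences <<- seqs
      write_fasta(seqs, out("sequences_focal.fasta"))
    } else {
      res$genomes <<- NULL
      tabs <- lapply(config$gene_tables, read_gene_table)
      names(tabs) <- names(config$gene_tables)
      res$gene_tables <<- tabs
      res$focal_sequences <<- read_fasta(config$sequences)
    }
  })

  run_stage("annotate", function() {
    seqs <- res$focal_sequences
    hits <- scan_motif_set(seqs, opioid_core_pattern(), config$max_mismatch)
    write_motif_report(hits, out("motif_report.tsv"))
    peps <- do.call(rbind, lapply(names(seqs), function(nm) {
      h <- hits[hits$sequence_id == nm, , drop = FALSE]
      p <- predict_mature_peptides(seqs[[nm]], h)
      if (nrow(p) > 0L) cbind(sequence_id = nm, p) else NULL
    }))
    if (is.null(peps))
      peps <- data.frame(sequence_id = character(), start = integer(),
                         end = integer(), peptide = character())
    write_peptide_intervals(peps, out("mature_peptides.tsv"))
    res$motif_hits <<- hits
  })

  run_stage("align", function() {
    aln <- progressive_align(res$focal_sequences, scoring = config$scoring)
    res$alignment <<- aln
    write_alignment(aln, out("alignment_focal.fasta"))
  })

  run_stage("tree", function() {
    aln <- res$alignment %||% read_alignment(out("alignment_focal.fasta"))
    tre <- bootstrap_support(aln, n_replicates = config$bootstrap,
                             seed = boot_seed)
    res$tree <<- tre
    write_tree(tre, out("tree_focal.nwk"))
  })

  run_stage("synteny", function() {
    tabs <- if (!is.null(res$genomes))
      lapply(res$genomes, function(g) g$genes) else res$gene_tables
    ref_sp <- config$reference_species %||% names(tabs)[1]
    ref_tab <- tabs[[ref_sp]]
    anc <- config$ancestral_chromosome
    cand <- sort(unique(ref_tab$chromosome[
      ref_tab$chromosome == anc |
      startsWith(ref_tab$chromosome, paste0(anc, "-"))]))
    regions <- lapply(cand, function(ch)
      genomic_region(ch, whole_chromosome = TRUE))
    pres <- family_presence(ref_tab, regions)
    sel <- select_families(pres, config$min_chromosomes)
    qt <- quartet_completeness(sel, pres)
    res$presence <<- pres
    res$selected_families <<- sel
    res$quartets <<- qt
    utils::write.table(
      data.frame(family_id = rownames(pres$counts), pres$counts,
                 check.names = FALSE),
      out("synteny_presence.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(sel, out("selected_families.tsv"))
    utils::write.table(qt, out("quartet_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## ortholog groups: simulator gene ids are lineage-deterministic, so
    ## identical ids across species are orthologs
    all_ids <- unique(unlist(lapply(tabs, function(t) t$gene_id)))
    groups <- lapply(all_ids, function(id) id)
    ptabs <- build_synteny_table(tabs, groups, ref_sp)
    for (sp in names(ptabs))
      write_paralogon_table(ptabs[[sp]],
                            out(paste0("paralogon_", sp, ".tsv")))
    res$paralogon_tables <<- ptabs
  })

  run_stage("scenarios", function() {
    rk <- rank_scenarios(all_event_orders(), config$observed,
                         config$constraints)
    res$ranking <<- rk
    write_scenario_ranking(rk, out("scenario_ranking.tsv"))
  })

  ## manifest over every result file (run log and markers excluded: they
  ## record wall-clock timings, not results)
  files <- sort(setdiff(list.files(config$outdir),
                        c("run.log", "stages.done", "manifest.tsv")))
  sums <- tools::md5sum(file.path(config$outdir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  .log_line(logcon, "pipeline complete: ", nrow(manifest), " files")
  invisible(res)
}
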