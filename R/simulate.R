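## Genome-evolution simulator: two rounds of whole-genome duplication (2R),
## optional teleost-branch 3R, tandem duplication, stochastic gene loss,
## translocation and protein sequence divergence, with a replayable event log.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic stream of derived sub-seeds from one master seed. Each call
## to the returned function yields the next sub-seed; the caller's RNG state
## is never disturbed.
seed_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- with_seed(seed, .Random.seed)
  function() {
    old <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    s <- sample.int(2147483646L, 1L)
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
}

#' Motif cassette specification
#'
#' Describes a short peptide motif planted (in a fixed number of copies) in
#' the root sequence of selected gene families, optionally protected from
#' substitution so that motif-recovery tests have exact ground truth.
#'
#' @param pattern literal residue string (e.g. `"YGGFM"`).
#' @param copies number of copies to plant.
#' @param families family ids carrying the cassette; `NULL` means the first
#'   family of the genome.
#' @param protected if `TRUE`, cassette positions are excluded from
#'   substitution by [evolve_sequences()].
#' @return a list of class `"cassette_spec"`.
#' @export
cassette_spec <- function(pattern, copies = 1L, families = NULL,
                          protected = TRUE) {
  stopifnot(is.character(pattern), nchar(pattern) >= 2L, copies >= 1L)
  structure(list(pattern = pattern, copies = as.integer(copies),
                 families = families, protected = isTRUE(protected)),
            class = "cassette_spec")
}

## Plant `copies` exact copies of `pattern` into a random sequence of length
## >= len, then scrub accidental extra occurrences so the count is exact.
.plant_cassette <- function(len, pattern, copies) {
  pl <- nchar(pattern)
  block <- pl + 6L                      # motif + spacer room
  need <- 8L + copies * block + 8L
  len <- max(len, need)
  s <- sample(AA20, len, replace = TRUE)
  starts <- 8L + (seq_len(copies) - 1L) * block + 1L   # 1-based
  pat <- strsplit(pattern, "")[[1]]
  planted <- integer(0)
  for (st in starts) {
    s[st:(st + pl - 1L)] <- pat
    planted <- c(planted, st:(st + pl - 1L))
  }
  seqstr <- paste(s, collapse = "")
  for (iter in 1:100) {
    occ <- gregexpr(pattern, seqstr, fixed = TRUE)[[1]]
    occ <- occ[occ > 0]
    extra <- setdiff(occ, starts)
    if (length(extra) == 0L) break
    for (e in extra) {
      pos <- setdiff(e:(e + pl - 1L), planted)
      if (length(pos) == 0L)
        stop("cannot plant exact cassette count: pattern self-overlaps")
      p <- pos[1L]
      cur <- substr(seqstr, p, p)
      repl <- setdiff(AA20, c(cur, pat))[1L]
      substr(seqstr, p, p) <- repl
    }
  }
  list(sequence = seqstr, protected = sort(planted))
}

#' Build an ancestral (pre-duplication) genome
#'
#' Lays out `families_per_chromosome` single-copy gene families on each of
#' `n_chromosomes` chromosomes at regular spacing, draws a random root
#' protein sequence per family, and plants motif cassettes where requested.
#' Deterministic given `seed`.
#'
#' @param n_chromosomes,families_per_chromosome positive integers.
#' @param cassette optional [cassette_spec()].
#' @param seed integer random seed.
#' @param sequence_length root protein length in residues (cassette families
#'   may be longer if the copies do not fit).
#' @param gene_width,gene_spacing gene extent and inter-gene spacing in bp.
#' @return a [genome()] for species `"ancestor"`.
#' @export
make_ancestral_genome <- function(n_chromosomes, families_per_chromosome,
                                  cassette = NULL, seed = 1L,
                                  sequence_length = 120L,
                                  gene_width = 2000, gene_spacing = 100000) {
  if (n_chromosomes < 1L || families_per_chromosome < 1L)
    stop("counts must be positive")
  with_seed(seed, {
    n_fam <- n_chromosomes * families_per_chromosome
    fam_ids <- sprintf("f%02d", seq_len(n_fam))
    cass_fams <- character(0)
    if (!is.null(cassette)) {
      cass_fams <- if (is.null(cassette$families)) fam_ids[1L]
                   else cassette$families
      if (!all(cass_fams %in% fam_ids))
        stop("cassette families not present in genome")
    }
    gid <- paste0(fam_ids, ".1")
    starts <- rep((seq_len(families_per_chromosome) - 1L) * gene_spacing,
                  times = n_chromosomes)
    genes <- data.frame(
      gene_id = gid, species = "ancestor",
      chromosome = rep(paste0("chr", seq_len(n_chromosomes)),
                       each = families_per_chromosome),
      start = starts, end = starts + gene_width, strand = "+",
      family_id = fam_ids, stringsAsFactors = FALSE)
    seqs <- character(length(gid)); names(seqs) <- gid
    prot <- list()
    for (k in seq_along(gid)) {
      if (fam_ids[k] %in% cass_fams) {
        pc <- .plant_cassette(sequence_length, cassette$pattern,
                              cassette$copies)
        seqs[gid[k]] <- pc$sequence
        if (cassette$protected) prot[[gid[k]]] <- pc$protected
      } else {
        seqs[gid[k]] <- paste(sample(AA20, sequence_length, replace = TRUE),
                              collapse = "")
      }
    }
    chrlen <- stats::setNames(
      rep(families_per_chromosome * gene_spacing + gene_spacing,
          n_chromosomes),
      paste0("chr", seq_len(n_chromosomes)))
    genome("ancestor", genes, chrlen, seqs,
           protected_sites = if (length(prot)) prot else NULL)
  })
}

#' Apply a whole-genome duplication
#'
#' Every chromosome is copied wholesale under a `-<label>` suffix; each gene
#' gains exactly one co-ortholog at homologous coordinates on the duplicated
#' chromosome. Gene and chromosome counts exactly double.
#'
#' @param g a [genome()].
#' @param label suffix identifying the duplication (e.g. `"R1"`, `"R2"`,
#'   `"3R"`).
#' @return the duplicated genome, with a `WGD` event appended to its log.
#' @export
apply_wgd <- function(g, label = "dup") {
  stopifnot(inherits(g, "genome"))
  if (n_genes(g) == 0L) stop("cannot duplicate an empty genome")
  dup <- g$genes
  dup$gene_id <- paste0(dup$gene_id, "-", label)
  dup$chromosome <- paste0(dup$chromosome, "-", label)
  new_seqs <- stats::setNames(g$sequences, paste0(names(g$sequences), "-", label))
  new_prot <- NULL
  if (!is.null(g$protected_sites)) {
    new_prot <- c(g$protected_sites,
                  stats::setNames(g$protected_sites,
                                  paste0(names(g$protected_sites), "-", label)))
  }
  chrlen <- c(g$chromosome_lengths,
              stats::setNames(g$chromosome_lengths,
                              paste0(names(g$chromosome_lengths), "-", label)))
  out <- genome(g$species, rbind(g$genes, dup), chrlen,
                c(g$sequences, new_seqs), new_prot, g$log)
  out$log <- c(out$log, list(truth_event("WGD", branch = g$species,
                                         genes = g$genes$gene_id,
                                         label = label)))
  out
}

#' Apply independent stochastic gene loss
#'
#' Each gene is independently retained with probability `retention_prob`;
#' deleted gene ids are recorded in the log so the draw can be replayed
#' exactly.
#'
#' @param g a [genome()].
#' @param retention_prob retention probability in `[0, 1]`.
#' @param seed integer seed for the retention draw.
#' @param exclude gene ids exempt from loss (always retained); used to
#'   condition a history on the survival of a focal family.
#' @return genome with the surviving genes.
#' @export
apply_losses <- function(g, retention_prob, seed = 1L, exclude = character()) {
  stopifnot(inherits(g, "genome"))
  if (retention_prob < 0 || retention_prob > 1)
    stop("retention_prob must be in [0, 1]")
  keep <- with_seed(seed, stats::runif(n_genes(g)) <= retention_prob)
  keep <- keep | g$genes$gene_id %in% exclude
  lost <- g$genes$gene_id[!keep]
  delete_genes(g, lost, retention = retention_prob, seed = seed)
}

#' Delete named genes
#'
#' Deterministic deletion used both for targeted losses in configured
#' histories and for replaying logged stochastic losses.
#'
#' @param g a [genome()].
#' @param gene_ids gene ids to remove (must all exist).
#' @param retention,seed optional provenance recorded in the `LOSS` event.
#' @return genome without the listed genes.
#' @export
delete_genes <- function(g, gene_ids, retention = NA_real_, seed = NA_integer_) {
  stopifnot(inherits(g, "genome"))
  if (!all(gene_ids %in% g$genes$gene_id)) stop("unknown gene id in deletion")
  keep <- !(g$genes$gene_id %in% gene_ids)
  out <- g
  out$genes <- g$genes[keep, , drop = FALSE]
  rownames(out$genes) <- NULL
  out$sequences <- g$sequences[out$genes$gene_id]
  if (!is.null(g$protected_sites))
    out$protected_sites <- g$protected_sites[
      intersect(names(g$protected_sites), out$genes$gene_id)]
  out$log <- c(out$log, list(truth_event("LOSS", branch = g$species,
                                         genes = gene_ids,
                                         retention = retention, seed = seed)))
  out
}

#' Apply a local (tandem) duplication
#'
#' Inserts a same-family copy of `gene_id` immediately downstream on the same
#' chromosome, within `offset` bp of the template; downstream genes are
#' shifted right to preserve non-overlap.
#'
#' @param g a [genome()].
#' @param gene_id template gene.
#' @param offset maximum separation (template end to copy start) in bp;
#'   default 50 kb.
#' @return genome with the tandem copy added.
#' @export
apply_local_duplication <- function(g, gene_id, offset = 50000) {
  stopifnot(inherits(g, "genome"))
  i <- match(gene_id, g$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  tmpl <- g$genes[i, ]
  gap <- min(offset, 1000)
  width <- tmpl$end - tmpl$start
  new_id <- paste0(gene_id, "-td")
  while (new_id %in% g$genes$gene_id) new_id <- paste0(new_id, "x")
  shift <- width + gap
  genes <- g$genes
  on_chr_after <- genes$chromosome == tmpl$chromosome & genes$start > tmpl$start
  genes$start[on_chr_after] <- genes$start[on_chr_after] + shift
  genes$end[on_chr_after] <- genes$end[on_chr_after] + shift
  new_row <- tmpl
  new_row$gene_id <- new_id
  new_row$start <- tmpl$end + gap
  new_row$end <- new_row$start + width
  genes <- rbind(genes, new_row)
  chrlen <- g$chromosome_lengths
  chrlen[tmpl$chromosome] <- chrlen[tmpl$chromosome] + shift
  seqs <- c(g$sequences, stats::setNames(g$sequences[gene_id], new_id))
  prot <- g$protected_sites
  if (!is.null(prot) && gene_id %in% names(prot))
    prot[[new_id]] <- prot[[gene_id]]
  out <- genome(g$species, genes, chrlen, seqs, prot, g$log)
  out$log <- c(out$log, list(truth_event("LOCAL_DUP", branch = g$species,
                                         genes = c(gene_id, new_id),
                                         offset = offset)))
  out
}

#' Apply a translocation
#'
#' Genes whose start falls in `[interval[1], interval[2])` on the source
#' chromosome are moved, in their original order, to the end of the target
#' chromosome. An interval containing no genes is a logged no-op.
#'
#' @param g a [genome()].
#' @param source_chromosome,target_chromosome chromosome names.
#' @param interval numeric length-2, 0-based half-open bp range on the source.
#' @return genome after the move.
#' @export
apply_translocation <- function(g, source_chromosome, interval,
                                target_chromosome) {
  stopifnot(inherits(g, "genome"), length(interval) == 2L)
  chrlen <- g$chromosome_lengths
  if (!source_chromosome %in% names(chrlen))
    stop("unknown chromosome: ", source_chromosome)
  if (!target_chromosome %in% names(chrlen))
    stop("unknown chromosome: ", target_chromosome)
  if (interval[1] < 0 || interval[2] > chrlen[source_chromosome])
    stop("interval outside source chromosome")
  genes <- g$genes
  mv <- genes$chromosome == source_chromosome &
        genes$start >= interval[1] & genes$start < interval[2]
  moved_ids <- genes$gene_id[mv][order(genes$start[mv])]
  gap <- 10000
  tgt <- genes$chromosome == target_chromosome
  cursor <- if (any(tgt)) max(genes$end[tgt]) + gap else 0
  for (id in moved_ids) {
    j <- match(id, genes$gene_id)
    w <- genes$end[j] - genes$start[j]
    genes$chromosome[j] <- target_chromosome
    genes$start[j] <- cursor
    genes$end[j] <- cursor + w
    cursor <- cursor + w + gap
  }
  chrlen[target_chromosome] <- max(chrlen[target_chromosome], cursor)
  out <- genome(g$species, genes, chrlen, g$sequences, g$protected_sites,
                g$log)
  out$log <- c(out$log, list(truth_event(
    "TRANSLOCATION", branch = g$species, genes = moved_ids,
    source = source_chromosome, target = target_chromosome,
    interval_start = interval[1], interval_end = interval[2])))
  out
}

#' Evolve protein sequences by random substitution
#'
#' The number of substitution events per sequence is Poisson with mean
#' `branch_length * length`; event positions are uniform over unprotected
#' sites and the replacement residue is drawn uniformly from the 19
#' alternatives (a single fixed symmetric exchangeability table).
#'
#' @param sequences named character vector of residue strings.
#' @param branch_length expected substitutions per site (>= 0).
#' @param seed integer seed.
#' @param protected_sites optional named list of 1-based positions to leave
#'   untouched.
#' @return the evolved sequences (same names, same lengths), with an
#'   `"n_events"` attribute giving the Poisson event count per sequence.
#' @export
evolve_sequences <- function(sequences, branch_length, seed = 1L,
                             protected_sites = NULL) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (branch_length == 0) {
    attr(sequences, "n_events") <- stats::setNames(
      rep(0L, length(sequences)), names(sequences))
    return(sequences)
  }
  with_seed(seed, {
    out <- sequences
    counts <- stats::setNames(integer(length(sequences)), names(sequences))
    for (nm in names(sequences)) {
      s <- strsplit(sequences[[nm]], "")[[1]]
      L <- length(s)
      pool <- seq_len(L)
      if (!is.null(protected_sites) && nm %in% names(protected_sites))
        pool <- setdiff(pool, protected_sites[[nm]])
      n_ev <- stats::rpois(1L, branch_length * L)
      counts[nm] <- n_ev
      if (n_ev > 0L && length(pool) > 0L) {
        pos <- pool[sample.int(length(pool), n_ev, replace = TRUE)]
        for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
      }
      out[[nm]] <- paste(s, collapse = "")
    }
    attr(out, "n_events") <- counts
    out
  })
}

## ---- configured histories --------------------------------------------------

#' Species-tree node for a simulation configuration
#'
#' @param name node (or leaf species) name.
#' @param length branch length above the node in substitutions/site.
#' @param events list of branch events, each a list with a `type` field:
#'   `wgd` (`label`), `loss` (`retention`), `loss_genes` (`genes`),
#'   `local_dup` (`gene` or `family`), `translocation` (`source`,
#'   `interval`, `target`).
#' @param children list of child nodes (empty for a leaf).
#' @return a nested list usable in [simulation_config()].
#' @export
tree_node <- function(name, length = 0, events = list(), children = list()) {
  stopifnot(is.character(name), length >= 0)
  list(name = name, length = length, events = events, children = children)
}

#' Simulation configuration
#'
#' @param seed master seed; all per-operation seeds are derived from it in a
#'   deterministic stream so runs are byte-reproducible.
#' @param n_chromosomes,families_per_chromosome ancestral genome shape.
#' @param tree root [tree_node()]; its branch carries the shared pre-species
#'   events (typically the two rounds of whole-genome duplication).
#' @param cassette optional [cassette_spec()].
#' @param sequence_length ancestral protein length.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed, n_chromosomes, families_per_chromosome,
                              tree, cassette = NULL, sequence_length = 120L) {
  stopifnot(is.numeric(seed), n_chromosomes >= 1,
            families_per_chromosome >= 1)
  .check_tree_node(tree)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 families_per_chromosome = families_per_chromosome,
                 tree = tree, cassette = cassette,
                 sequence_length = sequence_length),
            class = "simulation_config")
}

.check_tree_node <- function(node) {
  if (!is.list(node) || is.null(node$name))
    stop("malformed species-tree node (missing name)")
  if (!is.null(node$length) && node$length < 0)
    stop("negative branch length in species tree")
  for (e in node$events %||% list()) {
    if (is.null(e$type) ||
        !e$type %in% c("wgd", "loss", "loss_genes", "local_dup",
                       "translocation"))
      stop("unknown event type in species tree: ",
           if (is.null(e$type)) "<missing>" else e$type)
  }
  for (ch in node$children %||% list()) .check_tree_node(ch)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.apply_branch_event <- function(g, e, next_seed) {
  switch(e$type,
    wgd = apply_wgd(g, label = e$label %||% "dup"),
    loss = {
      excl <- if (!is.null(e$exclude_families))
        g$genes$gene_id[g$genes$family_id %in% e$exclude_families]
      else character()
      apply_losses(g, e$retention, seed = next_seed(), exclude = excl)
    },
    loss_genes = delete_genes(g, e$genes),
    local_dup = {
      gid <- e$gene
      if (is.null(gid)) {
        cand <- g$genes$gene_id[g$genes$family_id == e$family]
        if (length(cand) == 0L) stop("local_dup family absent: ", e$family)
        gid <- sort(cand)[1L]
      }
      apply_local_duplication(g, gid, offset = e$offset %||% 50000)
    },
    translocation = apply_translocation(g, e$source, e$interval, e$target),
    stop("unknown event type: ", e$type))
}

.rename_species <- function(g, species) {
  g$species <- species
  g$genes$species <- species
  g
}

#' Simulate a full evolutionary history
#'
#' Builds the ancestral genome, then walks the configured species tree
#' depth-first, applying each branch's events in order, evolving sequences by
#' the branch length, and emitting one genome per leaf species. Every genome
#' carries its complete lineage event log; [replay_log()] reproduces it
#' exactly from the ancestor.
#'
#' @param config a [simulation_config()].
#' @return list with elements `genomes` (named list of leaf [genome()]s),
#'   `ancestor` (the pre-event root genome) and `config`.
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  next_seed <- seed_stream(config$seed)
  anc <- make_ancestral_genome(config$n_chromosomes,
                               config$families_per_chromosome,
                               cassette = config$cassette,
                               seed = next_seed(),
                               sequence_length = config$sequence_length)
  genomes <- list()
  recurse <- function(node, g) {
    for (e in node$events %||% list())
      g <- .apply_branch_event(g, e, next_seed)
    if ((node$length %||% 0) > 0) {
      s <- next_seed()
      g$sequences <- evolve_sequences(g$sequences, node$length, seed = s,
                                      protected_sites = g$protected_sites)
      g$log <- c(g$log, list(truth_event(
        "SUBSTITUTION_EPOCH", branch = node$name,
        genes = names(g$sequences),
        branch_length = node$length, seed = s)))
    }
    kids <- node$children %||% list()
    if (length(kids) == 0L) {
      g <- .rename_species(g, node$name)
      g$log <- c(g$log, list(truth_event("SPECIATION", branch = node$name,
                                         species = node$name)))
      genomes[[node$name]] <<- g
    } else {
      for (ch in kids) recurse(ch, g)
    }
  }
  recurse(config$tree, anc)
  list(genomes = genomes, ancestor = anc, config = config)
}

#' Replay a lineage event log from the ancestral genome
#'
#' Re-applies each logged event (using the recorded parameters and derived
#' seeds) to the ancestral genome. The result must match the extant genome
#' exactly; this is the simulator's core correctness invariant.
#'
#' @param ancestor the ancestral [genome()].
#' @param log lineage log (an extant `genome$log`).
#' @return the replayed genome.
#' @export
replay_log <- function(ancestor, log) {
  g <- ancestor
  for (e in log) {
    g <- switch(e$kind,
      WGD = apply_wgd(g, label = e$params$label),
      LOSS = delete_genes(g, e$genes, retention = e$params$retention,
                          seed = e$params$seed),
      LOCAL_DUP = apply_local_duplication(g, e$genes[1L],
                                          offset = e$params$offset),
      TRANSLOCATION = apply_translocation(
        g, e$params$source,
        c(e$params$interval_start, e$params$interval_end),
        e$params$target),
      SUBSTITUTION_EPOCH = {
        g$sequences <- evolve_sequences(g$sequences, e$params$branch_length,
                                        seed = e$params$seed,
                                        protected_sites = g$protected_sites)
        g
      },
      SPECIATION = .rename_species(g, e$params$species),
      stop("unknown event kind in log: ", e$kind))
  }
  g
}
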