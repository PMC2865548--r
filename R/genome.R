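#' Gene table schema
#'
#' All genomic coordinates in this package are 0-based, half-open
#' `[start, end)`. Strand is recorded but ignored by every analysis.
#'
#' @name gene_table
#' @keywords internal
NULL

GENE_TABLE_COLUMNS <- c("gene_id", "species", "chromosome",
                        "start", "end", "strand", "family_id")

#' Construct and validate a gene table
#'
#' A gene table is a plain `data.frame` with columns `gene_id`, `species`,
#' `chromosome`, `start`, `end`, `strand` and `family_id`. Coordinates are
#' 0-based half-open base pairs.
#'
#' @param df a data.frame carrying at least the schema columns.
#' @return the validated data.frame (schema columns first, row names dropped).
#' @export
as_gene_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(GENE_TABLE_COLUMNS, names(df))
  if (length(missing) > 0L)
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[, c(GENE_TABLE_COLUMNS, setdiff(names(df), GENE_TABLE_COLUMNS)),
           drop = FALSE]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("start must be < end (0-based half-open)")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene table")
  if (any(!nzchar(df$family_id))) stop("empty family_id")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- NULL
  df
}

#' Construct a genome
#'
#' A genome bundles one species' gene table with chromosome lengths, the
#' protein sequence of each gene, optional protected (motif cassette) sites,
#' and the lineage event log that produced it (see [truth_log()]).
#'
#' @param species species name.
#' @param genes a gene table (see [as_gene_table()]).
#' @param chromosome_lengths named numeric vector, base pairs per chromosome.
#' @param sequences named character vector of protein sequences, one per gene.
#' @param protected_sites named list of integer vectors (1-based residue
#'   positions that [evolve_sequences()] must not touch), or `NULL`.
#' @param log lineage event list; each event is appended by the simulator
#'   operations.
#' @return an object of class `"genome"`.
#' @export
genome <- function(species, genes, chromosome_lengths, sequences,
                   protected_sites = NULL, log = list()) {
  genes <- as_gene_table(genes)
  if (!all(genes$chromosome %in% names(chromosome_lengths)))
    stop("every gene's chromosome must appear in chromosome_lengths")
  if (!setequal(names(sequences), genes$gene_id))
    stop("sequences must be named by gene_id, one per gene")
  .check_no_overlap(genes)
  structure(list(species = species,
                 genes = genes,
                 chromosome_lengths = chromosome_lengths,
                 sequences = sequences[genes$gene_id],
                 protected_sites = protected_sites,
                 log = log),
            class = "genome")
}

.check_no_overlap <- function(genes) {
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      stop("overlapping genes on chromosome ", chr)
  }
  invisible(TRUE)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome of", x$species, "-", nrow(x$genes), "genes on",
      length(x$chromosome_lengths), "chromosomes;",
      length(x$log), "logged events\n")
  invisible(x)
}

#' Number of genes in a genome
#' @param g a genome.
#' @return integer gene count.
#' @export
n_genes <- function(g) nrow(g$genes)

## ---- truth log -------------------------------------------------------------

TRUTH_LOG_KINDS <- c("WGD", "LOSS", "LOCAL_DUP", "TRANSLOCATION",
                     "SPECIATION", "SUBSTITUTION_EPOCH")

#' Create a truth-log event
#'
#' The truth log records every evolutionary event applied to a genome, with
#' enough parameters (including derived random seeds) that replaying the log
#' from the ancestral genome reproduces the extant genome exactly
#' (see [replay_log()]).
#'
#' @param kind one of `WGD`, `LOSS`, `LOCAL_DUP`, `TRANSLOCATION`,
#'   `SPECIATION`, `SUBSTITUTION_EPOCH`.
#' @param branch branch label (species-tree path) the event occurred on.
#' @param genes affected gene ids (may be empty).
#' @param ... event parameters (labels, seeds, intervals ...).
#' @return a list of class `"truth_event"`.
#' @export
truth_event <- function(kind, branch = "root", genes = character(), ...) {
  kind <- match.arg(kind, TRUTH_LOG_KINDS)
  structure(list(kind = kind, branch = branch, genes = genes,
                 params = list(...)),
            class = "truth_event")
}

#' Write a truth log to TSV (one event per row)
#'
#' @param log list of [truth_event()] objects (e.g. `genome$log`).
#' @param path output file.
#' @export
write_truth_log <- function(log, path) {
  rows <- vapply(log, function(e) {
    par <- vapply(names(e$params), function(nm) {
      paste0(nm, "=", paste(format(e$params[[nm]], digits = 15),
                            collapse = "|"))
    }, character(1))
    paste(e$kind, e$branch, paste(e$genes, collapse = ","),
          paste(par, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c("kind\tbranch\tgenes\tparams", rows), con = path)
  invisible(path)
}

## ---- file I/O --------------------------------------------------------------

#' Read / write gene tables
#'
#' Tab-separated, one gene per row, schema columns as in [as_gene_table()].
#'
#' @param path file path.
#' @return `read_gene_table`: a validated gene table.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  as_gene_table(df)
}

#' @rdname read_gene_table
#' @param genes gene table to write.
#' @export
write_gene_table <- function(genes, path) {
  genes <- as_gene_table(genes)
  genes$start <- format(genes$start, scientific = FALSE, trim = TRUE)
  genes$end <- format(genes$end, scientific = FALSE, trim = TRUE)
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings. Sequences are returned as a plain named
#' character vector; `X` is tolerated, other ambiguity codes are rejected.
#'
#' @param path file path.
#' @param aligned logical; if `TRUE`, gap characters `-` are allowed.
#' @return `read_fasta`: named character vector of residue strings.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  alphabet <- paste0("ACDEFGHIKLMNPQRSTVWYX", if (aligned) "-")
  bad <- grepl(sprintf("[^%s]", alphabet), seqs)
  if (any(bad))
    stop("illegal residue characters in: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of residue strings.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
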