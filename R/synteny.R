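## Conserved-synteny analysis: genomic region selection around anchor genes,
## family presence across a candidate chromosome set, neighboring-family
## selection (members on >= 3 candidate chromosomes), paralogon quartet
## completeness, and color-coded synteny table export.

#' Genomic region
#'
#' 0-based half-open base-pair window on a chromosome, or a whole
#' chromosome.
#'
#' @param chromosome chromosome name.
#' @param start,end window bounds (ignored when `whole_chromosome`).
#' @param whole_chromosome admit every gene on the chromosome.
#' @return list of class `"genomic_region"`.
#' @export
genomic_region <- function(chromosome, start = 0, end = Inf,
                           whole_chromosome = FALSE) {
  if (!whole_chromosome && !(start < end))
    stop("start must be < end unless whole_chromosome")
  structure(list(chromosome = chromosome, start = start, end = end,
                 whole_chromosome = isTRUE(whole_chromosome)),
            class = "genomic_region")
}

#' Region spanning a set of anchor genes plus a flank
#'
#' Mirrors the window construction "from `flank` before the first anchor to
#' `flank` after the last": `[min(start) - flank, max(end) + flank]`,
#' clipped to `[0, chromosome_length]`.
#'
#' @param anchor_genes gene-table rows sharing one chromosome.
#' @param flank flank in bp (>= 0); default 10 Mb.
#' @param chromosome_length optional upper clip bound.
#' @return a [genomic_region()].
#' @export
region_from_anchors <- function(anchor_genes, flank = 1e7,
                                chromosome_length = NULL) {
  if (nrow(anchor_genes) == 0L) stop("empty anchor list")
  if (flank < 0) stop("flank must be >= 0")
  chrs <- unique(anchor_genes$chromosome)
  if (length(chrs) != 1L) stop("anchors lie on different chromosomes")
  lo <- max(0, min(anchor_genes$start) - flank)
  hi <- max(anchor_genes$end) + flank
  if (!is.null(chromosome_length)) hi <- min(hi, chromosome_length)
  genomic_region(chrs, lo, hi)
}

#' Family presence over candidate chromosome regions
#'
#' Counts, for every family, its members inside each candidate chromosome's
#' region. Membership is decided by gene start position (0-based half-open);
#' whole-chromosome regions admit every gene on that chromosome.
#'
#' @param gene_table a gene table (see [as_gene_table()]).
#' @param regions list of [genomic_region()]s, one per candidate chromosome.
#' @param chromosomes optional chromosome universe; defaults to the
#'   chromosomes occurring in the gene table. A candidate chromosome may
#'   legitimately carry zero genes (every member lost) as long as it exists
#'   in the universe.
#' @return object of class `"family_presence"`: a family x chromosome count
#'   matrix plus the candidate chromosome set.
#' @export
family_presence <- function(gene_table, regions, chromosomes = NULL) {
  gene_table <- as_gene_table(gene_table)
  chrs <- vapply(regions, function(r) r$chromosome, character(1))
  if (anyDuplicated(chrs)) stop("one region per candidate chromosome")
  missing <- setdiff(chrs, union(unique(gene_table$chromosome),
                                 chromosomes))
  if (length(missing) > 0L)
    stop("region chromosome absent from gene table: ",
         paste(missing, collapse = ", "))
  fams <- sort(unique(gene_table$family_id))
  counts <- matrix(0L, length(fams), length(chrs),
                   dimnames = list(fams, chrs))
  for (r in regions) {
    g <- gene_table[gene_table$chromosome == r$chromosome, , drop = FALSE]
    if (!r$whole_chromosome)
      g <- g[g$start >= r$start & g$start < r$end, , drop = FALSE]
    if (nrow(g) > 0L) {
      tab <- table(g$family_id)
      counts[names(tab), r$chromosome] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, candidates = chrs),
            class = "family_presence")
}

#' @export
print.family_presence <- function(x, ...) {
  cat("family presence:", nrow(x$counts), "families x",
      length(x$candidates), "candidate chromosomes\n")
  invisible(x)
}

#' Select neighboring families present on enough candidate chromosomes
#'
#' Families whose members occur on at least `min_chromosomes` of the
#' candidate chromosomes (default 3, the selection rule for putative
#' 2R paralogon members).
#'
#' @param presence a [family_presence()].
#' @param min_chromosomes minimum chromosome count (>= 1).
#' @return sorted character vector of family ids.
#' @export
select_families <- function(presence, min_chromosomes = 3L) {
  stopifnot(inherits(presence, "family_presence"), min_chromosomes >= 1L)
  n_chr <- rowSums(presence$counts > 0L)
  sort(names(n_chr)[n_chr >= min_chromosomes])
}

#' Quartet completeness per family
#'
#' A family is a full quartet when all four candidate chromosomes carry at
#' least one member, i.e. all copies generated in the two genome doublings
#' were retained. With a candidate set of size other than 4 the flag is
#' computed against the actual size, with a warning.
#'
#' @param families family ids to evaluate.
#' @param presence a [family_presence()].
#' @return data.frame with `family_id`, `n_chromosomes`, `full_quartet`;
#'   attribute `"n_full"` carries the summary count.
#' @export
quartet_completeness <- function(families, presence) {
  stopifnot(inherits(presence, "family_presence"))
  k <- length(presence$candidates)
  if (k != 4L)
    warning("candidate set has ", k,
            " chromosomes; quartet flag computed against that size")
  cc <- rowSums(presence$counts[families, , drop = FALSE] > 0L)
  out <- data.frame(family_id = families,
                    n_chromosomes = as.integer(cc),
                    full_quartet = cc == k,
                    stringsAsFactors = FALSE)
  attr(out, "n_full") <- sum(out$full_quartet)
  out
}

#' Build conserved-synteny (paralogon) tables
#'
#' One table per species: rows are families, columns the reference
#' species' candidate chromosomes (the color classes of the presentation),
#' cells the gene ids placed there. Genes are placed by their ortholog
#' group's majority chromosome among the reference species' members; genes
#' whose group has no reference member land in the `unplaced` column.
#'
#' @param gene_tables named list of gene tables, one per species.
#' @param ortholog_groups list of gene-id character vectors (each group =
#'   one set of orthologs across species, e.g. a clade of the gene tree).
#' @param reference_species name of the reference species (must be in
#'   `gene_tables`).
#' @return named list of data.frames of class `"paralogon_table"` (one per
#'   species) with a `"reference_chromosomes"` attribute.
#' @export
build_synteny_table <- function(gene_tables, ortholog_groups,
                                reference_species) {
  stopifnot(reference_species %in% names(gene_tables))
  all_genes <- do.call(rbind, lapply(names(gene_tables), function(sp) {
    g <- as_gene_table(gene_tables[[sp]])
    g$species <- sp
    g
  }))
  missing <- setdiff(unlist(ortholog_groups), all_genes$gene_id)
  if (length(missing) > 0L)
    stop("ortholog group references genes missing from tables: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ref_chr_of <- function(group) {
    rows <- all_genes[all_genes$gene_id %in% group &
                      all_genes$species == reference_species, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_character_)
    tab <- sort(table(rows$chromosome), decreasing = TRUE)
    names(tab)[1]
  }
  group_chr <- vapply(ortholog_groups, ref_chr_of, character(1))
  ref_chroms <- sort(unique(group_chr[!is.na(group_chr)]))
  out <- list()
  for (sp in names(gene_tables)) {
    g <- as_gene_table(gene_tables[[sp]])
    fams <- sort(unique(g$family_id))
    cols <- c(ref_chroms, "unplaced")
    cells <- matrix("", length(fams), length(cols),
                    dimnames = list(fams, cols))
    for (gi in seq_along(ortholog_groups)) {
      grp <- ortholog_groups[[gi]]
      col <- if (is.na(group_chr[gi])) "unplaced" else group_chr[gi]
      rows <- g[g$gene_id %in% grp, , drop = FALSE]
      for (ri in seq_len(nrow(rows))) {
        fam <- rows$family_id[ri]
        cur <- cells[fam, col]
        cells[fam, col] <- if (nzchar(cur))
          paste(cur, rows$gene_id[ri], sep = ",") else rows$gene_id[ri]
      }
    }
    df <- data.frame(family_id = fams, cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
    class(df) <- c("paralogon_table", "data.frame")
    attr(df, "reference_chromosomes") <- ref_chroms
    out[[sp]] <- df
  }
  out
}

#' Write / read a paralogon table TSV
#'
#' The first line is a `#`-prefixed legend naming the reference-species
#' chromosome color classes; write then read is the identity.
#'
#' @param table a `paralogon_table` from [build_synteny_table()].
#' @param path file path.
#' @export
write_paralogon_table <- function(table, path) {
  legend <- paste0("# reference chromosomes: ",
                   paste(attr(table, "reference_chromosomes"),
                         collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(legend, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_paralogon_table
#' @return `read_paralogon_table`: the table with its legend attribute.
#' @export
read_paralogon_table <- function(path) {
  first <- readLines(path, n = 1L)
  ref <- strsplit(sub("^# reference chromosomes: ", "", first), ",")[[1]]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          colClasses = "character")
  class(df) <- c("paralogon_table", "data.frame")
  attr(df, "reference_chromosomes") <- ref
  df
}
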