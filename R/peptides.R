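## Prepropeptide annotation: opioid-core / melanocortin motif scanning,
## alignment-contextual core classification, conserved cysteines, and
## dibasic-cleavage mature-peptide prediction.

#' Motif patterns
#'
#' A motif pattern is an anchored per-position residue-class list. The two
#' built-ins are the opioid core tetrapeptide anchor `[YF]GGF` (the Y/FGGF
#' motif opening enkephalins, dynorphins, endorphin and nociceptin) and the
#' melanocortin tetrapeptide `HFRW` shared by the ACTH/MSH peptides.
#'
#' @param name pattern name, used as `motif_class` in scan output.
#' @param classes list of character vectors, one per position; each vector
#'   holds the residues allowed at that position.
#' @return a list of class `"motif_pattern"`.
#' @export
motif_pattern <- function(name, classes) {
  if (length(classes) < 2L) stop("pattern length must be >= 2")
  if (any(vapply(classes, length, 1L) == 0L)) stop("empty residue class")
  structure(list(name = name, classes = lapply(classes, toupper)),
            class = "motif_pattern")
}

#' @rdname motif_pattern
#' @export
opioid_core_pattern <- function() {
  motif_pattern("opioid_core", list(c("Y", "F"), "G", "G", "F"))
}

#' @rdname motif_pattern
#' @export
melanocortin_pattern <- function() {
  motif_pattern("melanocortin", list("H", "F", "R", "W"))
}

.check_protein <- function(sequence, what = "sequence") {
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop(what, " contains characters outside the amino-acid alphabet (+X)")
  invisible(TRUE)
}

#' Scan a sequence for motif occurrences
#'
#' Slides the anchor pattern over the sequence and reports every window with
#' at most `max_mismatch` mismatching positions (overlaps allowed, ascending
#' position). `X` never matches any residue class.
#'
#' @param sequence residue string (20-letter alphabet, `X` allowed).
#' @param pattern a [motif_pattern()].
#' @param max_mismatch maximum mismatches per window (default 0).
#' @param sequence_id id recorded in the output.
#' @return data.frame with columns `sequence_id`, `position` (0-based start),
#'   `matched_text`, `motif_class`, `status` (`intact` iff 0 mismatches,
#'   else `degenerate`), `mismatches`.
#' @export
scan_motifs <- function(sequence, pattern, max_mismatch = 0L,
                        sequence_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"), max_mismatch >= 0L)
  sequence <- toupper(sequence)
  .check_protein(sequence)
  m <- length(pattern$classes)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  hits <- list()
  if (L >= m) {
    for (i in seq_len(L - m + 1L)) {
      mm <- 0L
      for (j in seq_len(m)) {
        cj <- chars[i + j - 1L]
        if (cj == "X" || !(cj %in% pattern$classes[[j]])) mm <- mm + 1L
        if (mm > max_mismatch) break
      }
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_id = sequence_id,
          position = i - 1L,
          matched_text = substr(sequence, i, i + m - 1L),
          motif_class = pattern$name,
          status = if (mm == 0L) "intact" else "degenerate",
          mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(sequence_id = character(), position = integer(),
                      matched_text = character(), motif_class = character(),
                      status = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Scan a set of sequences and write a motif report
#'
#' @param sequences named character vector.
#' @param pattern a [motif_pattern()].
#' @param max_mismatch per-window mismatch budget.
#' @return combined hit data.frame (as [scan_motifs()]), one block per
#'   sequence in input order.
#' @export
scan_motif_set <- function(sequences, pattern, max_mismatch = 0L) {
  out <- lapply(names(sequences), function(nm)
    scan_motifs(sequences[[nm]], pattern, max_mismatch, sequence_id = nm))
  do.call(rbind, out)
}

#' @rdname scan_motif_set
#' @param hits a hit data.frame.
#' @param path output TSV path.
#' @export
write_motif_report <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- alignment-contextual classification ----------------------------------

#' Classify a core site as intact / degenerate / absent in alignment context
#'
#' A core site is a set of alignment columns at which homologs carry the
#' motif. The focal row is `intact` if it matches the pattern at every core
#' column, `absent` if all core columns are gaps (or if mismatches exceed
#' `max_degenerate`), otherwise `degenerate`. Gaps at individual columns
#' count as mismatches.
#'
#' @param alignment a [protein_alignment()].
#' @param core_columns 1-based alignment column indices, one per pattern
#'   position.
#' @param sequence_id focal row id.
#' @param pattern a [motif_pattern()] (default opioid core).
#' @param max_degenerate most mismatches still called `degenerate`
#'   (default 2; beyond it the site is called `absent`).
#' @return list with `status` and `mismatches`.
#' @export
classify_core_status <- function(alignment, core_columns, sequence_id,
                                 pattern = opioid_core_pattern(),
                                 max_degenerate = 2L) {
  stopifnot(inherits(alignment, "protein_alignment"), max_degenerate >= 1L)
  mat <- alignment_matrix(alignment)
  if (!sequence_id %in% rownames(mat)) stop("unknown sequence id: ",
                                            sequence_id)
  if (length(core_columns) != length(pattern$classes))
    stop("core_columns must have one column per pattern position")
  if (any(core_columns < 1L) || any(core_columns > ncol(mat)))
    stop("core_columns outside alignment")
  row <- mat[sequence_id, core_columns]
  if (all(row == "-")) return(list(status = "absent",
                                   mismatches = length(core_columns)))
  mm <- sum(vapply(seq_along(row), function(j) {
    cj <- row[j]
    cj == "-" || cj == "X" || !(cj %in% pattern$classes[[j]])
  }, logical(1)))
  status <- if (mm == 0L) "intact"
            else if (mm <= max_degenerate) "degenerate"
            else "absent"
  list(status = status, mismatches = as.integer(mm))
}

#' Find conserved cysteine columns
#'
#' Reports alignment columns where the fraction of non-gap rows equal to `C`
#' is at least `min_presence` (and at least one row is non-gap), optionally
#' restricted to columns before `n_terminal_limit`.
#'
#' @param alignment a [protein_alignment()].
#' @param min_presence required fraction of non-gap rows that are `C`.
#' @param n_terminal_limit optional last 1-based column to consider.
#' @return integer vector of 1-based column indices.
#' @export
find_conserved_cysteines <- function(alignment, min_presence = 1.0,
                                     n_terminal_limit = NULL) {
  stopifnot(inherits(alignment, "protein_alignment"))
  mat <- alignment_matrix(alignment)
  if (nrow(mat) == 0L) stop("empty alignment")
  last <- if (is.null(n_terminal_limit)) ncol(mat)
          else min(n_terminal_limit, ncol(mat))
  out <- integer(0)
  for (j in seq_len(last)) {
    col <- mat[, j]
    ng <- col[col != "-"]
    if (length(ng) >= 1L && sum(ng == "C") / length(ng) >= min_presence)
      out <- c(out, j)
  }
  out
}

#' Count consensus matches at configured positions
#'
#' Used e.g. for the six conserved nocistatin residues: counts at how many of
#' the given columns the focal row equals the supplied consensus residue. A
#' gap never matches.
#'
#' @param alignment a [protein_alignment()].
#' @param positions 1-based column indices.
#' @param consensus character vector of consensus residues, one per position.
#' @param sequence_id focal row.
#' @return integer count of matching positions.
#' @export
conservation_count <- function(alignment, positions, consensus, sequence_id) {
  stopifnot(inherits(alignment, "protein_alignment"),
            length(positions) == length(consensus))
  mat <- alignment_matrix(alignment)
  if (!sequence_id %in% rownames(mat)) stop("unknown sequence id: ",
                                            sequence_id)
  if (any(positions < 1L) || any(positions > ncol(mat)))
    stop("positions outside alignment")
  row <- mat[sequence_id, positions]
  sum(row != "-" & row == toupper(consensus))
}

## ---- mature-peptide prediction ---------------------------------------------

DIBASIC <- c("KK", "KR", "RK", "RR")

#' Predict mature peptides around intact motif hits
#'
#' For each intact hit, extends left and right to the nearest flanking
#' dibasic cleavage site (`KK`, `KR`, `RK`, `RR`) or sequence terminus. The
#' dibasic residues themselves are excluded; duplicate intervals are merged.
#' Monobasic cleavage is not modelled.
#'
#' @param sequence residue string.
#' @param hits hit data.frame from [scan_motifs()]; only rows with
#'   `status == "intact"` are used.
#' @return data.frame with `start`, `end` (0-based half-open) and `peptide`.
#' @export
predict_mature_peptides <- function(sequence, hits) {
  sequence <- toupper(sequence)
  .check_protein(sequence)
  L <- nchar(sequence)
  hits <- hits[hits$status == "intact", , drop = FALSE]
  if (nrow(hits) > 0L) {
    wlen <- nchar(hits$matched_text)
    if (any(hits$position < 0L) || any(hits$position + wlen > L))
      stop("hit outside sequence")
  }
  chars <- strsplit(sequence, "")[[1]]
  pairs <- which(paste0(chars[-L], chars[-1]) %in% DIBASIC)  # 1-based start
  res <- list()
  for (i in seq_len(nrow(hits))) {
    p0 <- hits$position[i]            # 0-based hit start
    h_start1 <- p0 + 1L               # 1-based
    h_end1 <- p0 + nchar(hits$matched_text[i])
    left <- pairs[pairs + 1L < h_start1]
    start1 <- if (length(left)) max(left) + 2L else 1L
    right <- pairs[pairs > h_end1]
    end1 <- if (length(right)) min(right) - 1L else L
    res[[length(res) + 1L]] <- c(start1 - 1L, end1)   # 0-based half-open
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  iv <- unique(do.call(rbind, res))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  data.frame(start = iv[, 1], end = iv[, 2],
             peptide = substring(sequence, iv[, 1] + 1L, iv[, 2]),
             stringsAsFactors = FALSE)
}

#' @rdname predict_mature_peptides
#' @param peptides interval data.frame from `predict_mature_peptides`.
#' @param path output TSV path.
#' @export
write_peptide_intervals <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
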