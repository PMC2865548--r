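## Self-contained progressive multiple alignment: k-mer guide distances,
## affine-gap global pairwise alignment (Gotoh), and profile-profile merging
## with average-of-pairs column scoring.

#' Protein alignment container
#'
#' An alignment is a named character vector of equal-length gapped residue
#' strings. Removing the gaps from any row reproduces the input sequence
#' exactly, and no column is all-gap.
#'
#' @param seqs named character vector of gapped residue strings.
#' @return object of class `"protein_alignment"`.
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) stop("alignment rows differ in length")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX-]", seqs)))
    stop("illegal characters in alignment")
  structure(seqs, class = "protein_alignment")
}

#' @rdname protein_alignment
#' @param x a protein_alignment.
#' @return `alignment_matrix`: character matrix (rows = sequences).
#' @export
alignment_matrix <- function(x) {
  stopifnot(inherits(x, "protein_alignment"))
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

#' @rdname protein_alignment
#' @return `ungap`: the input sequences with gap characters removed.
#' @export
ungap <- function(x) {
  out <- gsub("-", "", unclass(x), fixed = TRUE)
  names(out) <- names(x)
  out
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein alignment:", length(x), "rows x", nchar(x[[1]]), "columns\n")
  invisible(x)
}

#' Alignment scoring scheme
#'
#' Affine gap costs follow the Clustal-style parameterisation: a gap of
#' length L costs `gap_open + L * gap_extend` (the opening charge is paid
#' once per gap, the extension charge per column including the first).
#' Defaults are gap open 10.0 and extension 0.2 per column. The substitution
#' table is any matrix shipped with Biostrings (BLOSUM/PAM series);
#' BLOSUM62 by default.
#'
#' @param matrix substitution matrix name (e.g. `"BLOSUM62"`, `"PAM250"`).
#' @param gap_open,gap_extend non-negative gap costs.
#' @param terminal_gaps if `TRUE` (default) terminal gaps are charged like
#'   internal ones.
#' @return list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.2, terminal_gaps = TRUE) {
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be >= 0")
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || !exists(matrix, envir = e))
    stop("unknown substitution matrix: ", matrix)
  structure(list(name = matrix, mat = get(matrix, envir = e),
                 gap_open = gap_open, gap_extend = gap_extend,
                 terminal_gaps = isTRUE(terminal_gaps)),
            class = "scoring_scheme")
}

## Core affine-gap DP (Gotoh, three states) on a precomputed column-score
## matrix S (rows = columns of profile A, cols = columns of profile B).
## Predecessor-state pointers are fixed at fill time with the deterministic
## tie preference M (substitution) > GA (gap in A) > GB (gap in B).
## Returns the move path ("M" consume both, "GA" gap in A / consume B,
## "GB" gap in B / consume A) and the optimal score.
.affine_dp <- function(S, open, ext, terminal_gaps = TRUE) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e18
  eps <- 1e-9
  M  <- matrix(NEG, n + 1L, m + 1L)
  GA <- matrix(NEG, n + 1L, m + 1L)  # gap in A, consumes B (j advances)
  GB <- matrix(NEG, n + 1L, m + 1L)  # gap in B, consumes A (i advances)
  PM  <- matrix(NA_character_, n + 1L, m + 1L)
  PGA <- matrix(NA_character_, n + 1L, m + 1L)
  PGB <- matrix(NA_character_, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  lead_cost <- function(k) if (terminal_gaps) -(open + ext * k) else 0
  if (m > 0L) for (j in seq_len(m)) {
    GA[1L, j + 1L] <- lead_cost(j)
    PGA[1L, j + 1L] <- if (j == 1L) "START" else "GA"
  }
  if (n > 0L) for (i in seq_len(n)) {
    GB[i + 1L, 1L] <- lead_cost(i)
    PGB[i + 1L, 1L] <- if (i == 1L) "START" else "GB"
  }
  pick <- function(vm, vga, vgb) {
    best <- max(vm, vga, vgb)
    st <- if (vm >= best - eps) "M" else if (vga >= best - eps) "GA" else "GB"
    list(v = best, st = st)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      p <- pick(M[i, j], GA[i, j], GB[i, j])
      M[i + 1L, j + 1L] <- S[i, j] + p$v
      PM[i + 1L, j + 1L] <- if (i == 1L && j == 1L) "START" else p$st
      p <- pick(M[i + 1L, j] - open - ext,
                GA[i + 1L, j] - ext,
                GB[i + 1L, j] - open - ext)
      GA[i + 1L, j + 1L] <- p$v
      PGA[i + 1L, j + 1L] <- if (i == 0L && j == 1L) "START" else p$st
      p <- pick(M[i, j + 1L] - open - ext,
                GA[i, j + 1L] - open - ext,
                GB[i, j + 1L] - ext)
      GB[i + 1L, j + 1L] <- p$v
      PGB[i + 1L, j + 1L] <- p$st
    }
  }
  fin <- pick(M[n + 1L, m + 1L], GA[n + 1L, m + 1L], GB[n + 1L, m + 1L])
  state <- fin$st
  i <- n; j <- m
  path <- character(n + m)
  k <- n + m
  while (i > 0L || j > 0L) {
    path[k] <- state
    k <- k - 1L
    if (state == "M") {
      prev <- PM[i + 1L, j + 1L]; i <- i - 1L; j <- j - 1L
    } else if (state == "GA") {
      prev <- PGA[i + 1L, j + 1L]; j <- j - 1L
    } else {
      prev <- PGB[i + 1L, j + 1L]; i <- i - 1L
    }
    if (identical(prev, "START") || (i == 0L && j == 0L)) break
    state <- prev
  }
  list(path = path[(k + 1L):(n + m)], score = fin$v)
}

.residue_score <- function(a, b, mat) {
  if (!a %in% rownames(mat) || !b %in% colnames(mat))
    stop("residue not covered by substitution matrix: ", a, "/", b)
  mat[a, b]
}

#' Optimal global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing substitution score
#' minus affine gap cost (`gap_open + L * gap_extend` per gap of length L).
#' Tie-breaking is deterministic: substitution preferred over a gap in `a`,
#' which is preferred over a gap in `b`.
#'
#' @param a,b residue strings (non-empty).
#' @param scoring a [scoring_scheme()].
#' @return list with `alignment` (a two-row [protein_alignment()] named
#'   `a`/`b` or by the input names) and `score`.
#' @export
pairwise_align <- function(a, b, scoring = scoring_scheme()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  A <- protein_alignment(c(a = toupper(a)))
  B <- protein_alignment(c(b = toupper(b)))
  merged <- profile_merge(A, B, scoring)
  list(alignment = merged, score = attr(merged, "score"))
}

#' k-mer guide-tree distances
#'
#' Distance between two sequences is `1 - shared / min_total`, where
#' `shared` is the number of k-mers in common (counted with multiplicity)
#' and `min_total` the smaller of the two k-mer counts. Identical sequences
#' have distance 0; sequences with disjoint k-mer sets distance 1.
#'
#' @param sequences named character vector (each longer than or equal to
#'   `k` residues).
#' @param k word length (>= 1).
#' @return symmetric distance matrix with zero diagonal.
#' @export
guide_tree_distances <- function(sequences, k = 3L) {
  stopifnot(k >= 1L)
  if (any(nchar(sequences) < k)) stop("sequence shorter than k")
  kmers <- lapply(sequences, function(s) {
    n <- nchar(s) - k + 1L
    table(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ta <- kmers[[i]]; tb <- kmers[[j]]
    common <- intersect(names(ta), names(tb))
    shared <- sum(pmin(ta[common], tb[common]))
    denom <- min(sum(ta), sum(tb))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

#' Build a rooted guide tree from k-mer distances
#'
#' Average-linkage hierarchical clustering on [guide_tree_distances()],
#' returned as an `ape` phylo object whose leaves are the sequence ids.
#'
#' @param sequences named character vector.
#' @param k word length.
#' @return a rooted `phylo` guide tree.
#' @export
guide_tree <- function(sequences, k = 3L) {
  D <- guide_tree_distances(sequences, k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Merge two alignments (profile-profile alignment)
#'
#' Aligns two profiles column-against-column under the affine-gap DP, using
#' average-of-pairs column scoring (gap/residue pairs contribute zero).
#' Within-profile columns are preserved as units: only full gap columns are
#' ever inserted into a profile.
#'
#' @param alignment_a,alignment_b [protein_alignment()]s with disjoint ids.
#' @param scoring a [scoring_scheme()].
#' @return merged [protein_alignment()] with a `"score"` attribute.
#' @export
profile_merge <- function(alignment_a, alignment_b,
                          scoring = scoring_scheme()) {
  stopifnot(inherits(alignment_a, "protein_alignment"),
            inherits(alignment_b, "protein_alignment"))
  if (length(intersect(names(alignment_a), names(alignment_b))) > 0L)
    stop("sequence id collision between profiles")
  ma <- alignment_matrix(alignment_a)
  mb <- alignment_matrix(alignment_b)
  mat <- scoring$mat
  alpha <- intersect(rownames(mat), c(AA20, "X"))
  fa <- .col_freq(ma, alpha)
  fb <- .col_freq(mb, alpha)
  S <- t(fa) %*% mat[alpha, alpha] %*% fb / (nrow(ma) * nrow(mb))
  dp <- .affine_dp(S, scoring$gap_open, scoring$gap_extend,
                   scoring$terminal_gaps)
  gap_a <- paste(rep("-", nrow(ma)), collapse = "")
  gap_b <- paste(rep("-", nrow(mb)), collapse = "")
  ia <- 0L; ib <- 0L
  cols_a <- character(length(dp$path)); cols_b <- character(length(dp$path))
  for (k in seq_along(dp$path)) {
    mv <- dp$path[k]
    if (mv == "M") {
      ia <- ia + 1L; ib <- ib + 1L
      cols_a[k] <- paste(ma[, ia], collapse = "")
      cols_b[k] <- paste(mb[, ib], collapse = "")
    } else if (mv == "GA") {
      ib <- ib + 1L
      cols_a[k] <- gap_a
      cols_b[k] <- paste(mb[, ib], collapse = "")
    } else {
      ia <- ia + 1L
      cols_a[k] <- paste(ma[, ia], collapse = "")
      cols_b[k] <- gap_b
    }
  }
  rows_a <- .cols_to_rows(cols_a, nrow(ma))
  rows_b <- .cols_to_rows(cols_b, nrow(mb))
  out <- c(stats::setNames(rows_a, rownames(ma)),
           stats::setNames(rows_b, rownames(mb)))
  res <- protein_alignment(out)
  attr(res, "score") <- dp$score
  res
}

## residue-frequency count matrix (alphabet x columns); gaps/unknowns drop out
.col_freq <- function(m, alpha) {
  f <- matrix(0, length(alpha), ncol(m), dimnames = list(alpha, NULL))
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    tab <- tab[names(tab) %in% alpha]
    f[names(tab), j] <- as.numeric(tab)
  }
  f
}

.cols_to_rows <- function(cols, n_rows) {
  chm <- do.call(cbind, strsplit(cols, ""))
  apply(chm, 1L, paste, collapse = "")
}

#' Progressive multiple alignment
#'
#' Aligns sequences in post-order over a rooted guide tree, merging child
#' profiles with [profile_merge()]. With two sequences this reduces to
#' [pairwise_align()]. Every output row reproduces its input sequence when
#' ungapped.
#'
#' @param sequences named character vector.
#' @param tree rooted `phylo` guide tree whose tip labels equal
#'   `names(sequences)`; built with [guide_tree()] when `NULL`.
#' @param scoring a [scoring_scheme()].
#' @return a [protein_alignment()].
#' @export
progressive_align <- function(sequences, tree = NULL,
                              scoring = scoring_scheme()) {
  if (length(sequences) == 0L) stop("no sequences")
  sequences <- toupper(sequences)
  if (!is.null(tree) && !setequal(tree$tip.label, names(sequences)))
    stop("guide-tree leaves do not match sequence ids")
  if (length(sequences) == 1L)
    return(protein_alignment(sequences))
  if (is.null(tree)) tree <- guide_tree(sequences)
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) {
      id <- tree$tip.label[node]
      return(protein_alignment(stats::setNames(sequences[id], id)))
    }
    kids <- children[[as.character(node)]]
    prof <- build(kids[1])
    for (k in kids[-1]) prof <- profile_merge(prof, build(k), scoring)
    prof
  }
  root <- ntip + 1L
  res <- build(root)
  attr(res, "score") <- NULL
  res
}

#' Read / write aligned FASTA
#'
#' @param path file path.
#' @return `read_alignment`: a [protein_alignment()].
#' @export
read_alignment <- function(path) {
  protein_alignment(read_fasta(path, aligned = TRUE))
}

#' @rdname read_alignment
#' @param alignment a [protein_alignment()].
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(unclass(alignment), path)
}
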