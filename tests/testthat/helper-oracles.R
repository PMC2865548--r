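# Independent oracles used across the suite.

# Exhaustive enumeration of every global alignment of a and b under affine
# gap cost (open charged once per gap, extension per column including the
# first). Exponential; only for short sequences.
brute_align_score <- function(a, b, scoring) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mat <- scoring$mat
  open <- scoring$gap_open
  ext <- scoring$gap_extend
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(av) && j > length(bv)) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1L, j + 1L, "M", sc + mat[av[i], bv[j]])
    if (j <= length(bv))
      rec(i, j + 1L, "GA", sc - ext - if (prev == "GA") 0 else open)
    if (i <= length(av))
      rec(i + 1L, j, "GB", sc - ext - if (prev == "GB") 0 else open)
  }
  rec(1L, 1L, "start", 0)
  best
}

# Brute-force sliding-window exact matcher for a motif pattern.
brute_motif_positions <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  m <- length(pattern$classes)
  out <- integer(0)
  if (length(chars) < m) return(out)
  for (i in seq_len(length(chars) - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      cj <- chars[i + j - 1L]
      if (cj == "X" || !(cj %in% pattern$classes[[j]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i - 1L)   # 0-based
  }
  out
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               n, replace = TRUE), collapse = "")
}

# Random additive distance matrix from a random binary tree with branch
# lengths in [0.1, 2]; returns the generating tree (ape phylo) and the
# path-length matrix computed by ape (independent of the NJ under test).
random_additive_case <- function(n_taxa) {
  labs <- paste0("t", seq_len(n_taxa))
  nodes <- as.list(labs)
  while (length(nodes) > 2L) {
    pick <- sample.int(length(nodes), 2L)
    bl <- runif(2, 0.1, 2)
    merged <- sprintf("(%s:%.10f,%s:%.10f)",
                      nodes[[pick[1]]], bl[1], nodes[[pick[2]]], bl[2])
    nodes <- c(nodes[-pick], merged)
  }
  bl <- runif(2, 0.1, 2)
  nwk <- sprintf("(%s:%.10f,%s:%.10f);",
                 nodes[[1]], bl[1], nodes[[2]], bl[2])
  phy <- ape::read.tree(text = nwk)
  D <- stats::cophenetic(phy)[labs, labs]
  list(tree = phy, D = D)
}
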