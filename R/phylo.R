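## Distance computation, neighbor joining, bootstrap supports, outgroup
## rooting, species-overlap duplication annotation, and relative dating of
## duplications against a speciation split. Trees are ape "phylo" objects;
## leaf labels follow the species|gene_id|chromosome convention.

#' Protein distance matrix from an alignment
#'
#' Pairwise proportion of mismatching residues over mutually ungapped
#' columns (pairwise deletion by default; complete deletion drops every
#' column with any gap first), optionally transformed with the Kimura
#' protein correction `d = -ln(1 - p - 0.2 p^2)`. The correction becomes
#' singular at `p ~ 0.854102` (the positive root of `1 - p - 0.2 p^2`);
#' beyond it the pair is reported as saturated.
#'
#' @param alignment a [protein_alignment()] with at least 2 rows.
#' @param correction `"kimura"` (default) or `"none"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @param saturation `"error"` (default) stops on a saturated pair;
#'   `"cap"` assigns the distance at p = 0.85 instead (used internally by
#'   bootstrap resampling, where occasional saturated replicates are
#'   expected).
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(alignment,
                                    correction = c("kimura", "none"),
                                    deletion = c("pairwise", "complete"),
                                    saturation = c("error", "cap")) {
  correction <- match.arg(correction)
  deletion <- match.arg(deletion)
  saturation <- match.arg(saturation)
  stopifnot(inherits(alignment, "protein_alignment"))
  mat <- alignment_matrix(alignment)
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  ids <- rownames(mat)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  cap_d <- -log(1 - 0.85 - 0.2 * 0.85^2)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) {
      if (saturation == "cap") { D[i, j] <- D[j, i] <- cap_d; next }
      stop("no mutually ungapped columns for pair ", ids[i], " / ", ids[j])
    }
    p <- mean(mat[i, ok] != mat[j, ok])
    d <- if (correction == "none") p else {
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0) {
        if (saturation == "cap") cap_d
        else stop("saturated distance (p = ", signif(p, 6), ") for pair ",
                  ids[i], " / ", ids[j])
      } else -log(arg)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Kimura protein distance correction
#'
#' @param p observed proportion of differing residues.
#' @return corrected distance `-ln(1 - p - 0.2 p^2)`; errors at or beyond
#'   the saturation root `p ~ 0.854102`.
#' @export
kimura_correction <- function(p) {
  arg <- 1 - p - 0.2 * p^2
  if (any(arg <= 0)) stop("saturated distance: p at or beyond 0.854102")
  -log(arg)
}

.check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix not square")
  if (is.null(rownames(D))) stop("distance matrix needs taxon labels")
  if (max(abs(D - t(D))) > 1e-12) stop("asymmetric distance matrix")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

.fmt_bl <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in Q are
#' broken by the lexicographically lowest taxon-index pair, so the result
#' is deterministic. Negative branch-length estimates are clamped to zero
#' (without redistribution). For an additive distance matrix the
#' leaf-to-leaf path lengths of the result equal the input distances.
#'
#' @param D symmetric distance matrix with taxon labels (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  .check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  nwk <- labels            # current subtree newick per active node
  d <- D
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * d[i, j] - r[i] - r[j]
      if (q < best - 1e-12) { best <- q; bi <- i; bj <- j }
    }
    li <- d[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- d[bi, bj] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_nwk <- paste0("(", nwk[bi], ":", .fmt_bl(li), ",",
                      nwk[bj], ":", .fmt_bl(lj), ")")
    others <- setdiff(seq_len(m), c(bi, bj))
    du <- (d[bi, others] + d[bj, others] - d[bi, bj]) / 2
    d2 <- d[others, others, drop = FALSE]
    d2 <- rbind(cbind(d2, du), c(du, 0))
    nwk <- c(nwk[others], new_nwk)
    d <- d2
  }
  ## terminal three-way join via the three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  tre <- paste0("(", nwk[1], ":", .fmt_bl(la), ",",
                nwk[2], ":", .fmt_bl(lb), ",",
                nwk[3], ":", .fmt_bl(lc), ");")
  ape::read.tree(text = tre)
}

## ---- bipartitions ----------------------------------------------------------

.children_map <- function(tree) {
  base::split(tree$edge[, 2], tree$edge[, 1])
}

## tip-label sets below each node (list indexed by node number)
.clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  children <- .children_map(tree)
  rec <- function(v) {
    if (v <= ntip) {
      sets[[v]] <<- tree$tip.label[v]
    } else {
      kids <- children[[as.character(v)]]
      for (k in kids) rec(k)
      sets[[v]] <<- unlist(lapply(kids, function(k) sets[[k]]))
    }
  }
  rec(ntip + 1L)
  sets
}

## canonical keys for the non-trivial bipartitions of an (un)rooted tree
.bipartition_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  sets <- .clade_tip_sets(tree)
  root <- ntip + 1L
  keys <- character(0)
  for (v in seq_along(sets)) {
    if (v <= ntip || v == root) next
    side <- sets[[v]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Bootstrap supports on the reference neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds an NJ tree per
#' replicate, and annotates each internal edge of the full-alignment
#' reference tree with the percentage of replicates containing its
#' bipartition (supports on the reference tree, Clustal-style, not a
#' consensus tree). Deterministic given `seed`. Replicate distances use the
#' saturation cap so occasional saturated resamples do not abort the run.
#'
#' @param alignment a [protein_alignment()].
#' @param n_replicates number of bootstrap replicates (0 = reference tree
#'   without supports).
#' @param seed integer seed.
#' @param correction distance correction, as [protein_distance_matrix()].
#' @return the reference `phylo` tree; internal nodes carry integer support
#'   percentages in `node.label` when `n_replicates > 0`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              correction = "kimura") {
  if (n_replicates < 0L) stop("negative replicate count")
  D <- protein_distance_matrix(alignment, correction = correction,
                               saturation = "cap")
  ref <- neighbor_joining(D)
  if (n_replicates == 0L) return(ref)
  mat <- alignment_matrix(alignment)
  L <- ncol(mat)
  ref_keys <- .bipartition_keys(ref)
  counts <- stats::setNames(rep(0L, length(ref_keys)), ref_keys)
  next_seed <- seed_stream(seed)
  for (r in seq_len(n_replicates)) {
    cols <- with_seed(next_seed(), sample.int(L, L, replace = TRUE))
    rep_rows <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    rep_aln <- protein_alignment(stats::setNames(rep_rows, rownames(mat)))
    Dr <- protein_distance_matrix(rep_aln, correction = correction,
                                  saturation = "cap")
    tr <- neighbor_joining(Dr)
    hit <- ref_keys %in% .bipartition_keys(tr)
    counts[hit] <- counts[hit] + 1L
  }
  pct <- round(100 * counts / n_replicates)
  ## map supports onto reference internal nodes
  ntip <- length(ref$tip.label)
  sets <- .clade_tip_sets(ref)
  tips <- sort(ref$tip.label)
  anchor <- tips[1]
  labs <- rep("", ref$Nnode)
  for (v in (ntip + 1L):(ntip + ref$Nnode)) {
    if (v == ntip + 1L) next                  # root (trifurcation) unlabeled
    side <- sets[[v]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(pct)) labs[v - ntip] <- as.character(pct[[key]])
  }
  ref$node.label <- labs
  ref
}

#' Root a tree on the edge above an outgroup
#'
#' The outgroup must form one full side of some bipartition of the unrooted
#' tree; the root is placed at the midpoint of that edge. An invalid
#' outgroup (not a bipartition side, or the whole leaf set) is an error -
#' there is no silent fallback.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup character vector of tip labels.
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (!all(outgroup %in% tips)) stop("outgroup tips not in tree")
  if (setequal(outgroup, tips)) stop("outgroup cannot be the whole leaf set")
  sets <- .clade_tip_sets(tree)
  valid <- FALSE
  for (v in seq_along(sets)) {
    side <- sets[[v]]
    if (setequal(side, outgroup) || setequal(setdiff(tips, side), outgroup)) {
      valid <- TRUE; break
    }
  }
  if (!valid) stop("outgroup is not one side of any bipartition")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ## split the divided edge length evenly (midpoint rooting on that edge)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  re <- which(rooted$edge[, 1] == root)
  if (length(re) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

## ---- duplication annotation and relative dating ----------------------------

#' Extract the species from tree leaf labels
#'
#' Labels of the form `species|gene_id|chromosome` yield the first field;
#' otherwise the prefix before the first underscore; otherwise the label
#' itself.
#'
#' @param labels character vector of leaf labels.
#' @return character vector of species names.
#' @export
leaf_species <- function(labels) {
  vapply(labels, function(l) {
    if (grepl("|", l, fixed = TRUE)) strsplit(l, "|", fixed = TRUE)[[1]][1]
    else if (grepl("_", l, fixed = TRUE)) sub("_.*$", "", l)
    else l
  }, character(1), USE.NAMES = FALSE)
}

#' Annotate internal nodes as duplication or speciation (species overlap)
#'
#' An internal node of a rooted gene tree is labeled a duplication iff the
#' species sets of its child clades intersect, otherwise a speciation.
#'
#' @param tree a rooted `phylo` whose leaves carry species (see
#'   [leaf_species()]).
#' @param species optional named character vector mapping tip label to
#'   species, overriding the label convention.
#' @return the tree with a `node.annotation` character vector (one entry per
#'   internal node, `"duplication"` or `"speciation"`).
#' @export
annotate_duplications <- function(tree, species = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  spp <- if (is.null(species)) {
    stats::setNames(leaf_species(tree$tip.label), tree$tip.label)
  } else species
  sets <- .clade_tip_sets(tree)
  children <- .children_map(tree)
  ann <- character(tree$Nnode)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- children[[as.character(v)]]
    kid_species <- lapply(kids, function(k) unique(spp[sets[[k]]]))
    dup <- FALSE
    if (length(kid_species) >= 2L) {
      for (i in seq_len(length(kid_species) - 1L))
        for (j in (i + 1L):length(kid_species))
          if (length(intersect(kid_species[[i]], kid_species[[j]])) > 0L)
            dup <- TRUE
    }
    ann[v - ntip] <- if (dup) "duplication" else "speciation"
  }
  tree$node.annotation <- ann
  tree
}

#' Date duplications relative to a speciation split
#'
#' For each node annotated `duplication`, compares the species content of
#' its child clades with a two-sided species split: `before_split` if each
#' child clade contains species from both sides (the duplicate lineages
#' both straddle the speciation), `after_split` if the whole duplication
#' clade is confined to one side, otherwise `unresolved` (e.g. when losses
#' emptied one side of one child clade). Species absent from the split
#' (such as outgroups) are ignored.
#'
#' @param tree a rooted tree annotated by [annotate_duplications()].
#' @param split list of two character vectors of species names.
#' @param species optional tip-to-species override as in
#'   [annotate_duplications()].
#' @return data.frame with `node` (internal node number) and `dating`.
#' @export
relative_dating <- function(tree, split, species = NULL) {
  if (is.null(tree$node.annotation))
    stop("tree lacks duplication annotation; run annotate_duplications()")
  stopifnot(is.list(split), length(split) == 2L)
  ntip <- length(tree$tip.label)
  spp <- if (is.null(species)) {
    stats::setNames(leaf_species(tree$tip.label), tree$tip.label)
  } else species
  tree_species <- unique(unname(spp))
  unknown <- setdiff(c(split[[1]], split[[2]]), tree_species)
  if (length(unknown) > 0L)
    stop("split references species absent from the tree: ",
         paste(unknown, collapse = ", "))
  sets <- .clade_tip_sets(tree)
  children <- .children_map(tree)
  left <- split[[1]]; right <- split[[2]]
  both_sides <- function(s) any(s %in% left) && any(s %in% right)
  res_node <- integer(0); res_lab <- character(0)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (tree$node.annotation[v - ntip] != "duplication") next
    kids <- children[[as.character(v)]]
    kid_species <- lapply(kids, function(k)
      intersect(unique(spp[sets[[k]]]), c(left, right)))
    all_species <- unique(unlist(kid_species))
    lab <- if (length(all_species) == 0L) "unresolved"
      else if (all(vapply(kid_species, function(s)
        length(s) > 0L && both_sides(s), logical(1)))) "before_split"
      else if (all(all_species %in% left) || all(all_species %in% right))
        "after_split"
      else "unresolved"
    res_node <- c(res_node, v); res_lab <- c(res_lab, lab)
  }
  data.frame(node = res_node, dating = res_lab, stringsAsFactors = FALSE)
}

#' Compose / parse leaf labels in the species|gene|chromosome convention
#'
#' @param species,gene_id,chromosome character vectors.
#' @return `make_leaf_labels`: character vector of labels.
#' @export
make_leaf_labels <- function(species, gene_id, chromosome = NULL) {
  if (is.null(chromosome)) paste(species, gene_id, sep = "|")
  else paste(species, gene_id, chromosome, sep = "|")
}

#' @rdname make_leaf_labels
#' @param labels labels to parse.
#' @return `parse_leaf_labels`: data.frame with `species`, `gene_id`,
#'   `chromosome`.
#' @export
parse_leaf_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  data.frame(
    species = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
    chromosome = vapply(parts, function(p) if (length(p) > 2L) p[3L] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Write a tree as Newick with integer supports
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
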