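test_that("protein distances follow the closed forms and flag saturation", {
  aln <- protein_alignment(c(a = "AAAAAAAAAA", b = "AAAAACCCCC"))
  D <- protein_distance_matrix(aln, correction = "none")
  expect_equal(D["a", "b"], 0.5)
  Dk <- protein_distance_matrix(aln, correction = "kimura")
  expect_equal(Dk["a", "b"], -log(0.45), tolerance = 1e-12)

  ident <- protein_alignment(c(a = "ACDEF", b = "ACDEF"))
  expect_equal(protein_distance_matrix(ident, "kimura")["a", "b"], 0)
  expect_equal(protein_distance_matrix(ident, "none")["a", "b"], 0)

  expect_equal(kimura_correction(0.5), 0.79850769621777, tolerance = 1e-10)
  # saturation boundary: the positive root of 1 - p - 0.2 p^2
  p_star <- (sqrt(1.8) - 1) / 0.4
  expect_equal(p_star, 0.854101966249685, tolerance = 1e-12)
  expect_error(kimura_correction(p_star), "saturated")
  expect_silent(kimura_correction(p_star - 1e-6))

  gappy <- protein_alignment(c(a = "AC---", b = "--DEF"))
  expect_error(protein_distance_matrix(gappy), "ungapped")
})

test_that("neighbor joining solves the three-taxon case exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl, c(A = 0.5, B = 1.5, C = 2.5))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  Dasym <- D; Dasym[1, 2] <- 2.5
  expect_error(neighbor_joining(Dasym), "asymmetric")
})

test_that("neighbor joining recovers a four-taxon additive tree exactly", {
  phy <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- stats::cophenetic(phy)[LETTERS[1:4], LETTERS[1:4]]
  tr <- neighbor_joining(D)
  # split AB|CD present, and path lengths reproduce D exactly
  expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  P <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(P - D)), 1e-9)
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(2025)
  for (i in 1:30) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- neighbor_joining(case$D)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    labs <- rownames(case$D)
    P <- stats::cophenetic(tr)[labs, labs]
    expect_lt(max(abs(P - case$D)), 1e-9)
  }
})

test_that("tied distance matrices resolve deterministically", {
  n <- 5
  D <- matrix(1, n, n) - diag(n)
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
})

test_that("bootstrap supports behave at the extremes and are seed-stable", {
  set.seed(9)
  base <- random_protein(60)
  twin <- base
  others <- vapply(1:3, function(i) random_protein(60), "")
  aln <- protein_alignment(c(p = base, q = twin,
                             r = others[1], s = others[2], t = others[3]))
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 5,
                          correction = "none")
  # the identical pair's bipartition survives every replicate
  sets <- paralogon:::.clade_tip_sets(tr)
  ntip <- length(tr$tip.label)
  pq_support <- NA
  for (v in (ntip + 1):(ntip + tr$Nnode)) {
    if (setequal(sets[[v]], c("p", "q")))
      pq_support <- tr$node.label[v - ntip]
  }
  expect_equal(pq_support, "100")

  t0 <- bootstrap_support(aln, n_replicates = 0, seed = 5)
  expect_null(t0$node.label)

  ta <- bootstrap_support(aln, n_replicates = 30, seed = 7)
  tb <- bootstrap_support(aln, n_replicates = 30, seed = 7)
  expect_identical(ta$node.label, tb$node.label)
  expect_error(bootstrap_support(aln, -1), "negative")
})

test_that("bootstrap support is non-decreasing when clade signal columns are duplicated", {
  set.seed(13)
  block <- c(p = "AAAAAAAA", q = "AAAAAAAA", r = "CCCCCCCC",
             s = "DDDDDDDD", t = "EEEEEEEE")
  noise <- setNames(vapply(1:5, function(i) random_protein(30), ""),
                    names(block))
  a1 <- protein_alignment(paste0(block, noise) |> setNames(names(block)))
  a2 <- protein_alignment(paste0(block, block, noise) |>
                            setNames(names(block)))
  support_pq <- function(tr) {
    sets <- paralogon:::.clade_tip_sets(tr)
    ntip <- length(tr$tip.label)
    for (v in (ntip + 1):(ntip + tr$Nnode))
      if (setequal(sets[[v]], c("p", "q")))
        return(as.integer(tr$node.label[v - ntip]))
    NA_integer_
  }
  s1 <- support_pq(bootstrap_support(a1, 40, seed = 3, correction = "none"))
  s2 <- support_pq(bootstrap_support(a2, 40, seed = 3, correction = "none"))
  expect_false(is.na(s1))
  expect_gte(s2, s1)
  expect_true(all(c(s1, s2) >= 0 & c(s1, s2) <= 100))
})

test_that("outgroup rooting places the root on the outgroup edge and rejects invalid sides", {
  tr <- ape::read.tree(text = "(A:1,B:1,(C:1,D:1):1);")
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "A") %in% root_children)
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")), "whole leaf")
  expect_error(root_with_outgroup(tr, c("A", "C")), "bipartition")
})

test_that("species-overlap annotation distinguishes duplication from speciation", {
  tr <- ape::read.tree(text = "((human_A:1,fish_A:1):1,(human_B:1,fish_B:1):1);")
  ann <- annotate_duplications(tr)
  # root = duplication (both children contain human and fish); children speciations
  expect_equal(ann$node.annotation, c("duplication", "speciation",
                                      "speciation"))
  tr2 <- ape::read.tree(text = "((human_A:1,human_B:1):1,fish_A:1);")
  ann2 <- annotate_duplications(tr2)
  expect_equal(ann2$node.annotation[2], "duplication")
  expect_equal(ann2$node.annotation[1], "speciation")
  expect_error(annotate_duplications(ape::read.tree(text = "(a:1,b:1,c:1);")),
               "rooted")
})

test_that("relative dating labels duplications before, after, or unresolved", {
  tr <- ape::read.tree(text = "((human_A:1,fish_A:1):1,(human_B:1,fish_B:1):1);")
  ann <- annotate_duplications(tr)
  d <- relative_dating(ann, split = list("human", "fish"))
  expect_equal(d$dating, "before_split")

  tr2 <- ape::read.tree(text = "((fish_A1:1,fish_A2:1):1,human_A:1);")
  d2 <- relative_dating(annotate_duplications(tr2),
                        split = list("human", "fish"))
  expect_equal(d2$dating, "after_split")

  # loss emptied fish from one child clade: unresolved
  tr3 <- ape::read.tree(text = "((human_A:1,fish_A:1):1,human_B:1);")
  d3 <- relative_dating(annotate_duplications(tr3),
                        split = list("human", "fish"))
  expect_equal(d3$dating, "unresolved")

  expect_error(relative_dating(ann, split = list("human", "mouse")),
               "absent from the tree")
  expect_error(relative_dating(tr, split = list("human", "fish")),
               "annotation")
})

test_that("simulated pre-split duplications are recovered as before_split", {
  hits <- 0L
  for (i in 1:25) {
    case <- simulate_dating_case(1000 + i)
    expect_true("duplication" %in% case$tree$node.annotation)
    if (any(case$dating$dating == "before_split")) hits <- hits + 1L
    expect_false(any(case$dating$dating == "after_split"))
  }
  expect_gte(hits / 25, 0.95)
  # with a loss: degradation to unresolved allowed, never after_split
  for (i in 1:10) {
    case <- simulate_dating_case(2000 + i, with_loss = TRUE)
    expect_false(any(case$dating$dating == "after_split"))
  }
})

test_that("leaf labels round-trip through the species|gene|chromosome convention", {
  labs <- make_leaf_labels(c("human", "fish"), c("g1", "g2"),
                           c("chr2", "chr6"))
  parsed <- parse_leaf_labels(labs)
  expect_equal(parsed$species, c("human", "fish"))
  expect_equal(parsed$gene_id, c("g1", "g2"))
  expect_equal(parsed$chromosome, c("chr2", "chr6"))
  expect_equal(leaf_species(labs), c("human", "fish"))
  expect_equal(leaf_species("human_A"), "human")
})
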