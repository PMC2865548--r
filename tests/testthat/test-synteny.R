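toy_table <- function() {
  as_gene_table(data.frame(
    gene_id = paste0("g", 1:8),
    species = "sp",
    chromosome = c("c2", "c2", "c3", "c3", "c20", "c23", "c2", "c3"),
    start = c(41940000, 113660000, 5e6, 9e6, 1e6, 2e6, 5e7, 7e6),
    end   = c(41941000, 113661000, 5.001e6, 9.001e6, 1.001e6, 2.001e6,
              5.0001e7, 7.001e6),
    strand = "+",
    family_id = c("fam1", "fam2", "fam1", "fam1", "fam1", "fam1",
                  "fam2", "fam2"),
    stringsAsFactors = FALSE))
}

test_that("anchor regions span min-to-max plus flank, clipped at zero", {
  anchors <- as_gene_table(data.frame(
    gene_id = c("a1", "a2"), species = "sp", chromosome = "c2",
    start = c(5.0e7, 5.9e7), end = c(5.01e7, 6.0e7), strand = "+",
    family_id = "f", stringsAsFactors = FALSE))
  r <- region_from_anchors(anchors, flank = 1e7)
  expect_equal(c(r$start, r$end), c(4.0e7, 7.0e7))
  r0 <- region_from_anchors(anchors, flank = 0)
  expect_equal(c(r0$start, r0$end), c(5.0e7, 6.0e7))
  near0 <- anchors; near0$start <- c(4e6, 5e6); near0$end <- c(4.1e6, 5.1e6)
  rc <- region_from_anchors(near0, flank = 1e7)
  expect_equal(rc$start, 0)
  mixed <- anchors; mixed$chromosome <- c("c2", "c3")
  expect_error(region_from_anchors(mixed, 1e7), "different chromosomes")
  expect_error(region_from_anchors(anchors[0, ], 1e7), "empty")
})

test_that("family presence respects half-open windows and whole chromosomes", {
  tab <- toy_table()
  regions <- list(genomic_region("c2", 41940000, 113660000),
                  genomic_region("c3", 0, 1e7),
                  genomic_region("c20", whole_chromosome = TRUE),
                  genomic_region("c23", whole_chromosome = TRUE))
  pres <- family_presence(tab, regions)
  # g1 at exactly 41.94 Mb included; g2 at exactly 113.66 Mb excluded
  expect_equal(pres$counts["fam1", "c2"], 1L)
  expect_equal(pres$counts["fam2", "c2"], 1L)   # g7 only, g2 on boundary out
  expect_equal(pres$counts["fam1", "c3"], 2L)
  expect_equal(pres$counts["fam1", "c20"], 1L)
  expect_equal(pres$counts["fam1", "c23"], 1L)
  # membership invariant under row shuffling
  set.seed(1)
  pres2 <- family_presence(tab[sample(nrow(tab)), ], regions)
  expect_equal(pres2$counts, pres$counts)
  expect_error(family_presence(tab, list(genomic_region("c99", 0, 10))),
               "absent")
})

test_that("family selection applies the >= 3 chromosomes rule monotonically", {
  tab <- toy_table()
  regions <- lapply(c("c2", "c3", "c20", "c23"), function(ch)
    genomic_region(ch, whole_chromosome = TRUE))
  pres <- family_presence(tab, regions)
  expect_equal(select_families(pres, 3), "fam1")   # fam1 on c2,c3,c20,c23
  expect_equal(select_families(pres, 5), character(0))
  s3 <- select_families(pres, 3)
  s4 <- select_families(pres, 4)
  expect_true(all(s4 %in% s3))
})

test_that("quartet completeness counts families on all four chromosomes", {
  counts <- matrix(0L, 6, 4,
                   dimnames = list(paste0("f", 1:6), paste0("c", 1:4)))
  n_chr <- c(4, 4, 3, 3, 2, 4)
  for (i in 1:6) counts[i, seq_len(n_chr[i])] <- 1L
  pres <- structure(list(counts = counts, candidates = paste0("c", 1:4)),
                    class = "family_presence")
  qt <- quartet_completeness(rownames(counts), pres)
  expect_equal(attr(qt, "n_full"), 3L)
  expect_equal(qt$full_quartet, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  pres3 <- structure(list(counts = counts[, 1:3],
                          candidates = paste0("c", 1:3)),
                     class = "family_presence")
  expect_warning(quartet_completeness(rownames(counts), pres3),
                 "quartet flag")
})

test_that("planted 2R paralogons are recovered exactly (sensitivity and specificity 1)", {
  for (seed in 1:5) {
    retention <- 0.3 + 0.5 * (seed - 1) / 4
    case <- simulate_paralogon_case(seed, retention)
    sel <- run_family_selection(case)$selected
    expect_identical(sel, case$truth_selected)
    # families from other ancestral chromosomes never appear
    expect_true(all(grepl("^f(0[1-9]|1[0-9]|20)$", sel)))
  }
})

test_that("a translocation can only remove a family from the selected set", {
  case <- simulate_paralogon_case(101, 0.8)
  before <- run_family_selection(case)
  sel <- before$selected
  expect_gt(length(sel), 0)
  fam <- sel[1]
  g <- case$genome
  victim <- g$genes[g$genes$family_id == fam &
                    g$genes$chromosome %in% case$candidates, ][1, ]
  moved <- apply_translocation(g, victim$chromosome,
                               c(victim$start, victim$end), "chr2")
  case2 <- case; case2$genome <- moved
  after <- run_family_selection(case2)$selected
  expect_true(all(after %in% sel))           # nothing new appears
  expect_true(all(setdiff(sel, after) == fam))
})

test_that("synteny tables place genes by reference linkage and round-trip through TSV", {
  tree <- tree_node("root", length = 0,
    events = list(list(type = "wgd", label = "R1")),
    children = list(tree_node("spA", length = 0.02),
                    tree_node("spB", length = 0.02)))
  sim <- simulate_history(simulation_config(7, 1, 4, tree,
                                            sequence_length = 30))
  tabs <- lapply(sim$genomes, function(g) g$genes)
  ids <- unique(unlist(lapply(tabs, function(t) t$gene_id)))
  groups <- lapply(ids, identity)
  pt <- build_synteny_table(tabs, groups, reference_species = "spA")
  expect_setequal(names(pt), c("spA", "spB"))
  # no translocations: every gene lands in the column of its own chromosome
  for (sp in names(pt)) {
    df <- pt[[sp]]
    for (col in attr(df, "reference_chromosomes")) {
      cells <- unlist(strsplit(df[[col]][nzchar(df[[col]])], ","))
      tab <- tabs[[sp]]
      expect_true(all(tab$chromosome[match(cells, tab$gene_id)] == col))
    }
  }
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_paralogon_table(pt$spA, tf)
  back <- read_paralogon_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(pt$spA),
               ignore_attr = TRUE)
  expect_equal(attr(back, "reference_chromosomes"),
               attr(pt$spA, "reference_chromosomes"))
  expect_error(build_synteny_table(tabs, list("nonexistent-gene"), "spA"),
               "missing from tables")
})
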