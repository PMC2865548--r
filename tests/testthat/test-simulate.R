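test_that("ancestral genome construction plants cassettes exactly and is deterministic", {
  g <- make_ancestral_genome(1, 3, seed = 7)
  expect_equal(nrow(g$genes), 3L)
  expect_equal(length(unique(g$genes$family_id)), 3L)
  ord <- g$genes[order(g$genes$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-3]))

  g2 <- make_ancestral_genome(2, 5, cassette_spec("YGGFM", 7), seed = 1)
  root <- g2$sequences[["f01.1"]]
  n_hits <- length(gregexpr("YGGFM", root, fixed = TRUE)[[1]])
  expect_equal(n_hits, 7L)

  ga <- make_ancestral_genome(2, 4, seed = 11)
  gb <- make_ancestral_genome(2, 4, seed = 11)
  gc <- make_ancestral_genome(2, 4, seed = 12)
  expect_identical(ga$sequences, gb$sequences)
  expect_false(identical(ga$sequences, gc$sequences))

  expect_error(make_ancestral_genome(0, 3), "positive")
})

test_that("whole-genome duplication doubles genes and chromosomes with co-orthologs", {
  g <- make_ancestral_genome(1, 3, seed = 2)
  d1 <- apply_wgd(g, "R1")
  expect_equal(nrow(d1$genes), 6L)
  expect_equal(length(d1$chromosome_lengths), 2L)
  expect_equal(length(d1$log), length(g$log) + 1L)
  # homologous coordinates on the duplicated chromosome
  orig <- d1$genes[d1$genes$chromosome == "chr1", ]
  dup <- d1$genes[d1$genes$chromosome == "chr1-R1", ]
  expect_equal(dup$start, orig$start)

  d2 <- apply_wgd(d1, "R2")
  per_family <- table(d2$genes$family_id)
  expect_true(all(per_family == 4L))
  for (f in names(per_family)) {
    chrs <- d2$genes$chromosome[d2$genes$family_id == f]
    expect_equal(length(unique(chrs)), 4L)
  }
  expect_error(apply_wgd(delete_genes(g, g$genes$gene_id)), "empty")
})

test_that("stochastic loss respects the retention probability (binomial SE)", {
  g <- make_ancestral_genome(10, 1000, seed = 3, gene_spacing = 5000,
                             gene_width = 1000, sequence_length = 10)
  expect_equal(nrow(g$genes), 10000L)
  kept <- apply_losses(g, 1, seed = 5)
  expect_equal(nrow(kept$genes), 10000L)
  none <- apply_losses(g, 0, seed = 5)
  expect_equal(nrow(none$genes), 0L)
  p <- 0.6
  lost <- apply_losses(g, p, seed = 17)
  frac <- nrow(lost$genes) / 10000
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(apply_losses(g, 1.2), "\\[0, 1\\]")
})

test_that("local duplication creates an adjacent same-family pair within the offset", {
  g <- make_ancestral_genome(1, 3, seed = 4)
  gid <- g$genes$gene_id[1]
  d <- apply_local_duplication(g, gid, offset = 50000)
  fam <- g$genes$family_id[1]
  members <- d$genes[d$genes$family_id == fam, ]
  expect_equal(nrow(members), 2L)
  expect_equal(length(unique(members$chromosome)), 1L)
  members <- members[order(members$start), ]
  expect_lte(members$start[2] - members$end[1], 50000)
  # downstream neighbors shifted, no overlap
  expect_silent(as_gene_table(d$genes))
  expect_error(apply_local_duplication(g, "no-such-gene"), "unknown gene")
})

test_that("translocation moves exactly the targeted block and preserves counts", {
  g <- make_ancestral_genome(2, 4, seed = 5)
  src <- g$genes[g$genes$chromosome == "chr1", ]
  src <- src[order(src$start), ]
  iv <- c(src$start[2], src$start[3] + 1)      # genes 2 and 3
  d <- apply_translocation(g, "chr1", iv, "chr2")
  moved <- d$genes[d$genes$gene_id %in% src$gene_id[2:3], ]
  expect_true(all(moved$chromosome == "chr2"))
  moved <- moved[order(moved$start), ]
  expect_equal(moved$gene_id, src$gene_id[2:3])  # order preserved
  expect_equal(nrow(d$genes), nrow(g$genes))

  # interval with no genes: table unchanged, event still logged
  d0 <- apply_translocation(g, "chr1", c(1, 2), "chr2")
  expect_equal(d0$genes, g$genes)
  expect_equal(length(d0$log), length(g$log) + 1L)
  expect_error(apply_translocation(g, "chrX", c(0, 1), "chr2"),
               "unknown chromosome")
})

test_that("sequence evolution is Poisson with the requested mean and honors protection", {
  seqs <- c(s1 = random_protein(1000))
  same <- evolve_sequences(seqs, 0, seed = 1)
  expect_equal(as.character(same), as.character(seqs), ignore_attr = TRUE)

  counts <- vapply(1:500, function(i) {
    attr(evolve_sequences(seqs, 0.1, seed = i), "n_events")[["s1"]]
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 500))

  g <- make_ancestral_genome(1, 2, cassette_spec("YGGFM", 5), seed = 9)
  ev <- evolve_sequences(g$sequences, 0.5, seed = 3,
                         protected_sites = g$protected_sites)
  n_hits <- length(gregexpr("YGGFM", ev[["f01.1"]], fixed = TRUE)[[1]])
  expect_equal(n_hits, 5L)
  expect_error(evolve_sequences(seqs, -0.1), ">= 0")
})

test_that("a between-WGD tandem duplication history yields the expected extant repertoire", {
  tree <- tree_node("sp", length = 0, events = list(
    list(type = "wgd", label = "R1"),
    list(type = "local_dup", family = "f01"),
    list(type = "wgd", label = "R2"),
    list(type = "loss_genes", genes = c("f01.1-td-R2", "f01.1-R1-R2"))))
  cfg <- simulation_config(1, 1, 1, tree, sequence_length = 30)
  sim <- simulate_history(cfg)
  g <- sim$genomes$sp
  expect_equal(nrow(g$genes), 4L)
  expect_equal(length(unique(g$genes$chromosome)), 3L)
  # one adjacent same-family pair on the original chromosome
  on1 <- g$genes[g$genes$chromosome == "chr1", ]
  expect_equal(nrow(on1), 2L)
  # one paralogous chromosome left empty
  empty <- setdiff(names(g$chromosome_lengths), unique(g$genes$chromosome))
  expect_equal(empty, "chr1-R1-R2")
})

test_that("a teleost branch with an extra WGD doubles its chromosome count", {
  tree <- tree_node("root", length = 0.01,
    events = list(list(type = "wgd", label = "R1")),
    children = list(
      tree_node("fish", length = 0.01,
                events = list(list(type = "wgd", label = "3R"))),
      tree_node("tetrapod", length = 0.01)))
  sim <- simulate_history(simulation_config(5, 2, 2, tree,
                                            sequence_length = 30))
  expect_equal(length(sim$genomes$fish$chromosome_lengths),
               2L * length(sim$genomes$tetrapod$chromosome_lengths))
})

test_that("simulated histories are reproducible and the truth log replays exactly", {
  cfg <- simulation_config(99, 2, 3, tree_node("sp", length = 0.1,
    events = list(list(type = "wgd", label = "R1"),
                  list(type = "loss", retention = 0.7))),
    sequence_length = 50)
  a <- simulate_history(cfg)
  b <- simulate_history(cfg)
  expect_identical(a$genomes$sp$genes, b$genomes$sp$genes)
  expect_identical(as.character(a$genomes$sp$sequences),
                   as.character(b$genomes$sp$sequences))

  # 50 random configurations: replaying each leaf's lineage log from the
  # ancestor reproduces the extant genome exactly
  set.seed(123)
  for (rep in 1:50) {
    events <- list(list(type = "wgd", label = "R1"))
    if (runif(1) < 0.5)
      events <- c(events, list(list(type = "local_dup", family = "f01")))
    if (runif(1) < 0.7)
      events <- c(events, list(list(type = "loss",
                                    retention = runif(1, 0.4, 0.9))))
    tree <- tree_node("root", length = runif(1, 0, 0.2), events = events,
                      children = list(
                        tree_node("sp1", length = runif(1, 0, 0.2)),
                        tree_node("sp2", length = runif(1, 0, 0.2))))
    cfg <- simulation_config(sample.int(1e6, 1), sample(1:2, 1),
                             sample(2:4, 1), tree, sequence_length = 40)
    sim <- simulate_history(cfg)
    for (sp in names(sim$genomes)) {
      replayed <- replay_log(sim$ancestor, sim$genomes[[sp]]$log)
      expect_identical(replayed$genes, sim$genomes[[sp]]$genes)
      expect_identical(as.character(replayed$sequences),
                       as.character(sim$genomes[[sp]]$sequences))
      expect_identical(replayed$chromosome_lengths,
                       sim$genomes[[sp]]$chromosome_lengths)
    }
  }
})

test_that("gene table and truth log round-trip through TSV", {
  g <- make_ancestral_genome(2, 3, seed = 8)
  d <- apply_losses(apply_wgd(g, "R1"), 0.8, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(d$genes, tf)
  back <- read_gene_table(tf)
  expect_equal(back, d$genes)
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_truth_log(d$log, lf)
  lines <- readLines(lf)
  expect_equal(length(lines), length(d$log) + 1L)
  expect_match(lines[1], "kind\tbranch")
})
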