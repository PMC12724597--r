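# Species-tree, coding-evolution, population-sample and locus-history
# simulators, including the truth-log replay oracle.

test_that("species trees are rooted, binary, ultrametric and deterministic", {
  tr <- generate_species_tree(3, 1, seed = 7)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-9)

  t1 <- ape::write.tree(generate_species_tree(8, 1, seed = 7))
  t2 <- ape::write.tree(generate_species_tree(8, 1, seed = 7))
  expect_identical(t1, t2)

  # a rooted binary tree on n tips has 2n-2 edges and n-1 internal nodes
  tr23 <- generate_species_tree(23, 1, seed = 99)
  expect_equal(nrow(tr23$edge), 2 * 23 - 2)
  expect_equal(tr23$Nnode, 22L)

  expect_error(generate_species_tree(2, 1, 1), "n_taxa")
})

test_that("coding evolution: no time means no change; omega 0 means all-synonymous", {
  set.seed(5)
  cds <- backtranslate(rand_protein(200))
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  res0 <- simulate_coding_evolution(tr0, cds, omega = 1, seed = 3)
  expect_identical(unname(res0$cds[["a"]]), cds)
  expect_identical(unname(res0$cds[["b"]]), cds)

  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  res <- simulate_coding_evolution(tr, cds, omega = 0, seed = 3)
  expect_gt(res$n_syn, 0)
  expect_equal(res$n_nonsyn, 0)
  # every fixed difference between the two tips is synonymous
  a <- strsplit(res$cds[["a"]], "")[[1]]; b <- strsplit(res$cds[["b"]], "")[[1]]
  diffs <- which(a != b)
  for (p in diffs) {
    ci <- (p - 1) %/% 3
    expect_equal(aa_of(paste(a[(3*ci+1):(3*ci+3)], collapse = "")),
                 aa_of(paste(b[(3*ci+1):(3*ci+3)], collapse = "")))
  }
  expect_error(simulate_coding_evolution(tr, "ATGTGAAAA", seed = 1),
               "stop")
})

test_that("neutral coding evolution matches the mutation-opportunity oracle", {
  # enumerate all single-nucleotide mutations of the root CDS, excluding
  # those that create stops, and count the nonsynonymous fraction; under
  # omega = 1, kappa = 1 the realized nonsynonymous fraction must match
  set.seed(6)
  cds <- backtranslate(rand_protein(150))
  ch <- strsplit(cds, "")[[1]]
  n_n <- 0; n_s <- 0
  for (p in seq_along(ch)) for (b in setdiff(BASES, ch[p])) {
    ci <- (p - 1) %/% 3
    cod <- ch[(3*ci+1):(3*ci+3)]
    newcod <- cod; newcod[(p - 1) %% 3 + 1] <- b
    a2 <- aa_of(paste(newcod, collapse = ""))
    if (a2 == "*") next
    if (a2 == aa_of(paste(cod, collapse = ""))) n_s <- n_s + 1 else n_n <- n_n + 1
  }
  frac_oracle <- n_n / (n_n + n_s)
  tot_n <- 0; tot <- 0
  for (r in 1:200) {
    tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
    res <- simulate_coding_evolution(tr, cds, omega = 1, kappa = 1,
                                     seed = 100 + r)
    tot_n <- tot_n + res$n_nonsyn
    tot <- tot + res$n_nonsyn + res$n_syn
  }
  frac <- tot_n / tot
  se <- sqrt(frac_oracle * (1 - frac_oracle) / tot)
  expect_lt(abs(frac - frac_oracle), 4 * se)
})

test_that("population samples: theta 0 identity, Watterson expectation, determinism", {
  set.seed(8)
  cds <- backtranslate(rand_protein(120))
  pop0 <- simulate_population_sample(cds, theta = 0, n_strains = 5, seed = 2)
  expect_true(all(pop0 == cds))
  expect_error(simulate_population_sample(cds, 1, 1, 1), "n_strains")

  # n = 2, theta = 1: a_2 = 1, so E[S] = 1; mean over replicates within 3 SE
  S <- vapply(1:1000, function(r) {
    pop <- simulate_population_sample(cds, theta = 1, n_strains = 2,
                                      seed = 4000 + r)
    a <- strsplit(pop[[1]], "")[[1]]; b <- strsplit(pop[[2]], "")[[1]]
    sum(a != b)
  }, numeric(1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 1), 3 * se)

  p1 <- simulate_population_sample(cds, 5, 6, seed = 77)
  p2 <- simulate_population_sample(cds, 5, 6, seed = 77)
  expect_identical(p1, p2)
})

test_that("an event-free history leaves every species with the ancestral context", {
  rates0 <- list(relocation = 0, dup_alt_retention = 0, dup_coretention = 0,
                 tandem_dup = 0, pseudogenization = 0,
                 neighbor_acquisition = 0)
  tr <- generate_species_tree(5, 1, seed = 3)
  h <- simulate_locus_history(tr, sim_config(seed = 5, event_rates = rates0,
                                             te_insertion_rate = 0))
  expect_equal(nrow(h$truth$events), 0L)
  for (sp in names(h$genomes)) {
    gt <- genes_table(h$genomes[[sp]])
    foc <- gt[gt$is_focal, ]
    expect_equal(nrow(foc), 1L)
    expect_equal(foc$contig, "c1")
    expect_equal(foc$order_index, 4L)  # three neighbors on each side
  }
})

test_that("a realized tandem duplication yields adjacent near-identical copies", {
  rates <- list(relocation = 0, dup_alt_retention = 0, dup_coretention = 0,
                tandem_dup = 0.5, pseudogenization = 0,
                neighbor_acquisition = 0)
  tr <- generate_species_tree(4, 1, seed = 9, height = 0.02)
  h <- simulate_locus_history(tr, sim_config(seed = 21, event_rates = rates))
  tand <- h$truth$events[h$truth$events$type == "tandem_dup", ]
  expect_gt(nrow(tand), 0)
  sp <- strsplit(tand$clade[1], ",")[[1]][1]
  gt <- genes_table(h$genomes[[sp]])
  foc <- gt[gt$is_focal & gt$status == "intact", ]
  expect_gte(nrow(foc), 2)
  idx <- sort(foc$order_index[foc$contig == foc$contig[1]])
  expect_true(any(diff(idx) == 1))
  g <- h$genomes[[sp]]
  ident <- percent_identity(g$genes[[foc$gene_id[1]]]$seq,
                            g$genes[[foc$gene_id[2]]]$seq)
  expect_gt(ident, 97)
})

test_that("replaying the truth log reproduces the extant genomes exactly", {
  for (s in c(101, 202, 303)) {
    tr <- generate_species_tree(10, 1, seed = s)
    h <- simulate_locus_history(tr, sim_config(seed = s + 1))
    rp <- replay_truth(h$truth)
    for (sp in names(h$genomes))
      expect_identical(emit_genome(rp[[sp]]), emit_genome(h$genomes[[sp]]))
  }
})

test_that("vestige law: decay 0 keeps all vestiges, huge decay removes them", {
  rates <- list(relocation = 0, dup_alt_retention = 0.3, dup_coretention = 0,
                tandem_dup = 0, pseudogenization = 0,
                neighbor_acquisition = 0)
  tr <- generate_species_tree(8, 1, seed = 4)
  h0 <- simulate_locus_history(tr, sim_config(seed = 31, event_rates = rates,
                                              vestige_decay_rate = 0))
  ev <- h0$truth$events
  expect_gt(sum(ev$type == "dup_alt_retention"), 0)
  expect_equal(sum(ev$type == "vestige_deletion"), 0L)
  # every source vestige survives in every descendant
  for (i in which(ev$type == "dup_alt_retention")) {
    for (sp in strsplit(ev$clade[i], ",")[[1]]) {
      gt <- genes_table(h0$genomes[[sp]])
      expect_true(ev$src_gene[i] %in% gt$gene_id[gt$status == "pseudogene"])
    }
  }
  h1 <- simulate_locus_history(tr, sim_config(seed = 31, event_rates = rates,
                                              vestige_decay_rate = 1e6))
  for (sp in names(h1$genomes)) {
    gt <- genes_table(h1$genomes[[sp]])
    expect_equal(sum(gt$is_focal & gt$status == "pseudogene"), 0L)
  }
})

test_that("no emitted intact CDS contains an internal stop codon", {
  tr <- generate_species_tree(8, 1, seed = 12)
  h <- simulate_locus_history(tr, sim_config(seed = 13))
  cds <- focal_alignment(h)
  for (s in cds) {
    aa <- translate0(s)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("identical configuration gives byte-identical fixtures", {
  tr <- generate_species_tree(5, 1, seed = 17)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(simulate_locus_history(tr, sim_config(seed = 19)), d1)
  write_fixture(simulate_locus_history(tr, sim_config(seed = 19)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("fixture round trip reproduces the emitted objects and valid GFF3", {
  tr <- generate_species_tree(5, 1, seed = 23)
  h <- simulate_locus_history(tr, sim_config(seed = 29))
  d <- file.path(tempdir(), "fx_rt")
  write_fixture(h, d)
  back <- read_fixture(d)
  for (sp in names(h$genomes)) {
    em <- emit_genome(h$genomes[[sp]])
    expect_identical(back$genomes[[sp]]$contigs, em$contigs)
    expect_equal(back$genomes[[sp]]$genes$start, em$genes$start)
    expect_equal(back$genomes[[sp]]$genes$gene_id, em$genes$gene_id)
    expect_equal(back$genomes[[sp]]$genes$status, em$genes$status)
  }
  expect_equal(ape::Ntip(back$tree), 5)
  # GFF3 rows are 1-based inclusive with start <= end and start >= 1
  for (sp in names(h$genomes)) {
    ln <- readLines(file.path(d, paste0(sp, ".gff3")))
    ln <- ln[!grepl("^#", ln)]
    f <- do.call(rbind, strsplit(ln, "\t"))
    st <- as.integer(f[, 4]); en <- as.integer(f[, 5])
    expect_true(all(st >= 1))
    expect_true(all(st <= en))
  }
  # an event-free fixture has one gene row per gene per species
  rates0 <- list(relocation = 0, dup_alt_retention = 0, dup_coretention = 0,
                 tandem_dup = 0, pseudogenization = 0,
                 neighbor_acquisition = 0)
  h0 <- simulate_locus_history(generate_species_tree(4, 1, seed = 2),
                               sim_config(seed = 3, event_rates = rates0,
                                          te_insertion_rate = 0))
  d0 <- file.path(tempdir(), "fx0")
  write_fixture(h0, d0)
  n_genes <- nrow(genes_table(h0$genomes[[1]]))
  for (sp in names(h0$genomes)) {
    ln <- readLines(file.path(d0, paste0(sp, ".gff3")))
    expect_equal(sum(grepl("\tgene\t", ln)), n_genes)
  }
})

test_that("event rates implying more than one structural event per branch are rejected", {
  expect_error(sim_config(event_rates = list(
    relocation = 0.5, dup_alt_retention = 0.4, dup_coretention = 0.2,
    tandem_dup = 0, pseudogenization = 0, neighbor_acquisition = 0)),
    "unidentifiable")
  expect_error(sim_config(event_rates = list(
    relocation = -0.1, dup_alt_retention = 0, dup_coretention = 0,
    tandem_dup = 0, pseudogenization = 0, neighbor_acquisition = 0)),
    "rates")
})
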