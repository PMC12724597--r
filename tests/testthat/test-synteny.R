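# Locus contexts, clustering, Dollo presence mapping and event inference.

mk_table_df <- function(...) {
  # build a gene table from (species, contig, families...) triples
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    fams <- r[[3]]
    data.frame(species = r[[1]], contig = r[[2]], gene_family = fams,
               order_index = seq_along(fams),
               strand = rep("+", length(fams)),
               status = r[[4]] %||% rep("intact", length(fams)),
               gene_id = paste0(r[[1]], ":", r[[2]], ":", seq_along(fams)),
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

test_that("locus contexts list the k nearest neighbors per side", {
  gt <- mk_table_df(list("spA", "c1", c("CG1427", "Cenp-C", "5-HT2B"), NULL))
  cx <- extract_locus_context(gt, "spA:c1:2", k = 1, focal_family = "Cenp-C")
  expect_equal(cx$upstream$family, "CG1427")
  expect_equal(cx$downstream$family, "5-HT2B")
  expect_false(is.null(cx$signature))

  # focal first on the contig: upstream empty and edge-truncated
  gt2 <- mk_table_df(list("spA", "c1", c("Cenp-C", "g1", "g2", "g3"), NULL))
  cx2 <- extract_locus_context(gt2, "spA:c1:1", k = 2, focal_family = "Cenp-C")
  expect_equal(nrow(cx2$upstream), 0L)
  expect_true(cx2$edge_truncated)

  # k = 3 on a 7-gene contig with the focal in the middle
  gt3 <- mk_table_df(list("spA", "c1",
                          c("a", "b", "c", "Cenp-C", "d", "e", "f"), NULL))
  cx3 <- extract_locus_context(gt3, "spA:c1:4", k = 3, focal_family = "Cenp-C")
  expect_equal(cx3$upstream$family, c("c", "b", "a"))  # nearest first
  expect_equal(cx3$downstream$family, c("d", "e", "f"))
  expect_false(cx3$edge_truncated)

  expect_error(extract_locus_context(gt3, "nope", focal_family = "Cenp-C"),
               "not found")
})

test_that("clustering joins identical signatures and separates disjoint ones", {
  gt <- mk_table_df(
    list("spA", "c1", c("x", "y", "Cenp-C", "z"), NULL),
    list("spB", "c9", c("x", "y", "Cenp-C", "z"), NULL),
    list("spC", "c2", c("p", "q", "Cenp-C", "r"), NULL))
  cx <- extract_all_contexts(gt, focal_family = "Cenp-C")
  cl <- match_loci_across_species(cx)
  expect_equal(length(cl), 2L)
  sizes <- sort(vapply(cl, function(c2) length(c2$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
})

test_that("clustering is invariant to input permutation", {
  gt <- paper_contexts("full")
  cx <- extract_all_contexts(gt, focal_family = "Cenp-C")
  cl1 <- match_loci_across_species(cx)
  set.seed(1)
  perm <- sample(length(cx))
  cxp <- cx[perm]
  cl2 <- match_loci_across_species(cxp)
  part1 <- lapply(cl1, function(c2) sort(vapply(c2$members, function(i)
    paste(cx[[i]]$species, cx[[i]]$gene_id), character(1))))
  part2 <- lapply(cl2, function(c2) sort(vapply(c2$members, function(i)
    paste(cxp[[i]]$species, cxp[[i]]$gene_id), character(1))))
  expect_setequal(part1, part2)
})

test_that("the packaged fixture yields the five known focal-bearing loci", {
  gt <- paper_contexts("full")
  cx <- extract_all_contexts(gt, focal_family = "Cenp-C")
  cl <- match_loci_across_species(cx)
  sigs <- lapply(cl, `[[`, "sig_core")
  has <- function(fams) any(vapply(sigs, function(s) all(fams %in% s),
                                   logical(1)))
  expect_true(has(c("CG7785", "DNaseII")))
  expect_true(has(c("CG1427", "CG42497", "Tim10")))
  expect_true(has(c("CG9775", "5-HT2A")))
  expect_true(has("eIF3f1"))
  expect_true(has(c("atms", "CG14655")))
  pr <- locus_presence(gt, cx, cl, focal_family = "Cenp-C")
  expect_equal(count_focal_bearing_clusters(pr, montium_species()), 5L)
})

test_that("Dollo placement puts gains on carrier-MRCA stems with minimal losses", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pres <- matrix(FALSE, 4, 3, dimnames = list(c("A", "B", "C", "D"),
                                              c("all", "one", "pair")))
  pres[, "all"] <- TRUE
  pres["C", "one"] <- TRUE
  pres[c("A", "B"), "pair"] <- TRUE
  mp <- map_presence_on_tree(pres, tr)
  expect_identical(mp$all$gain, "root")
  expect_equal(length(mp$all$losses), 0L)
  expect_equal(mp$one$gain_clade, "C")
  expect_setequal(mp$pair$gain_clade, c("A", "B"))
  expect_equal(length(mp$pair$losses), 0L)
  # enumeration oracle: under a single gain, the chosen gain must minimize
  # the loss count over all possible gain placements covering the carriers
  expect_error(map_presence_on_tree(
    matrix(TRUE, 1, 1, dimnames = list("Z", "x")), tr), "missing")
})

test_that("no chronology contains a Dollo violation and event-free input is empty", {
  rates0 <- list(relocation = 0, dup_alt_retention = 0, dup_coretention = 0,
                 tandem_dup = 0, pseudogenization = 0,
                 neighbor_acquisition = 0)
  tr <- generate_species_tree(6, 1, seed = 41)
  h <- simulate_locus_history(tr, sim_config(seed = 42, event_rates = rates0))
  ch <- infer_history_events(h)
  expect_equal(length(ch$events), 0L)

  # on eventful histories, a cluster never gains on two incomparable branches
  for (s in 1:5) {
    tr <- generate_species_tree(12, 1, seed = 50 + s)
    h <- simulate_locus_history(tr, sim_config(seed = 60 + s))
    ch <- infer_history_events(h)
    dests <- vapply(ch$events, function(e)
      if (e$type %in% c("block_translocation", "single_gene_move_ambiguous",
                        "dup_alt_retention", "dup_coretention"))
        as.character(e$dest) else NA_character_, character(1))
    expect_false(any(duplicated(na.omit(dests))))
  }
})

test_that("the fig4 fixture reproduces the five-step chronology", {
  ch <- paper_chronology("fig4")
  types <- vapply(ch$events, `[[`, character(1), "type")
  # step 2: a single-gene move that cannot be typed
  amb <- ch$events[types == "single_gene_move_ambiguous"]
  expect_equal(length(amb), 1L)
  expect_setequal(amb[[1]]$clade,
                  c("D.triauraria", "D.auraria", "D.rufa", "D.pectinifera"))
  # step 3: a four-gene block translocation shared by five subgroups
  blk <- ch$events[types == "block_translocation"]
  expect_equal(length(blk), 1L)
  expect_equal(blk[[1]]$evidence$n_genes_comoved, 4L)
  expect_setequal(blk[[1]]$genes_moved,
                  c("Cenp-C", "CG1427", "CG42497", "Tim10"))
  expect_true("D.kanapiae" %in% blk[[1]]$clade)
  # step 4: duplication with alternate retention, evidenced by the
  # co-duplicated pseudogene at the new locus
  dar <- ch$events[types == "dup_alt_retention"]
  expect_equal(length(dar), 1L)
  expect_equal(dar[[1]]$clade, "D.kanapiae")
  expect_true(dar[[1]]$evidence$vestige_found)
  # step 5: co-retention of both paralogs
  cor <- ch$events[types == "dup_coretention"]
  expect_equal(length(cor), 1L)
  expect_equal(cor[[1]]$clade, "D.vulcana")
  expect_true(cor[[1]]$evidence$both_loci_occupied)
  # step 1: the two-gene neighbor acquisition at the ancestral locus
  acq <- ch$events[types == "neighbor_acquisition"]
  expect_equal(length(acq), 1L)
  expect_setequal(acq[[1]]$genes_moved, c("CG42497", "Tim10"))
  expect_equal(count_transposition_events(ch, montium_species()), 5L)
})

test_that("the full fixture adds the tandem pair and the undecidable fifth-locus move", {
  ch <- paper_chronology("full")
  types <- vapply(ch$events, `[[`, character(1), "type")
  tand <- ch$events[types == "tandem_dup"]
  expect_equal(length(tand), 1L)
  expect_equal(tand[[1]]$clade, "D.birchii")
  amb <- ch$events[types == "single_gene_move_ambiguous"]
  clades <- lapply(amb, `[[`, "clade")
  expect_true(any(vapply(clades, function(x) identical(x, "D.burlai"),
                         logical(1))))
})

test_that("event-record invariants hold on inferred chronologies", {
  ch <- paper_chronology("full")
  for (e in ch$events) {
    if (e$type == "single_gene_move_ambiguous") {
      expect_equal(e$evidence$n_genes_comoved, 1L)
      expect_false(e$evidence$vestige_found)
      expect_false(e$evidence$both_loci_occupied)
    }
    if (e$type == "dup_alt_retention")
      expect_true(e$evidence$vestige_found)
    if (e$type == "dup_coretention")
      expect_true(e$evidence$both_loci_occupied)
    if (e$type == "block_translocation")
      expect_gte(e$evidence$n_genes_comoved, 2L)
  }
})

test_that("tandem detection honors the adjacency and identity triggers", {
  gt <- mk_table_df(
    list("spA", "c1", c("a", "Cenp-C", "Cenp-C", "b"), NULL),
    list("spB", "c1", c("a", "Cenp-C", "b"), NULL))
  seqs <- list(spA = list("spA:c1:2" = strrep("ACGT", 100),
                          "spA:c1:3" = paste0(strrep("ACGT", 99), "ACGA")),
               spB = list())
  td <- find_tandem_copies(gt, seqs, focal_family = "Cenp-C")
  expect_equal(nrow(td), 1L)
  expect_equal(td$species, "spA")
  expect_gt(td$identity, 97)
  # below the identity threshold: no call
  seqs$spA[["spA:c1:3"]] <- paste0(strrep("ACGT", 80), rand_dna(80))
  td2 <- find_tandem_copies(gt, seqs, focal_family = "Cenp-C")
  expect_equal(nrow(td2), 0L)
})

test_that("intron retention is judged by shared projected intron positions", {
  ex1 <- list(exons = rbind(c(0, 300), c(400, 700), c(800, 1100)),
              strand = "+")
  ex2 <- list(exons = rbind(c(1000, 1300), c(1450, 1750), c(1900, 2200)),
              strand = "+")
  res <- check_intron_retention(list(a = ex1, b = ex2))
  expect_true(all(res$retained))
  expect_false(any(res$retro_like))

  # an intronless copy in a multi-intron family is retro-like
  ex3 <- list(exons = rbind(c(0, 900)), strand = "+")
  res2 <- check_intron_retention(list(a = ex1, b = ex2, c = ex3))
  expect_true(res2$retro_like[res2$copy == "c"])
  expect_false(res2$retained[res2$copy == "c"])

  # reverse-strand copies project through transcription order
  ex4 <- list(exons = rbind(c(100, 400), c(500, 800), c(900, 1200)),
              strand = "-")
  res3 <- check_intron_retention(list(a = ex1, d = ex4))
  expect_true(all(res3$retained))

  expect_error(check_intron_retention(list(a = ex3, b = ex3)), "undecidable")
})
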