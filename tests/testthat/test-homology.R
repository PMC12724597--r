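# Translated homology search, HSP chaining and gene-copy classification.

test_that("six-frame translation follows the reading-frame conventions", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(unname(fr[["+1"]]), "MK")
  # length-7 input: frames +1/+2 give 2 residues, +3 gives 1
  fr7 <- six_frame_translate("ATGAAAC")
  expect_equal(nchar(fr7[["+1"]]), 2L)
  expect_equal(nchar(fr7[["+2"]]), 2L)
  expect_equal(nchar(fr7[["+3"]]), 1L)
  # codons containing N translate to X
  expect_equal(unname(six_frame_translate("ATGNAA")[["+1"]]), "MX")
  expect_error(six_frame_translate("ATGQ"), "non-IUPAC")
})

test_that("frame -1 equals translation of the reverse complement", {
  set.seed(11)
  for (i in 1:5) {
    dna <- rand_dna(60)
    fr <- six_frame_translate(dna)
    expect_equal(unname(fr[["-1"]]), translate0(rc(dna)))
    expect_equal(unname(fr[["-2"]]), translate0(substring(rc(dna), 2)))
  }
})

test_that("a planted query is found as a single full-coverage perfect HSP", {
  set.seed(21)
  q <- rand_protein(60)
  contig <- paste0(rand_dna(150), backtranslate(q), rand_dna(150))
  hs <- search_protein_vs_contig(q, contig)
  top <- hs[1, ]
  expect_equal(top$query_start, 0)
  expect_equal(top$query_end, 60)
  expect_equal(top$percent_identity, 100)
  expect_equal(top$subject_end - top$subject_start, 180)
})

test_that("a planted query with every 10th residue substituted gives 90% identity", {
  set.seed(22)
  q <- rand_protein(100)
  qm <- strsplit(q, "")[[1]]
  for (i in seq(5, 95, by = 10))
    qm[i] <- setdiff(AA20, qm[i])[1]
  contig <- paste0(rand_dna(90), backtranslate(paste(qm, collapse = "")),
                   rand_dna(90))
  hs <- search_protein_vs_contig(q, contig)
  expect_equal(hs$percent_identity[1], 90)
})

test_that("seeded search equals the exhaustive local-alignment optimum on short queries", {
  set.seed(31)
  mat <- search_params()$substitution_matrix
  for (i in 1:12) {
    qlen <- sample(8:15, 1)
    q <- rand_protein(qlen)
    # plant a mutated copy so a word seed exists, plus random context
    qm <- strsplit(q, "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(qlen, nmut)
      qm[at] <- sample(AA20, nmut, replace = TRUE)
    }
    contig <- paste0(rand_dna(30), backtranslate(paste(qm, collapse = "")),
                     rand_dna(30))
    oracle <- brute_tblastn_score(q, contig, mat, 11, 1)
    hs <- search_protein_vs_contig(q, contig,
            search_params(min_raw_score = 12))
    got <- if (nrow(hs)) max(hs$raw_score) else 0
    expect_lte(got, oracle)
    expect_equal(got, oracle)
  }
})

test_that("one full-coverage clean HSP is called intact; empty input is no_copy", {
  set.seed(41)
  q <- rand_protein(120)
  contig <- paste0(rand_dna(200), backtranslate(q), rand_dna(200))
  cc <- chain_and_classify(search_protein_vs_contig(q, contig), 120,
                           contig = contig)
  expect_equal(cc$status, "intact")
  expect_equal(nrow(cc$disruptions), 0)
  empty <- chain_and_classify(search_protein_vs_contig(q, contig)[0, ], 120)
  expect_equal(empty$status, "no_copy")
})

test_that("a 1 bp insertion mid-CDS yields a pseudogene with a frameshift", {
  set.seed(42)
  q <- rand_protein(200)
  cds <- backtranslate(q)
  broken <- paste0(substr(cds, 1, 300), "G", substr(cds, 301, 600))
  contig <- paste0(rand_dna(200), broken, rand_dna(200))
  cc <- chain_and_classify(search_protein_vs_contig(q, contig), 200,
                           contig = contig)
  expect_equal(cc$status, "pseudogene")
  expect_true("frameshift" %in% cc$disruptions$kind)
})

test_that("a planted premature stop codon yields a pseudogene", {
  set.seed(43)
  q <- rand_protein(200)
  cds <- backtranslate(q)
  broken <- paste0(substr(cds, 1, 300), "TGA", substr(cds, 304, 600))
  contig <- paste0(rand_dna(200), broken, rand_dna(200))
  cc <- chain_and_classify(search_protein_vs_contig(q, contig), 200,
                           contig = contig)
  expect_equal(cc$status, "pseudogene")
  expect_true("premature_stop" %in% cc$disruptions$kind)
})

test_that("a reverse-complemented middle segment is an inversion candidate", {
  set.seed(44)
  q <- rand_protein(300)
  cds <- backtranslate(q)
  # the inverted exon block sits inside an intron-like insert, as an
  # assembly artifact would
  contig <- paste0(rand_dna(200), substr(cds, 1, 300),
                   rand_dna(80), rc(substr(cds, 301, 600)), rand_dna(80),
                   substr(cds, 601, 900), rand_dna(200))
  cc <- chain_and_classify(search_protein_vs_contig(q, contig), 300,
                           contig = contig)
  expect_equal(cc$status, "inversion_candidate")
})

test_that("multi-exon genes with introns are classified intact", {
  set.seed(45)
  q <- rand_protein(300)
  cds <- backtranslate(q)
  gene <- paste0(substr(cds, 1, 300), rand_dna(90),
                 substr(cds, 301, 600), rand_dna(120),
                 substr(cds, 601, 900))
  contig <- paste0(rand_dna(200), gene, rand_dna(200))
  cc <- chain_and_classify(search_protein_vs_contig(q, contig), 300,
                           contig = contig)
  expect_equal(cc$status, "intact")
  expect_gte(cc$query_coverage, 0.9)
})

test_that("search sensitivity: diverged planted copies are recovered", {
  # planted copies at ~30% amino-acid divergence, well inside the <=40%
  # regime the scanner must handle
  set.seed(46)
  nrec <- 0; n <- 40
  for (i in 1:n) {
    q <- rand_protein(150)
    qm <- strsplit(q, "")[[1]]
    at <- sample(150, 45)
    qm[at] <- sample(AA20, 45, replace = TRUE)
    contig <- paste0(rand_dna(150), backtranslate(paste(qm, collapse = "")),
                     rand_dna(150))
    cc <- chain_and_classify(search_protein_vs_contig(q, contig), 150,
                             contig = contig)
    if (cc$query_coverage >= 0.9 && cc$status == "intact") nrec <- nrec + 1
  }
  expect_gte(nrec / n, 0.95)
})

test_that("TE annotation merges overlapping hits and keeps separated ones apart", {
  set.seed(51)
  te <- rand_dna(300)
  lib <- list(TEA = te)
  # no planted element: no intervals
  none <- annotate_tes(rand_dna(2000), lib)
  expect_equal(nrow(none$intervals), 0)
  # two copies 100 bp apart stay separate
  ctg2 <- paste0(rand_dna(400), te, rand_dna(100), te, rand_dna(400))
  two <- annotate_tes(ctg2, lib)
  expect_equal(nrow(two$intervals), 2)
  # two overlapping partial copies merge into one interval
  ctg3 <- paste0(rand_dna(400), substr(te, 1, 250),
                 substr(te, 100, 300), rand_dna(400))
  one <- annotate_tes(ctg3, lib)
  expect_equal(nrow(one$intervals), 1)
  # merged interval agrees with a position-wise coverage-marking oracle
  raw <- rbind(c(400, 650), c(650, 851))
  expect_equal(unname(one$intervals[1, "end"] - one$intervals[1, "start"]),
               coverage_bp(raw, c(0, nchar(ctg3))))
})

test_that("te_fraction computes covered percentage and is order/split invariant", {
  mk_te <- function(iv) list(intervals = iv, families = rep("T", nrow(iv)))
  span <- c(0, 10000)
  expect_equal(te_fraction(span, mk_te(matrix(numeric(0), ncol = 2)))$percent, 0)
  expect_equal(te_fraction(c(0, 100), mk_te(rbind(c(0, 100))))$percent, 100)
  res <- te_fraction(span, mk_te(rbind(c(0, 2000), c(1500, 3000))))
  expect_equal(res$percent, 30.0)
  expect_equal(res$bp, 3000L)
  # invariant to interval order and to splitting an interval in two
  res2 <- te_fraction(span, mk_te(rbind(c(1500, 3000), c(0, 2000))))
  res3 <- te_fraction(span, mk_te(rbind(c(0, 1000), c(1000, 2000),
                                        c(1500, 3000))))
  expect_equal(res2$bp, res$bp)
  expect_equal(res3$bp, res$bp)
  expect_error(te_fraction(c(5, 5), mk_te(rbind(c(0, 10)))), "degenerate")
})

test_that("percent identity follows the stated gap rule", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
  # hand count: 3 comparable columns, 3 identical
  expect_equal(percent_identity("A-CG", "ATCG", aligned = TRUE), 100)
  expect_error(percent_identity("--", "AA", aligned = TRUE), "comparable")
})
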