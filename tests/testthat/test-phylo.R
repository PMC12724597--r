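# Column masking, distances, NJ, GTR+G+I likelihood, branch optimization,
# bootstrap and tree comparison.

test_that("exon masking removes exactly the flagged exons", {
  aln <- c(a = strrep("ACGT", 100), b = strrep("ACGA", 100))
  emap <- rep(c("e1", "e2", "e3"), c(100, 300, 0))
  emap <- rep(c("e1", "e2"), c(100, 300))
  m0 <- mask_columns(aln, emap)
  expect_equal(m0$masked_length, 400L)
  expect_identical(m0$alignment[["a"]], aln[["a"]])
  m1 <- mask_columns(aln, emap, flags = "e2")
  expect_equal(m1$masked_length, 100L)
  expect_equal(m1$original_length - m1$masked_length, 300L)
  flags <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2,
                  dimnames = list(c("a", "b"), c("e1", "e2")))
  m2 <- mask_columns(aln, emap, flags = flags)  # e1 absent in b
  expect_equal(m2$masked_length, 300L)
  expect_error(mask_columns(aln, emap, flags = c("e1", "e2")), "all columns")
})

test_that("pairwise distances match the closed forms", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 90), rep("G", 10)), collapse = "")
  D <- pairwise_distance(c(x = a, y = b), "JC69")
  expect_equal(D["x", "y"], -0.75 * log(1 - 4/3 * 0.1), tolerance = 1e-6)
  expect_equal(unname(diag(D)), c(0, 0))
  Dp <- pairwise_distance(c(x = "ACGT", y = "ACGA"), "p")
  expect_equal(Dp["x", "y"], 0.25)
  Did <- pairwise_distance(c(x = "ACGT", y = "ACGT"), "p")
  expect_equal(Did["x", "y"], 0)
  # saturated pairs are flagged, not infinite
  sat <- pairwise_distance(c(x = strrep("A", 40), y = strrep("G", 40)),
                           "JC69")
  expect_true(is.finite(sat["x", "y"]))
  expect_true(attr(sat, "saturated")["x", "y"])
})

test_that("neighbor joining recovers additive trees exactly", {
  # distances generated from a hand-drawn 4-taxon tree:
  # ((A:1,B:2):1,(C:3,D:4):1) with internal edge 2
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A","B"] <- D["B","A"] <- 3
  D["A","C"] <- D["C","A"] <- 6
  D["A","D"] <- D["D","A"] <- 7
  D["B","C"] <- D["C","B"] <- 7
  D["B","D"] <- D["D","B"] <- 8
  D["C","D"] <- D["D","C"] <- 7
  # four-point condition check of the construction itself
  expect_equal(D["A","B"] + D["C","D"], 10)
  expect_equal(D["A","C"] + D["B","D"], D["A","D"] + D["B","C"])
  tr <- nj_tree(D)
  ref <- ape::read.tree(text = "((A:1,B:2):2,C:3,D:4);")
  expect_equal(rf_distance(tr, ref), 0L)
  # recovered branch lengths sum to the path lengths
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-8)
  # label-order invariance
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(rf_distance(tr, tr2), 0L)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a","b"), c("a","b")))),
               "symmetric")
})

test_that("two-taxon site likelihoods match the JC closed form", {
  # one site, different states, total path length t:
  # L = (1/4) * (1/4 - (1/4) exp(-4t/3))
  pars <- gtr_params()  # equal rates/frequencies, single-rate limit
  for (t in c(0.1, 0.5, 1.5)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t/2, t/2))
    ll <- gtr_gi_loglik(tr, c(a = "A", b = "C"), pars)
    expect_equal(exp(ll$loglik), 0.25 * (0.25 - 0.25 * exp(-4 * t / 3)),
                 tolerance = 1e-8)
  }
  # t = 0 and identical states: likelihood is the base frequency
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  ll0 <- gtr_gi_loglik(tr0, c(a = "G", b = "G"), pars)
  expect_equal(exp(ll0$loglik), 0.25, tolerance = 1e-10)
  expect_error(gtr_gi_loglik(tr0, c(a = "", b = ""), pars), "zero-length")
})

test_that("pruning equals the exhaustive ancestral-state oracle on a 4-taxon toy", {
  set.seed(31)
  tr <- ape::read.tree(text = "((a:0.2,b:0.35):0.1,(c:0.15,d:0.4):0.2);")
  aln <- c(a = "ACG", b = "ACT", c = "GCG", d = "ACG")
  pars <- gtr_params(rates = c(1.5, 3, 0.8, 1.1, 3.5, 1),
                     freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.7,
                     p_inv = 0.15)
  ll <- gtr_gi_loglik(tr, aln, pars)$loglik
  oracle <- oracle_loglik(tr, aln, pars$rates, pars$freqs, pars$alpha,
                          pars$p_inv)
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("the likelihood is invariant to re-rooting under reversibility", {
  set.seed(32)
  tr <- generate_species_tree(6, 1, seed = 5, height = 0.3)
  cds <- backtranslate(rand_protein(60))
  sim <- simulate_coding_evolution(tr, cds, omega = 1, seed = 6)
  pars <- gtr_params(rates = c(1, 2, 1, 1, 2, 1), alpha = 1, p_inv = 0.1)
  ll1 <- gtr_gi_loglik(tr, sim$cds, pars)$loglik
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  ll2 <- gtr_gi_loglik(rerooted, sim$cds, pars)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-6)
})

test_that("branch-length optimization is monotone and finds the 2-taxon MLE", {
  set.seed(33)
  # 2 taxa, 25% differing sites, JC: optimized length approaches the JC MLE
  n <- 2000
  a <- paste(sample(BASES, n, replace = TRUE), collapse = "")
  ach <- strsplit(a, "")[[1]]
  idx <- sample(n, n / 4)
  bch <- ach
  bch[idx] <- vapply(ach[idx], function(x) sample(setdiff(BASES, x), 1),
                     character(1))
  aln <- c(a = a, b = paste(bch, collapse = ""))
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  opt <- optimize_branch_lengths(tr, aln, gtr_params())
  jc <- -0.75 * log(1 - 4/3 * 0.25)
  expect_equal(sum(opt$tree$edge.length), jc, tolerance = 0.02)
  expect_true(all(diff(opt$trace) >= -1e-9))

  # starting from the truth, one sweep changes the likelihood negligibly
  tr6 <- generate_species_tree(6, 1, seed = 7, height = 0.3)
  sim <- simulate_coding_evolution(tr6, backtranslate(rand_protein(400)),
                                   omega = 1, seed = 8)
  l0 <- gtr_gi_loglik(tr6, sim$cds, gtr_params())$loglik
  opt6 <- optimize_branch_lengths(tr6, sim$cds, gtr_params(), max_sweeps = 3)
  expect_gte(opt6$loglik, l0 - 1e-9)
  expect_true(all(diff(opt6$trace) >= -1e-9))
})

test_that("bootstrap support is reproducible and unanimous signal gives 100", {
  # an alignment where every informative column supports the same split
  aln <- c(A = strrep("AAAA", 10), B = strrep("AAAA", 10),
           C = strrep("GGGG", 10), D = strrep("GGGG", 10))
  build <- function(a) nj_tree(pairwise_distance(a, "p"))
  bs <- bootstrap_support(aln, build, B = 100, seed = 5)
  expect_equal(unname(bs$support), 100)
  bs2 <- bootstrap_support(aln, build, B = 100, seed = 5)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(aln, build, B = 0), "B must be")
})

test_that("RF distance counts the symmetric split difference", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  resolved <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(rf_distance(star, resolved), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "tip sets")
  # independent cross-check on random trees
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (i in 1:10) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    y$tip.label <- x$tip.label
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(x, y)))
  }
})

test_that("monophyly is judged on the tree rooted at the outgroup", {
  tr <- ape::read.tree(text = "((A,B),((C,D),E));")
  expect_true(is_monophyletic(tr, c("C", "D"), "A"))
  expect_true(is_monophyletic(tr, c("C", "D", "E"), "A"))
  expect_true(is_monophyletic(tr, "B", "A"))
  expect_true(is_monophyletic(tr, setdiff(tr$tip.label, "A"), "A"))
  # a set straddling the root partition is not monophyletic
  expect_false(is_monophyletic(tr, c("B", "C"), "A"))
  expect_false(is_monophyletic(tr, c("A", "E"), "B"))
  expect_error(is_monophyletic(tr, c("A", "B"), "A"), "outgroup")
})

test_that("GTR-ML pairwise distances agree with JC on JC-like data", {
  set.seed(42)
  n <- 1500
  a <- paste(sample(BASES, n, replace = TRUE), collapse = "")
  ach <- strsplit(a, "")[[1]]
  idx <- sample(n, round(n * 0.12))
  bch <- ach
  bch[idx] <- vapply(ach[idx], function(x) sample(setdiff(BASES, x), 1),
                     character(1))
  aln <- c(a = a, b = paste(bch, collapse = ""))
  Djc <- pairwise_distance(aln, "JC69")
  Dml <- pairwise_distance(aln, "GTR-ML-pairwise")
  expect_equal(Dml["a", "b"], Djc["a", "b"], tolerance = 0.01)
})
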