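# PSSM construction, exact null distributions, scanning, and the two-round
# iterative procedure.

test_that("seed extraction applies the identity floor and the indel exclusion", {
  ref <- paste(rep("ARNDCQEGHIKLMNPQRS", 3), collapse = "")  # 54 aa, no gaps
  L <- nchar(ref)
  mk_seq <- function(x) x
  # one species at ~50% identity inside the window, one identical, one gapped
  win <- substr(ref, 11, 30)
  low <- ref
  substr(low, 11, 20) <- "YYYYYYYYYY"   # 10 of 20 differ -> 50% identity
  gapped <- ref
  substr(gapped, 15, 15) <- "-"
  aln <- c(D.melanogaster = ref, same = ref, low = low, gapped = gapped)
  defs <- data.frame(name = "w", start = 11, end = 30)
  seeds <- extract_reference_motifs(aln, defs, min_identity = 60)
  expect_true(all(c("D.melanogaster", "same") %in% names(seeds$w)))
  expect_false("low" %in% names(seeds$w))      # below the 60% floor
  expect_false("gapped" %in% names(seeds$w))   # indel exclusion
  # boundary: exactly 55% identity is excluded
  m55 <- ref
  substr(m55, 11, 19) <- "YYYYYYYYY"  # 9 of 20 differ -> 55%
  seeds55 <- extract_reference_motifs(c(aln, m55 = m55), defs)
  expect_false("m55" %in% names(seeds55$w))
  # all sequences identical to the reference are all retained
  allsame <- extract_reference_motifs(
    c(D.melanogaster = ref, a = ref, b = ref), defs)
  expect_equal(length(allsame$w), 3L)
})

test_that("PSSM probabilities and log-odds follow the stated formula", {
  # single seed "AAA", pseudocount 1, uniform background:
  # P(A) = (1 + 0.05) / 2 = 0.525, log-odds = log2(10.5)
  p <- build_pssm("AAA", pseudocount = 1)
  expect_equal(unname(p$prob[1, "A"]), 0.525)
  expect_equal(unname(p$logodds[1, "A"]), log2(10.5))
  # uniform counts in a column give log-odds 0 everywhere in that column
  seeds20 <- vapply(AA20, function(a) paste0(a, "AA"), character(1))
  p20 <- build_pssm(unname(seeds20), pseudocount = 1)
  expect_true(all(abs(p20$logodds[1, ]) < 1e-12))
  # adding a duplicate of an existing seed never decreases its own score
  sc <- function(pssm, s) {
    ch <- strsplit(s, "")[[1]]
    sum(pssm$lattice[cbind(seq_along(ch), match(ch, AA20))])
  }
  set.seed(2)
  seeds <- vapply(1:5, function(i) rand_protein(6), character(1))
  p1 <- build_pssm(seeds)
  p2 <- build_pssm(c(seeds, seeds[3]))
  expect_gte(sc(p2, seeds[3]), sc(p1, seeds[3]))
  expect_error(build_pssm(c("AA", "AAA")), "length")
})

test_that("the exact null equals brute-force enumeration", {
  # w = 1: a strictly highest-scoring residue has tail probability 1/20
  p1 <- build_pssm("A", pseudocount = 0.1)
  expect_equal(p1$null$tail(max(p1$lattice)), 0.05)
  expect_equal(p1$null$tail(p1$null$min), 1.0)
  # w = 3 over the full alphabet: compare to all 8000 words
  set.seed(4)
  p3 <- build_pssm(vapply(1:4, function(i) rand_protein(3), character(1)))
  at <- quantile(p3$lattice %*% rep(1, 20), c(0, .5, 1))
  at <- unique(as.integer(c(p3$null$min, 0, p3$null$max, at)))
  oracle <- enumerate_null_tail(p3$lattice, rep(1/20, 20), at)
  expect_lt(max(abs(p3$null$tail(at) - oracle)), 1e-12)
})

test_that("scanning finds planted motifs and respects the threshold semantics", {
  set.seed(6)
  seeds <- replicate(6, {
    base <- strsplit("WYCHKR MF", "")[[1]]
    rand_protein(8)
  })
  consensus <- rand_protein(8)
  seeds <- vapply(1:6, function(i) {
    ch <- strsplit(consensus, "")[[1]]
    j <- sample(8, 1); ch[j] <- sample(AA20, 1)
    paste(ch, collapse = "")
  }, character(1))
  p <- build_pssm(c(consensus, seeds))
  prot <- paste0(rand_protein(246), consensus, rand_protein(246))
  h <- scan_sequence(p, prot)
  best <- h[h$best, ]
  expect_equal(best$start, 246L)
  expect_lt(best$p_value, 1e-6)
  expect_true(best$passes_threshold)
  # two disjoint planted copies give two passing hits
  prot2 <- paste0(rand_protein(100), consensus, rand_protein(100), consensus,
                  rand_protein(100))
  h2 <- scan_sequence(p, prot2)
  expect_equal(sort(h2$start[h2$passes_threshold]), c(100L, 208L))
  # prepending 10 residues shifts every hit start by exactly 10
  h3 <- scan_sequence(p, paste0(rand_protein(10), prot2))
  expect_equal(sort(h3$start[h3$passes_threshold]),
               c(100L, 208L) + 10L)
  # threshold boundary: passes_threshold is exactly p < 1e-6, both sides
  pv <- h$p_value[h$best]
  expect_identical(h$passes_threshold[h$best], pv < 1e-6)
  loose <- scan_sequence(p, prot, threshold = pv)        # p == threshold
  expect_false(loose$passes_threshold[loose$best])       # strict <
  loose2 <- scan_sequence(p, prot, threshold = pv * 1.01)
  expect_true(loose2$passes_threshold[loose2$best])
})

test_that("a minimally scoring sequence yields no passing hits and short input no scan", {
  p <- build_pssm(c("AAAA", "AAAA"))
  worst <- names(which.min(p$lattice[1, ]))
  h <- scan_sequence(p, strrep(worst, 30))
  expect_equal(sum(h$passes_threshold), 0L)
  h0 <- scan_sequence(p, "AA")  # shorter than the motif
  expect_equal(nrow(h0), 0L)
})

test_that("the two-round scan is a fixed point without matches and absorbs them otherwise", {
  set.seed(8)
  seeds <- list(m = vapply(1:5, function(i) rand_protein(10), character(1)))
  queries <- c(q1 = rand_protein(80), q2 = rand_protein(80))
  res <- iterative_scan(seeds, queries)
  expect_equal(res$matrices$m$n_seeds, 5L)  # no matches absorbed
  expect_equal(nrow(res$round_hits[[1]][res$round_hits[[1]]$passes_threshold, ]),
               nrow(res$hits[res$hits$passes_threshold, ]))

  # duplicate queries receive identical hit sets
  qd <- c(a = queries[[1]], b = queries[[1]])
  resd <- iterative_scan(seeds, qd)
  ha <- resd$hits[resd$hits$sequence_id == "a", -1]
  hb <- resd$hits[resd$hits$sequence_id == "b", -1]
  rownames(ha) <- rownames(hb) <- NULL
  expect_identical(ha, hb)
})

test_that("a distant homolog crosses the threshold only in round 2", {
  # construct a family where a close homolog's round-1 match sharpens the
  # matrix enough to pull a distant homolog over the threshold; both
  # p-values are computed exactly on the constructed instance
  found <- FALSE
  for (attempt in 1:40) {
    set.seed(900 + attempt)
    w <- 12
    consensus <- rand_protein(w)
    mutate <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      at <- sample(length(ch), k)
      for (j in at) ch[j] <- sample(setdiff(AA20, ch[j]), 1)
      paste(ch, collapse = "")
    }
    seeds <- list(m = vapply(1:3, function(i) mutate(consensus, 1),
                             character(1)))
    close_h <- mutate(consensus, 1)
    distant <- mutate(consensus, 5)
    queries <- c(close = paste0(rand_protein(40), close_h, rand_protein(40)),
                 far = paste0(rand_protein(40), distant, rand_protein(40)))
    r1 <- iterative_scan(seeds, queries, rounds = 1)
    h1 <- r1$hits
    far1 <- h1[h1$sequence_id == "far" & h1$start == 40, ]
    close1 <- h1[h1$sequence_id == "close" & h1$start == 40, ]
    if (!nrow(far1) || !nrow(close1)) next
    if (far1$passes_threshold || !close1$passes_threshold) next
    r2 <- iterative_scan(seeds, queries, rounds = 2)
    h2 <- r2$hits
    far2 <- h2[h2$sequence_id == "far" & h2$start == 40, ]
    if (nrow(far2) && far2$passes_threshold) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("single-residue conservation is mapped through the alignment", {
  aln <- c(D.melanogaster = "MA-RKL",
           s1 = "MACRKL",
           s2 = "MA-KKL",
           s3 = "MA--KL")
  # reference ungapped position 3 is R, at alignment column 4
  res <- check_residue_conservation(aln, "R3")
  expect_true(res$conserved[res$sequence == "D.melanogaster"])
  expect_true(res$conserved[res$sequence == "s1"])
  expect_false(res$conserved[res$sequence == "s2"])  # K there
  expect_false(res$conserved[res$sequence == "s3"])  # gap
  expect_true(res$is_gap[res$sequence == "s3"])
  # the packaged reference family keeps its critical arginine everywhere
  rc <- check_residue_conservation(reference_msa(), "R1101")
  expect_true(all(rc$conserved))
})

test_that("exact-null equivalence holds on a reduced alphabet up to width 8", {
  # restrict the background to four residues; enumeration over 4^8 words
  set.seed(10)
  bg <- rep(0, 20); bg[1:4] <- 0.25
  seeds <- vapply(1:3, function(i)
    paste(sample(AA20[1:4], 8, replace = TRUE), collapse = ""), character(1))
  p <- build_pssm(seeds, background = bg)
  lat4 <- p$lattice[, 1:4]
  idx <- do.call(expand.grid, rep(list(1:4), 8))
  tot <- vapply(seq_len(nrow(idx)), function(i)
    sum(lat4[cbind(1:8, as.integer(idx[i, ]))]), numeric(1))
  at <- as.integer(quantile(tot, c(0, .25, .5, .75, 1)))
  oracle <- vapply(at, function(s) mean(tot >= s), numeric(1))
  expect_lt(max(abs(p$null$tail(at) - oracle)), 1e-12)
})
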