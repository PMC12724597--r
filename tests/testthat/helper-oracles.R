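# Independent oracles and small constructors shared across the suite.
# Every oracle here is implemented from first principles, independent of the
# package code paths it checks.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
BASES <- c("A","C","G","T")

GC_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

aa_of <- function(codon) {
  a <- GC_TABLE[[codon]]
  if (is.null(a)) "X" else a
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# back-translate a protein, sampling synonymous codons
backtranslate <- function(protein) {
  paste(vapply(strsplit(protein, "")[[1]], function(a) {
    cods <- names(GC_TABLE)[GC_TABLE == a]
    sample(cods, 1)
  }, character(1)), collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

translate0 <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  paste(vapply(seq_len(n), function(i)
    aa_of(substr(dna, 3 * i - 2, 3 * i)), character(1)), collapse = "")
}

# --- brute-force local alignment oracle (full DP, affine gaps) -------------
# Returns the optimal local alignment score of a protein query against a
# protein subject under the given matrix; gap of length k costs open + k*ext.
brute_local_score <- function(query, subject, mat, open, ext) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  Fm <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
    Fm[i, j] <- max(H[i, j - 1] - open - ext, Fm[i, j - 1] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[q[i - 1], s[j - 1]],
                   E[i, j], Fm[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# best tBLASTn-style score: max over the six frame translations
brute_tblastn_score <- function(query, contig, mat, open, ext) {
  rcc <- rc(contig)
  frames <- c(substring(contig, 1:3), substring(rcc, 1:3))
  max(vapply(frames, function(f)
    brute_local_score(query, translate0(f), mat, open, ext), numeric(1)))
}

# --- exact PSSM null by enumeration ----------------------------------------
# tail probabilities of the lattice score of all |alphabet|^w words
enumerate_null_tail <- function(lattice, background, scores_at) {
  w <- nrow(lattice)
  idx <- rep(list(seq_along(background)), w)
  grid <- do.call(expand.grid, idx)
  probs <- apply(grid, 1, function(r) prod(background[r]))
  tot <- vapply(seq_len(nrow(grid)), function(i)
    sum(lattice[cbind(seq_len(w), as.integer(grid[i, ]))]), numeric(1))
  vapply(scores_at, function(s) sum(probs[tot >= s]), numeric(1))
}

# --- exhaustive ancestral-state likelihood oracle --------------------------
# Sums over all internal-node state assignments; GTR transition probabilities
# from matrix exponentials (Pade via repeated squaring on small t is fine:
# use eigen of the numeric Q built independently).
oracle_qmatrix <- function(rates, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pairs <- rbind(c(1,2),c(1,3),c(1,4),c(2,3),c(2,4),c(3,4))
  for (k in 1:6) {
    i <- pairs[k,1]; j <- pairs[k,2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(freqs * diag(Q)))
}

oracle_pmat <- function(Q, t) as.matrix(Matrix::expm(Q * t))

oracle_loglik <- function(tree, seqs, rates, freqs, alpha, p_inv, ncat = 4) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- setdiff(unique(as.vector(tree$edge)), seq_len(ntip))
  Q <- oracle_qmatrix(rates, freqs)
  # discrete gamma category rates (equal-probability bins, bin means)
  cat_rates <- if (is.finite(alpha)) {
    b <- qgamma(seq(0, 1, length.out = ncat + 1), alpha, rate = alpha)
    r <- ncat * diff(pgamma(b, alpha + 1, rate = alpha))
    r / mean(r)
  } else rep(1, ncat)
  if (p_inv > 0) cat_rates <- cat_rates / (1 - p_inv)
  L <- nchar(seqs[[1]])
  states <- lapply(tree$tip.label, function(tp)
    match(strsplit(toupper(seqs[[tp]]), "")[[1]], BASES))
  root <- tree$edge[nrow(tree$edge), 1]
  Ps_by_cat <- lapply(seq_along(cat_rates), function(ci)
    lapply(seq_len(nrow(tree$edge)), function(k)
      oracle_pmat(Q, tree$edge.length[k] * cat_rates[ci])))
  total <- 0
  for (site in seq_len(L)) {
    site_lik <- 0
    for (ci in seq_along(cat_rates)) {
      Ps <- Ps_by_cat[[ci]]
      # enumerate internal states
      grid <- do.call(expand.grid, rep(list(1:4), length(internal)))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- integer(nnode)
        assign_state[internal] <- as.integer(grid[g, ])
        for (tp in seq_len(ntip)) assign_state[tp] <- states[[tp]][site]
        p <- freqs[assign_state[root]]
        ok <- TRUE
        for (k in seq_len(nrow(tree$edge))) {
          a <- assign_state[tree$edge[k, 1]]; b <- assign_state[tree$edge[k, 2]]
          if (is.na(b)) { # missing tip data: sum over states = row sum = 1
            next
          }
          p <- p * Ps[[k]][a, b]
        }
        lik <- lik + p
      }
      site_lik <- site_lik + lik * (1 - p_inv) / length(cat_rates)
    }
    if (p_inv > 0) {
      obs <- vapply(seq_len(ntip), function(tp) states[[tp]][site], integer(1))
      obs <- obs[!is.na(obs)]
      inv <- if (length(unique(obs)) <= 1) {
        if (length(obs)) freqs[obs[1]] else 1
      } else 0
      site_lik <- site_lik + p_inv * inv
    }
    total <- total + log(site_lik)
  }
  total
}

# --- Fisher exact two-sided by hypergeometric enumeration ------------------
oracle_fisher2 <- function(tab) {
  a <- tab[1,1]; b <- tab[1,2]; c <- tab[2,1]; d <- tab[2,2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- position-wise interval coverage oracle --------------------------------
coverage_bp <- function(intervals, span) {
  if (!nrow(intervals)) return(0)
  pos <- rep(FALSE, span[2] - span[1])
  for (r in seq_len(nrow(intervals))) {
    lo <- max(intervals[r, 1], span[1]); hi <- min(intervals[r, 2], span[2])
    if (hi > lo) pos[(lo - span[1] + 1):(hi - span[1])] <- TRUE
  }
  sum(pos)
}

# seed-scoped helpers used by the acceptance suite
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_cds_local <- function(n_codons) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
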