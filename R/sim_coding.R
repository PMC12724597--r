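## Codon-aware sequence evolution and population samples.
##
## Coding evolution proposes point mutations at the neutral rate (branch
## lengths are neutral-equivalent expected substitutions per site) with a
## transition/transversion bias kappa; nonsynonymous proposals are accepted
## with probability min(1, omega) and synonymous ones with min(1, 1/omega),
## so the nonsynonymous/synonymous rate ratio equals omega. Proposals
## creating a stop codon are always rejected, so intact CDS never gain
## internal stops. No indels arise in intact CDS: the true alignment of the
## extant sequences is gap-free and column-homologous.

## draw a target base with transition bias kappa given the current base
draw_base <- function(from, kappa) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(DNA_BASES, from)
  w <- ifelse(others == transitions[[from]], kappa, 1)
  sample(others, 1, prob = w)
}

## one branch of codon-aware evolution; returns new cds + accepted mutations
evolve_cds_branch <- function(cds, t, omega, kappa) {
  L <- nchar(cds)
  n_prop <- rpois(1, L * t)
  ch <- s2c(cds)
  acc_n <- min(1, omega); acc_s <- min(1, 1 / omega)
  pos <- integer(0); base <- character(0)
  if (n_prop > 0) for (i in seq_len(n_prop)) {
    p <- sample.int(L, 1)
    b <- draw_base(ch[p], kappa)
    ci <- (p - 1) %/% 3
    cod <- ch[(3 * ci + 1):(3 * ci + 3)]
    newcod <- cod; newcod[(p - 1) %% 3 + 1] <- b
    aa1 <- codon_aa(c2s(cod)); aa2 <- codon_aa(c2s(newcod))
    if (aa2 == "*") next
    acc <- if (aa1 == aa2) acc_s else acc_n
    if (runif(1) < acc) {
      ch[p] <- b
      pos <- c(pos, p); base <- c(base, b)
    }
  }
  list(cds = c2s(ch), muts = data.frame(pos = pos, base = base,
                                        stringsAsFactors = FALSE))
}

## neutral (non-coding) evolution of a plain sequence
evolve_neutral_branch <- function(seq, t, kappa) {
  L <- nchar(seq)
  n <- rpois(1, L * t)
  ch <- s2c(seq)
  pos <- integer(0); base <- character(0)
  if (n > 0) for (i in seq_len(n)) {
    p <- sample.int(L, 1)
    if (!ch[p] %in% DNA_BASES) next
    b <- draw_base(ch[p], kappa)
    ch[p] <- b
    pos <- c(pos, p); base <- c(base, b)
  }
  list(seq = c2s(ch), muts = data.frame(pos = pos, base = base,
                                        stringsAsFactors = FALSE))
}

#' Simulate coding evolution along a tree
#'
#' Applies codon-aware substitution (see above) along every branch of the
#' tree, starting from a root CDS with no internal stop codons. Because no
#' indels occur, the true alignment of the extant sequences is the sequences
#' themselves (gap-free, column-homologous).
#'
#' @param tree `phylo` tree with branch lengths (substitutions/site)
#' @param root_cds root coding sequence, length divisible by 3, no internal
#'   stops
#' @param omega dN/dS ratio
#' @param kappa transition/transversion ratio
#' @param seed RNG seed
#' @return list with `cds` (named character vector per tip), `alignment`
#'   (identical to `cds`; gap-free), `n_syn`, `n_nonsyn` (accepted
#'   substitution counts over the whole tree)
#' @export
simulate_coding_evolution <- function(tree, root_cds, omega = 1, kappa = 2,
                                      seed = 1) {
  L <- nchar(root_cds)
  if (L %% 3 != 0) stop("root_cds length not divisible by 3")
  aa <- translate_cds(root_cds)
  if (grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    stop("root_cds contains an internal stop codon")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1]
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- root_cds
  n_syn <- 0; n_nonsyn <- 0
  with_seed(seed, {
    for (k in rev(seq_len(nrow(tree$edge)))) {  # preorder
      p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
      res <- evolve_cds_branch(seqs[[p]], tree$edge.length[k], omega, kappa)
      seqs[[v]] <- res$cds
      if (nrow(res$muts)) {
        ## classify accepted changes against the pre-mutation sequence state
        cur <- s2c(seqs[[p]])
        for (i in seq_len(nrow(res$muts))) {
          pp <- res$muts$pos[i]; ci <- (pp - 1) %/% 3
          cod <- cur[(3 * ci + 1):(3 * ci + 3)]
          newcod <- cod; newcod[(pp - 1) %% 3 + 1] <- res$muts$base[i]
          if (codon_aa(c2s(cod)) == codon_aa(c2s(newcod)))
            n_syn <- n_syn + 1 else n_nonsyn <- n_nonsyn + 1
          cur[pp] <- res$muts$base[i]
        }
      }
    }
  })
  cds <- setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
  list(cds = cds, alignment = cds, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate a within-species population sample (infinite sites)
#'
#' Draws Poisson(theta * a_n) segregating mutations, a_n = sum_{i<n} 1/i,
#' places each at a distinct site, assigns the derived allele to i haplotypes
#' with P(i) proportional to 1/i (the neutral frequency spectrum), and
#' rejects placements that would create a stop codon in any carrier. The
#' same selective constraint that shapes divergence applies to segregating
#' variation: a nonsynonymous placement is kept with probability
#' min(1, omega), a synonymous one with min(1, 1/omega), and rejected
#' placements are redrawn, so the total segregating-site count keeps its
#' expectation theta * a_n while the nonsynonymous fraction reflects omega.
#' With theta = 0 all haplotypes are identical.
#'
#' @param species_cds the species coding sequence (in frame)
#' @param theta population-scaled mutation rate (per gene)
#' @param n_strains number of haplotypes (>= 2)
#' @param seed RNG seed
#' @param kappa transition/transversion ratio for the derived base
#' @param omega dN/dS constraint on segregating variation (1 = neutral)
#' @return named character vector of `n_strains` gap-free haplotypes
#' @export
simulate_population_sample <- function(species_cds, theta, n_strains,
                                       seed = 1, kappa = 2, omega = 1) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  stopifnot(theta >= 0)
  L <- nchar(species_cds)
  a_n <- sum(1 / seq_len(n_strains - 1))
  hap <- matrix(rep(s2c(species_cds), n_strains), nrow = n_strains,
                byrow = TRUE)
  with_seed(seed, {
    S <- rpois(1, theta * a_n)
    used <- integer(0)
    freq_w <- 1 / seq_len(n_strains - 1)
    placed <- 0
    guard <- 0
    while (placed < S && guard < 50 * (S + 1)) {
      guard <- guard + 1
      p <- sample.int(L, 1)
      if (p %in% used) next
      i <- sample.int(n_strains - 1, 1, prob = freq_w)
      carriers <- sample.int(n_strains, i)
      b <- draw_base(hap[carriers[1], p], kappa)
      ci <- (p - 1) %/% 3
      cols <- (3 * ci + 1):(3 * ci + 3)
      ok <- TRUE
      nonsyn <- FALSE
      for (h in carriers) {
        cod <- hap[h, cols]
        newcod <- cod; newcod[(p - 1) %% 3 + 1] <- b
        if (codon_aa(c2s(newcod)) == "*") { ok <- FALSE; break }
        if (codon_aa(c2s(cod)) != codon_aa(c2s(newcod))) nonsyn <- TRUE
      }
      if (!ok) next
      acc <- if (nonsyn) min(1, omega) else min(1, 1 / omega)
      if (runif(1) >= acc) next
      hap[carriers, p] <- b
      used <- c(used, p)
      placed <- placed + 1
    }
  })
  setNames(apply(hap, 1, c2s), sprintf("hap%02d", seq_len(n_strains)))
}
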