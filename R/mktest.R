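## Unpolarized McDonald-Kreitman tests with codon-aware pathway averaging.
##
## Differences between codons are classified synonymous / nonsynonymous by
## enumerating minimal single-step mutational pathways and averaging over the
## equally parsimonious orders (paths through stop codons are excluded when a
## stop-free path exists). Divergence is counted between the population
## consensus and a single outgroup sequence, with no ancestral polarization.

## average (nonsyn, syn) step counts over minimal mutational pathways between
## two codons
codon_path_counts <- function(a, b) {
  pos <- which(s2c(a) != s2c(b))
  k <- length(pos)
  if (k == 0) return(c(n = 0, s = 0))
  perms <- if (k == 1) list(pos)
           else if (k == 2) list(pos, rev(pos))
           else {
    p <- list()
    for (i in 1:3) for (j in setdiff(1:3, i))
      p[[length(p) + 1]] <- c(pos[i], pos[j], pos[setdiff(1:3, c(i, j))])
    p
  }
  tally <- function(order) {
    cur <- s2c(a); tgt <- s2c(b)
    n <- 0; s <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- tgt[p]
      aa1 <- codon_aa(c2s(cur)); aa2 <- codon_aa(c2s(nxt))
      if (aa2 == "*" || aa1 == "*") return(NULL)  # path through a stop
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(n = n, s = s)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally))
  if (!length(res))  # no stop-free path: average over all orders regardless
    res <- lapply(perms, function(order) {
      cur <- s2c(a); tgt <- s2c(b); n <- 0; s <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- tgt[p]
        if (codon_aa(c2s(cur)) == codon_aa(c2s(nxt))) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(n = n, s = s)
    })
  colMeans(do.call(rbind, res))
}

#' Classify polymorphism and divergence changes at one codon column
#'
#' Polymorphic differences among the population codons are counted between
#' each minor allele and the majority allele with pathway averaging.
#' Divergence is counted between the population consensus and the outgroup
#' codon; a nucleotide position that is both polymorphic and divergent counts
#' as polymorphism only.
#'
#' @param pop_codons character vector of population codons (one per
#'   haplotype, multiplicities included)
#' @param outgroup_codon the outgroup codon
#' @return named numeric vector (pn, ps, dn, ds)
#' @export
classify_codon_changes <- function(pop_codons, outgroup_codon) {
  all_cod <- c(pop_codons, outgroup_codon)
  if (any(vapply(all_cod, function(x) codon_aa(x) == "*", logical(1))))
    stop("stop codon encountered")
  tab <- sort(table(pop_codons), decreasing = TRUE)
  major <- names(tab)[1]
  pn <- 0; ps <- 0
  for (al in names(tab)[-1]) {
    cc <- codon_path_counts(major, al)
    pn <- pn + cc[["n"]]; ps <- ps + cc[["s"]]
  }
  ## divergence: consensus vs outgroup, masking polymorphic positions
  poly_pos <- which(vapply(1:3, function(p)
    length(unique(substr(pop_codons, p, p))) > 1, logical(1)))
  og <- s2c(outgroup_codon)
  cons <- s2c(major)
  og[poly_pos] <- cons[poly_pos]
  cc <- codon_path_counts(major, c2s(og))
  c(pn = pn, ps = ps, dn = cc[["n"]], ds = cc[["s"]])
}

#' Build an unpolarized McDonald-Kreitman table for one gene
#'
#' Sums [classify_codon_changes()] over codons of an in-frame population
#' alignment against a single outgroup sequence, then attaches the exact
#' two-sided test and the derived neutrality index and alpha. Codons
#' containing a gap or ambiguity in any haplotype (or the outgroup) are
#' excluded entirely. Fractional pathway-averaged counts are rounded
#' half-to-even for the exact test only; NI uses the unrounded counts.
#'
#' @param pop named/unnamed character vector of equal-length in-frame
#'   haplotype sequences
#' @param outgroup outgroup nucleotide sequence of the same length
#' @return object of class `mk_table`: list with counts (Pn, Ps, Dn, Ds),
#'   p_two_sided, NI, alpha, n_codons_used, has_data
#' @export
mk_table <- function(pop, outgroup) {
  L <- unique(nchar(c(pop, outgroup)))
  if (length(L) != 1) stop("sequences must have equal length")
  if (L %% 3 != 0) stop("alignment length not divisible by 3 (frame violation)")
  Pn <- Ps <- Dn <- Ds <- 0
  used <- 0
  for (i in seq_len(L / 3)) {
    a <- 3 * (i - 1) + 1
    cods <- substr(pop, a, a + 2)
    ogc <- substr(outgroup, a, a + 2)
    allc <- c(cods, ogc)
    aas <- GENETIC_CODE_STD[allc]
    if (anyNA(aas)) next            # gap or ambiguity in some haplotype
    if (any(aas == "*")) next       # stop codons are excluded entirely
    if (all(allc == allc[1])) { used <- used + 1; next }  # invariant codon
    cc <- classify_codon_changes(cods, ogc)
    Pn <- Pn + cc[["pn"]]; Ps <- Ps + cc[["ps"]]
    Dn <- Dn + cc[["dn"]]; Ds <- Ds + cc[["ds"]]
    used <- used + 1
  }
  has_data <- (Pn + Ps + Dn + Ds) > 0
  p <- if (has_data)
    fisher_exact(matrix(round(c(Pn, Ps, Dn, Ds)), 2)) else NA_real_
  ni <- neutrality_index(c(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds))
  structure(list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
                 p_two_sided = p, NI = ni$NI, alpha = ni$alpha,
                 n_codons_used = used, has_data = has_data),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  if (!x$has_data) {
    cat("MK table: no data (all counts zero)\n")
    return(invisible(x))
  }
  cat(sprintf("MK table: Pn=%.2f Ps=%.2f Dn=%.2f Ds=%.2f  p=%.4g  NI=%s  alpha=%s\n",
              x$Pn, x$Ps, x$Dn, x$Ds, x$p_two_sided,
              ifelse(is.na(x$NI), "undef", sprintf("%.3f", x$NI)),
              ifelse(is.na(x$alpha), "undef", sprintf("%.3f", x$alpha))))
  invisible(x)
}

#' Exact two-sided test for a 2x2 contingency table
#'
#' Exact conditional (hypergeometric) test, two-sided by summing all tables
#' with probability not exceeding the observed one. A table with a zero
#' margin has a degenerate conditional distribution and returns p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#' @return two-sided p-value in (0, 1]
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0)) stop("negative entries")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1.0)
  stats::fisher.test(table)$p.value
}

#' Neutrality index and alpha from MK counts
#'
#' NI = (Pn/Ps) / (Dn/Ds), computed as (Pn * Ds) / (Ps * Dn) so that it is
#' defined whenever Ps > 0 and Dn > 0; alpha = 1 - NI. Undefined
#' combinations are returned as NA with a flag, never as a division error.
#'
#' @param counts named vector or list with Pn, Ps, Dn, Ds
#' @return list with NI, alpha, defined
#' @export
neutrality_index <- function(counts) {
  Pn <- counts[["Pn"]]; Ps <- counts[["Ps"]]
  Dn <- counts[["Dn"]]; Ds <- counts[["Ds"]]
  if (Ps > 0 && Dn > 0) {
    ni <- (Pn * Ds) / (Ps * Dn)
    list(NI = ni, alpha = 1 - ni, defined = TRUE)
  } else {
    list(NI = NA_real_, alpha = NA_real_, defined = FALSE)
  }
}
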