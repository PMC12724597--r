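## GTR+G+I phylogenetics: exon-level column masking, distance/NJ starting
## trees, Felsenstein pruning likelihood with 4 discrete gamma categories
## plus an invariant class, coordinate-ascent branch-length optimization,
## bootstrap support and tree-comparison utilities.

#' Mask alignment columns by exon flags
#'
#' Removes all columns belonging to any exon flagged absent or duplicated in
#' at least one species. Masking granularity is whole exons.
#'
#' @param alignment named character vector of equal-length aligned sequences
#' @param exon_map integer/character vector of length `nchar(alignment[1])`
#'   giving the exon id of every column
#' @param flags either a character vector of flagged exon ids, or a logical
#'   matrix (species x exons, TRUE = absent/duplicated in that species)
#' @return object of class `masked_alignment`: list with `alignment` (masked
#'   sequences), `retained` (original column indices kept), `exon_map`,
#'   `original_length`, `masked_length`
#' @export
mask_columns <- function(alignment, exon_map, flags = character(0)) {
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("alignment rows differ in length")
  if (length(exon_map) != L) stop("exon map does not tile the alignment")
  flagged <- if (is.matrix(flags)) colnames(flags)[apply(flags, 2, any)]
             else as.character(flags)
  keep <- !(as.character(exon_map) %in% flagged)
  if (!any(keep)) stop("all columns masked")
  idx <- which(keep)
  masked <- vapply(alignment, function(s) c2s(s2c(s)[idx]), character(1))
  structure(list(alignment = masked, retained = idx,
                 exon_map = exon_map[idx],
                 original_length = L, masked_length = length(idx)),
            class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("masked alignment: %d of %d columns retained (%d sequences)\n",
              x$masked_length, x$original_length, length(x$alignment)))
  invisible(x)
}

aln_strings <- function(alignment) {
  if (inherits(alignment, "masked_alignment")) alignment$alignment else alignment
}

#' Pairwise distances from an alignment
#'
#' Gap or N positions are excluded pairwise. Saturated pairs (where the
#' correction is undefined) are reported as a flagged large distance, not
#' infinity; the flag matrix is attached as attribute `saturated`.
#'
#' @param alignment named character vector or [mask_columns()] result
#' @param model one of "p", "JC69", "K80", "GTR-ML-pairwise"
#' @param gtr_params for model "GTR-ML-pairwise", a [gtr_params()] object
#' @param max_distance distance reported for saturated pairs
#' @return symmetric matrix of distances with zero diagonal
#' @export
pairwise_distance <- function(alignment, model = c("JC69", "p", "K80",
                                                   "GTR-ML-pairwise"),
                              gtr_params = NULL, max_distance = 5) {
  model <- match.arg(model)
  seqs <- aln_strings(alignment)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  n <- length(seqs)
  chm <- matrix(unlist(lapply(seqs, function(s) s2c(toupper(s)))),
                nrow = n, byrow = TRUE, dimnames = list(names(seqs), NULL))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  SAT <- matrix(FALSE, n, n, dimnames = dimnames(D))
  purine <- c("A", "G")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chm[i, ]; b <- chm[j, ]
    comp <- a %in% DNA_BASES & b %in% DNA_BASES
    m <- sum(comp)
    if (m == 0) stop("pair with zero comparable columns: ",
                     names(seqs)[i], " / ", names(seqs)[j])
    diff <- a[comp] != b[comp]
    p <- sum(diff) / m
    d <- switch(model,
      p = p,
      JC69 = {
        if (p >= 0.75) { SAT[i, j] <- SAT[j, i] <- TRUE; max_distance }
        else -0.75 * log(1 - 4 * p / 3)
      },
      K80 = {
        ts <- sum(diff & (a[comp] %in% purine) == (b[comp] %in% purine)) / m
        tv <- p - ts
        w1 <- 1 - 2 * ts - tv; w2 <- 1 - 2 * tv
        if (w1 <= 0 || w2 <= 0) { SAT[i, j] <- SAT[j, i] <- TRUE; max_distance }
        else -0.5 * log(w1) - 0.25 * log(w2)
      },
      `GTR-ML-pairwise` = {
        pars <- gtr_params %||% gtr_params()
        f <- function(t) gtr_gi_loglik(two_taxon_tree(names(seqs)[c(i, j)], t),
                                       seqs[c(i, j)], pars)$loglik
        opt <- stats::optimize(f, c(1e-8, max_distance), maximum = TRUE,
                               tol = 1e-6)
        opt$maximum
      })
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- SAT
  D
}

two_taxon_tree <- function(labels, t_total) {
  tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                      labels[1], t_total / 2,
                                      labels[2], t_total / 2))
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape) on a symmetric matrix.
#'
#' @param D symmetric distance matrix with labels
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' GTR+G+I parameter set
#'
#' Six symmetric exchangeabilities (order AC, AG, AT, CG, CT, GT), base
#' frequencies summing to 1, gamma shape alpha with `ncat` equal-probability
#' categories (category rate = bin mean), and an invariant-site proportion.
#' The rate matrix is normalized to one expected substitution per site per
#' unit branch length (the invariant class included).
#'
#' @param rates exchangeabilities (AC, AG, AT, CG, CT, GT)
#' @param freqs base frequencies (A, C, G, T)
#' @param alpha gamma shape (> 0)
#' @param p_inv invariant proportion in [0, 1)
#' @param ncat number of gamma categories
#' @return object of class `gtr_params`
#' @export
gtr_params <- function(rates = c(1, 1, 1, 1, 1, 1),
                       freqs = c(0.25, 0.25, 0.25, 0.25),
                       alpha = Inf, p_inv = 0, ncat = 4) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(freqs) == 4, abs(sum(freqs) - 1) < 1e-6,
            alpha > 0, p_inv >= 0, p_inv < 1)
  structure(list(rates = rates, freqs = freqs / sum(freqs),
                 alpha = alpha, p_inv = p_inv, ncat = as.integer(ncat)),
            class = "gtr_params")
}

## GTR rate matrix, normalized to mean rate 1, with eigendecomposition
gtr_eigen <- function(params) {
  r <- params$rates; f <- params$freqs
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  Q["A", "C"] <- r[1] * f[2]; Q["A", "G"] <- r[2] * f[3]
  Q["A", "T"] <- r[3] * f[4]
  Q["C", "A"] <- r[1] * f[1]; Q["C", "G"] <- r[4] * f[3]
  Q["C", "T"] <- r[5] * f[4]
  Q["G", "A"] <- r[2] * f[1]; Q["G", "C"] <- r[4] * f[2]
  Q["G", "T"] <- r[6] * f[4]
  Q["T", "A"] <- r[3] * f[1]; Q["T", "C"] <- r[5] * f[2]
  Q["T", "G"] <- r[6] * f[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q <- Q / mu
  ## reversible: symmetrize with sqrt(pi) similarity transform
  sp <- sqrt(f)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(Q = Q, values = es$values,
       U = diag(1 / sp) %*% es$vectors,
       Uinv = t(es$vectors) %*% diag(sp))
}

gtr_pmatrix <- function(eig, t) {
  P <- eig$U %*% diag(exp(eig$values * t)) %*% eig$Uinv
  P[P < 0] <- 0
  P
}

## equal-probability discrete gamma category rates (bin means)
gamma_category_rates <- function(alpha, ncat) {
  if (!is.finite(alpha)) return(rep(1, ncat))
  b <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  r <- ncat * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r) * 1  # exact mean 1
}

## pattern-compressed alignment: list(states (n x npat integer, NA = missing),
## weight, index of each original column)
compress_alignment <- function(seqs) {
  chm <- matrix(unlist(lapply(seqs, function(s) s2c(toupper(s)))),
                nrow = length(seqs), byrow = TRUE)
  key <- apply(chm, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  map <- match(key, key[u])
  states <- matrix(match(chm[, u, drop = FALSE], DNA_BASES),
                   nrow = nrow(chm))
  list(states = states, weight = as.numeric(tabulate(map, sum(u))),
       map = map, n = nrow(chm), npat = sum(u),
       labels = names(seqs))
}

tip_partial <- function(states_row, npat) {
  Lp <- matrix(0, 4, npat)
  known <- !is.na(states_row)
  Lp[cbind(states_row[known], which(known))] <- 1
  Lp[, !known] <- 1
  Lp
}

## internal engine: postorder partials for one rate category
## tree must be in postorder; returns list(partials per node, logscale per node)
prune_partials <- function(tree, tips, rate, eig, npat) {
  nnode <- max(tree$edge)
  D <- vector("list", nnode)
  sc <- vector("list", nnode)
  ntip <- length(tree$tip.label)
  for (i in seq_len(ntip)) { D[[i]] <- tips[[i]]; sc[[i]] <- rep(0, npat) }
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    P <- gtr_pmatrix(eig, tree$edge.length[k] * rate)
    contrib <- P %*% D[[v]]
    if (is.null(D[[p]])) { D[[p]] <- contrib; sc[[p]] <- sc[[v]] }
    else { D[[p]] <- D[[p]] * contrib; sc[[p]] <- sc[[p]] + sc[[v]] }
    if (v > ntip || k %% 8 == 0) {  # rescale occasionally
      mx <- apply(D[[p]], 2, max)
      mx[mx <= 0] <- 1
      D[[p]] <- sweep(D[[p]], 2, mx, "/")
      sc[[p]] <- sc[[p]] + log(mx)
    }
  }
  root <- tree$edge[nrow(tree$edge), 1]
  list(D = D, sc = sc, root = root)
}

#' GTR+G+I log-likelihood by Felsenstein pruning
#'
#' Four discrete gamma categories (equal-probability bins, category rate =
#' bin mean) plus an invariant class; gamma category rates are rescaled by
#' 1/(1 - p_inv) so the expected substitution rate stays 1. Gaps and
#' ambiguity codes are treated as missing data. Site log-likelihoods are
#' exposed.
#'
#' @param tree `phylo` tree whose tips match the alignment names
#' @param alignment named character vector or [mask_columns()] result
#' @param params [gtr_params()] object
#' @return list with `loglik` and `site_loglik` (per original column)
#' @export
gtr_gi_loglik <- function(tree, alignment, params = gtr_params()) {
  seqs <- aln_strings(alignment)
  if (!all(sort(tree$tip.label) == sort(names(seqs))))
    stop("tree tips and alignment sequences differ")
  if (nchar(seqs[[1]]) == 0) stop("zero-length alignment")
  comp <- compress_alignment(seqs[tree$tip.label])
  eig <- gtr_eigen(params)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  tips <- lapply(seq_len(ntip), function(i) tip_partial(comp$states[i, ], comp$npat))
  rates <- gamma_category_rates(params$alpha, params$ncat)
  if (params$p_inv > 0) rates <- rates / (1 - params$p_inv)
  f <- params$freqs
  ## gamma categories
  lik_log <- matrix(NA_real_, length(rates), comp$npat)
  for (c_i in seq_along(rates)) {
    pr <- prune_partials(tree, tips, rates[c_i], eig, comp$npat)
    rootlik <- colSums(pr$D[[pr$root]] * f)
    lik_log[c_i, ] <- log(pmax(rootlik, 1e-300)) + pr$sc[[pr$root]]
  }
  w <- (1 - params$p_inv) / length(rates)
  mx <- apply(lik_log, 2, max)
  site_lik <- w * colSums(exp(sweep(lik_log, 2, mx, "-")))
  if (params$p_inv > 0) {
    ## invariant class: product of tip partials, no substitution
    con <- Reduce(`*`, tips)
    inv <- colSums(con * f)
    site_lik <- site_lik + params$p_inv * inv * exp(-mx)
  }
  site_loglik_pat <- log(site_lik) + mx
  site_loglik <- site_loglik_pat[comp$map]
  list(loglik = sum(site_loglik_pat * comp$weight), site_loglik = site_loglik)
}

#' Optimize branch lengths by coordinate ascent
#'
#' Per-branch scalar bracketing search (Brent) against the GTR+G+I
#' likelihood, with partials cached per sweep, iterated until the
#' log-likelihood gain of a sweep drops below `tol`. The reported likelihood
#' trace never decreases: a sweep that fails to improve is reverted and the
#' search stops.
#'
#' @param tree starting `phylo` tree with branch lengths
#' @param alignment named character vector or [mask_columns()] result
#' @param params [gtr_params()] object
#' @param tol convergence tolerance on the per-sweep log-likelihood gain
#' @param max_sweeps cap on coordinate-ascent sweeps
#' @param max_branch upper bound for any single branch length
#' @return list with `tree` (optimized), `loglik`, `trace` (per-sweep
#'   log-likelihoods, monotone non-decreasing)
#' @export
optimize_branch_lengths <- function(tree, alignment, params = gtr_params(),
                                    tol = 1e-6, max_sweeps = 20,
                                    max_branch = 10) {
  seqs <- aln_strings(alignment)
  comp <- compress_alignment(seqs[tree$tip.label])
  eig <- gtr_eigen(params)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  tips <- lapply(seq_len(ntip), function(i) tip_partial(comp$states[i, ], comp$npat))
  rates <- gamma_category_rates(params$alpha, params$ncat)
  if (params$p_inv > 0) rates <- rates / (1 - params$p_inv)
  f <- params$freqs
  w_cat <- (1 - params$p_inv) / length(rates)
  nE <- nrow(tree$edge)
  root <- tree$edge[nE, 1]

  con <- Reduce(`*`, tips)
  inv_lik <- if (params$p_inv > 0) colSums(con * f) else rep(0, comp$npat)

  total_loglik <- function(tr) gtr_gi_loglik(tr, seqs, params)$loglik

  cur <- total_loglik(tree)
  trace <- cur
  for (sweep_i in seq_len(max_sweeps)) {
    old_tree <- tree
    ## cache partials per category: D (below), G (above, pi-weighted)
    Ds <- Gs <- vector("list", length(rates))
    for (c_i in seq_along(rates)) {
      pr <- prune_partials(tree, tips, rates[c_i], eig, comp$npat)
      D <- pr$D; dsc <- pr$sc
      G <- vector("list", max(tree$edge)); gsc <- vector("list", max(tree$edge))
      G[[root]] <- matrix(f, 4, comp$npat); gsc[[root]] <- rep(0, comp$npat)
      ## preorder = reversed postorder edges
      for (k in rev(seq_len(nE))) {
        p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
        sibs <- which(tree$edge[, 1] == p & tree$edge[, 2] != v)
        M <- G[[p]]; msc <- gsc[[p]]
        for (sk in sibs) {
          sP <- gtr_pmatrix(eig, tree$edge.length[sk] * rates[c_i])
          M <- M * (sP %*% D[[tree$edge[sk, 2]]])
          msc <- msc + dsc[[tree$edge[sk, 2]]]
        }
        P <- gtr_pmatrix(eig, tree$edge.length[k] * rates[c_i])
        G[[v]] <- t(P) %*% M
        mx <- apply(G[[v]], 2, max); mx[mx <= 0] <- 1
        G[[v]] <- sweep(G[[v]], 2, mx, "/")
        gsc[[v]] <- msc + log(mx)
      }
      Ds[[c_i]] <- list(D = D, sc = dsc)
      Gs[[c_i]] <- list(G = G, sc = gsc, M = NULL)
    }
    ## per-edge objective using cached partials: for edge (p,v),
    ## L_c(t) = sum_x M_x (P(t) D_v)_x with M = G_p * prod(sib contribs)
    for (k in seq_len(nE)) {
      p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
      Ms <- msc_list <- vector("list", length(rates))
      for (c_i in seq_along(rates)) {
        sibs <- which(tree$edge[, 1] == p & tree$edge[, 2] != v)
        M <- Gs[[c_i]]$G[[p]]; msc <- Gs[[c_i]]$sc[[p]]
        for (sk in sibs) {
          sP <- gtr_pmatrix(eig, tree$edge.length[sk] * rates[c_i])
          M <- M * (sP %*% Ds[[c_i]]$D[[tree$edge[sk, 2]]])
          msc <- msc + Ds[[c_i]]$sc[[tree$edge[sk, 2]]]
        }
        Ms[[c_i]] <- M; msc_list[[c_i]] <- msc
      }
      obj <- function(t) {
        ll <- matrix(NA_real_, length(rates), comp$npat)
        for (c_i in seq_along(rates)) {
          P <- gtr_pmatrix(eig, t * rates[c_i])
          lik <- colSums(Ms[[c_i]] * (P %*% Ds[[c_i]]$D[[v]]))
          ll[c_i, ] <- log(pmax(lik, 1e-300)) + msc_list[[c_i]] +
            Ds[[c_i]]$sc[[v]]
        }
        mx <- apply(ll, 2, max)
        site <- w_cat * colSums(exp(sweep(ll, 2, mx, "-"))) +
          params$p_inv * inv_lik * exp(-mx)
        sum((log(site) + mx) * comp$weight)
      }
      t0 <- tree$edge.length[k]
      opt <- stats::optimize(obj, c(0, max_branch), maximum = TRUE,
                             tol = 1e-6)
      if (opt$objective > obj(t0)) tree$edge.length[k] <- opt$maximum
    }
    new <- total_loglik(tree)
    if (new < cur) { tree <- old_tree; break }
    gain <- new - cur
    cur <- new
    trace <- c(trace, cur)
    if (gain < tol) break
  }
  list(tree = tree, loglik = cur, trace = trace)
}

#' Fit GTR+G+I parameters by coordinate ascent
#'
#' Base frequencies are empirical; exchangeabilities (GT fixed at 1 for
#' identifiability), alpha and p_inv are optimized one scalar at a time
#' against the pruning likelihood on a fixed tree.
#'
#' @param tree `phylo` tree with branch lengths
#' @param alignment named character vector or [mask_columns()] result
#' @param init starting [gtr_params()]
#' @param sweeps number of coordinate-ascent sweeps
#' @param fit_alpha,fit_pinv optimize the gamma shape / invariant proportion?
#' @return fitted [gtr_params()] object with attribute `loglik`
#' @export
fit_gtr_params <- function(tree, alignment, init = NULL, sweeps = 2,
                           fit_alpha = TRUE, fit_pinv = TRUE) {
  seqs <- aln_strings(alignment)
  ch <- unlist(strsplit(toupper(unlist(seqs)), ""))
  tabf <- table(factor(ch, levels = DNA_BASES))
  freqs <- as.numeric(tabf) / sum(tabf)
  pars <- init %||% gtr_params(freqs = freqs, alpha = 1, p_inv = 0.05)
  pars$freqs <- freqs
  ll <- function(p) gtr_gi_loglik(tree, seqs, p)$loglik
  for (s in seq_len(sweeps)) {
    for (i in 1:5) {  # GT (6th) fixed at 1
      f <- function(x) { q <- pars; q$rates[i] <- x; ll(q) }
      pars$rates[i] <- stats::optimize(f, c(0.02, 50), maximum = TRUE,
                                       tol = 1e-3)$maximum
    }
    if (fit_alpha) {
      f <- function(x) { q <- pars; q$alpha <- x; ll(q) }
      pars$alpha <- stats::optimize(f, c(0.05, 50), maximum = TRUE,
                                    tol = 1e-3)$maximum
    }
    if (fit_pinv) {
      f <- function(x) { q <- pars; q$p_inv <- x; ll(q) }
      pars$p_inv <- stats::optimize(f, c(0, 0.9), maximum = TRUE,
                                    tol = 1e-3)$maximum
    }
  }
  attr(pars, "loglik") <- ll(pars)
  pars
}

#' Bootstrap support for the splits of a reference tree
#'
#' Resamples alignment columns with replacement B times, rebuilds a tree per
#' replicate with `build_fun`, and reports, for each non-trivial split of the
#' reference tree, the percentage of replicates containing that split.
#'
#' @param alignment named character vector or [mask_columns()] result
#' @param build_fun function(alignment) -> `phylo`
#' @param B number of bootstrap replicates (>= 1)
#' @param seed RNG seed for the resampling
#' @param reference_tree optional reference tree; default `build_fun` on the
#'   original alignment
#' @return list with `tree` (reference with node labels = support),
#'   `support` (per-split percentages), `splits` (tip sets)
#' @export
bootstrap_support <- function(alignment, build_fun, B = 1000, seed = 1,
                              reference_tree = NULL) {
  if (B < 1) stop("B must be >= 1")
  seqs <- aln_strings(alignment)
  ref <- reference_tree %||% build_fun(seqs)
  refsp <- tree_splits(ref)
  if (!length(refsp))
    return(list(tree = ref, support = numeric(0), splits = list()))
  counts <- numeric(length(refsp))
  L <- nchar(seqs[[1]])
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(L, L, replace = TRUE)
      bs <- vapply(seqs, function(s) c2s(s2c(s)[idx]), character(1))
      tr <- build_fun(bs)
      sp <- tree_splits(tr)
      counts <- counts + (vapply(refsp, function(x)
        any(vapply(sp, identical, logical(1), x)), logical(1)))
    }
  })
  support <- 100 * counts / B
  ## attach as node labels on the internal nodes defining each split
  ref2 <- ref
  ref2$node.label <- rep("", ref$Nnode)
  spl_nodes <- attr(refsp, "nodes")
  ref2$node.label[spl_nodes - length(ref$tip.label)] <-
    sprintf("%g", support)
  list(tree = ref2, support = support, splits = refsp)
}

## non-trivial splits of an unrooted tree as canonical sorted tip-label sets
## (the side not containing the alphabetically first label)
tree_splits <- function(tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  anchor <- sort(tr$tip.label)[1]
  desc <- descendant_tips(tr)
  out <- list(); nodes <- integer(0)
  for (node in (ntip + 1):(ntip + tr$Nnode)) {
    tipset <- desc[[node]]
    if (length(tipset) <= 1 || length(tipset) >= ntip - 1) next
    side <- sort(tipset)
    if (anchor %in% side) side <- sort(setdiff(tr$tip.label, side))
    key <- side
    if (!any(vapply(out, identical, logical(1), key))) {
      out[[length(out) + 1]] <- key
      nodes <- c(nodes, node)
    }
  }
  attr(out, "nodes") <- nodes
  out
}

## tip labels below every node
descendant_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  res <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) res[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    res[[p]] <- c(res[[p]], res[[v]])
  }
  res
}

#' Robinson-Foulds distance
#'
#' Symmetric difference of the non-trivial splits of two trees over the same
#' tip set.
#'
#' @param t1,t2 `phylo` trees
#' @return integer RF distance
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("tip sets differ")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  in2 <- vapply(s1, function(x) any(vapply(s2, identical, logical(1), x)),
                logical(1))
  in1 <- vapply(s2, function(x) any(vapply(s1, identical, logical(1), x)),
                logical(1))
  sum(!in2) + sum(!in1)
}

#' Monophyly of a taxon set after rooting at an outgroup
#'
#' TRUE iff the taxon set is exactly the tip set of one clade of the tree
#' rooted at the outgroup taxon.
#'
#' @param tree `phylo` tree
#' @param taxa character vector of tip labels
#' @param outgroup a single tip label, not in `taxa`
#' @return logical flag
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  stopifnot(all(c(taxa, outgroup) %in% tree$tip.label))
  if (outgroup %in% taxa) stop("outgroup inside the query set")
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup,
                  resolve.root = TRUE)
  desc <- descendant_tips(rt)
  any(vapply(desc, function(x) setequal(x, taxa), logical(1)))
}
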