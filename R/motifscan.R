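## PSSM-based protein motif scanning with exact null p-values.
##
## Matrices are seeded from windows of a reference alignment (sequences with
## indels in the window, or below an identity floor against the reference
## window, are excluded), scores are discretized to an integer lattice
## (1/1000 bit) and position p-values come from the exact null distribution
## of a random i.i.d.-background word, computed by convolution. A two-round
## procedure absorbs first-round matches into the matrices before the final
## scan.

#' Read motif definitions from a tab-separated table
#'
#' Columns: name, start, end (1-based inclusive coordinates on the ungapped
#' reference protein).
#'
#' @param path file path
#' @return data.frame with name, start, end, width
#' @export
read_motif_defs <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "start", "end") %in% names(d)))
  d$width <- d$end - d$start + 1L
  if (any(d$width < 1)) stop("motif end precedes start")
  d
}

## map ungapped reference positions to alignment columns
ref_column_map <- function(ref_row) {
  which(s2c(ref_row) != "-")
}

#' Extract per-motif seed windows from a reference alignment
#'
#' Locates each motif's alignment columns through the reference row, then
#' keeps, per motif, the sequences that (i) have no indel relative to the
#' reference inside the window and (ii) reach at least `min_identity` percent
#' identity to the reference window. Returns ungapped seed strings; the
#' reference window is always retained.
#'
#' @param ref_alignment named character vector: one aligned protein per
#'   species, equal lengths, gaps as `-`; must include `reference`
#' @param defs motif definition data.frame (name, start, end)
#' @param min_identity identity floor in percent (default 60)
#' @param reference name of the reference row
#' @return named list: per motif, a character vector of seed strings
#' @export
extract_reference_motifs <- function(ref_alignment, defs, min_identity = 60,
                                     reference = "D.melanogaster") {
  if (!reference %in% names(ref_alignment))
    stop("reference sequence '", reference, "' not in alignment")
  refrow <- ref_alignment[[reference]]
  cmap <- ref_column_map(refrow)
  nref <- length(cmap)
  out <- list()
  for (i in seq_len(nrow(defs))) {
    nm <- defs$name[i]; st <- defs$start[i]; en <- defs$end[i]
    if (st < 1 || en > nref)
      stop("motif ", nm, " outside the ungapped reference length (", nref, ")")
    cols <- cmap[st]:cmap[en]
    refcols <- cmap[st:en]                 # columns holding reference residues
    inscols <- setdiff(cols, refcols)      # insertion columns inside window
    refseed <- c2s(s2c(refrow)[refcols])
    seeds <- c()
    for (sp in names(ref_alignment)) {
      ch <- s2c(ref_alignment[[sp]])
      if (any(ch[refcols] == "-")) next                # deletion vs reference
      if (length(inscols) && any(ch[inscols] != "-")) next  # insertion
      win <- c2s(ch[refcols])
      if (sp != reference) {
        ident <- 100 * sum(ch[refcols] == s2c(refrow)[refcols]) / length(refcols)
        if (ident < min_identity) next
      }
      seeds[sp] <- win
    }
    if (!reference %in% names(seeds)) seeds[reference] <- refseed
    out[[nm]] <- seeds
  }
  out
}

#' Build a position-specific scoring matrix from seed windows
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`; entries are `log2(probability / background)`,
#' discretized to a 1/1000-bit integer lattice for exact null computation.
#'
#' @param seeds equal-length protein strings
#' @param pseudocount total pseudocount weight, allocated proportionally to
#'   the background
#' @param background length-20 amino-acid frequency vector (sums to 1)
#' @param lattice_scale lattice units per bit
#' @return object of class `pssm`
#' @export
build_pssm <- function(seeds, pseudocount = 1,
                       background = rep(1 / 20, 20), lattice_scale = 1000) {
  if (length(seeds) < 1) stop("at least one seed required")
  w <- unique(nchar(seeds))
  if (length(w) != 1) stop("seed length mismatch")
  stopifnot(abs(sum(background) - 1) < 1e-8, lattice_scale > 0)
  background <- setNames(background, AMINO_ACIDS)
  n <- length(seeds)
  counts <- matrix(0, w, 20, dimnames = list(NULL, AMINO_ACIDS))
  for (s in seeds) {
    ch <- s2c(s)
    for (p in seq_len(w))
      if (ch[p] %in% AMINO_ACIDS)
        counts[p, ch[p]] <- counts[p, ch[p]] + 1
  }
  prob <- (counts + pseudocount * matrix(background, w, 20, byrow = TRUE)) /
    (n + pseudocount)
  logodds <- log2(sweep(prob, 2, background, "/"))
  ## letters with zero background frequency cannot occur under the null;
  ## give them a strongly negative finite score for scanning
  logodds[!is.finite(logodds)] <- -100
  lattice <- matrix(as.integer(round(logodds * lattice_scale)), w, 20,
                    dimnames = list(NULL, AMINO_ACIDS))
  obj <- structure(list(width = w, n_seeds = n, prob = prob,
                        logodds = logodds, lattice = lattice,
                        background = background, pseudocount = pseudocount,
                        lattice_scale = lattice_scale, null = NULL),
                   class = "pssm")
  obj$null <- pssm_null_distribution(obj)
  obj
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d, %d seeds, lattice 1/%d bit\n",
              x$width, x$n_seeds, x$lattice_scale))
  invisible(x)
}

#' Exact null distribution of the PSSM lattice score
#'
#' Distribution of the total lattice score of a random width-w word with
#' i.i.d. background letters, by exact convolution across positions.
#'
#' @param pssm a [build_pssm()] object
#' @param background optional override of the background frequencies
#' @return list with `min`, `max`, `prob` (probability vector over
#'   consecutive lattice scores) and `tail(s)`, a function returning
#'   P(score >= s)
#' @export
pssm_null_distribution <- function(pssm, background = pssm$background) {
  res <- .pssm_null_cpp(pssm$lattice, as.numeric(background))
  prob <- res$prob
  lo <- res$min
  hi <- lo + length(prob) - 1
  tailvec <- rev(cumsum(rev(prob)))
  tailfun <- function(s) {
    ifelse(s <= lo, 1.0, ifelse(s > hi, 0.0, tailvec[pmax(s - lo + 1, 1)]))
  }
  list(min = lo, max = hi, prob = prob, tail = tailfun)
}

## lattice score of every window of `protein`; NA for windows containing
## letters outside the 20-letter alphabet
window_scores <- function(pssm, protein) {
  ch <- s2c(protein)
  L <- length(ch)
  w <- pssm$width
  if (L < w) return(integer(0))
  idx <- match(ch, AMINO_ACIDS)
  n_win <- L - w + 1
  sc <- rep(0L, n_win)
  ok <- rep(TRUE, n_win)
  for (p in seq_len(w)) {
    v <- idx[p:(p + n_win - 1)]
    bad <- is.na(v)
    ok <- ok & !bad
    v[bad] <- 1L
    sc <- sc + pssm$lattice[cbind(p, v)]
  }
  sc[!ok] <- NA_integer_
  sc
}

#' Scan a protein with a PSSM
#'
#' Scores every window, converts lattice scores to position p-values through
#' the exact null tail, and reports all windows with p below the threshold
#' plus the best-scoring window. Windows containing non-standard letters are
#' not scored.
#'
#' @param pssm a [build_pssm()] object
#' @param protein protein string
#' @param threshold position p-value threshold (default 1e-6)
#' @param sequence_id optional id copied into the hit table
#' @param length_correct if TRUE, threshold the length-corrected p-value
#'   `1 - (1 - p)^(L - w + 1)` (the chance of at least one such window in a
#'   sequence of this length) instead of the position p-value
#' @return data.frame with sequence_id, start (0-based), score (lattice),
#'   bits, p_value, passes_threshold, best (and p_corrected when
#'   `length_correct` is set)
#' @export
scan_sequence <- function(pssm, protein, threshold = 1e-6,
                          sequence_id = NA_character_,
                          length_correct = FALSE) {
  sc <- window_scores(pssm, protein)
  if (!length(sc) || all(is.na(sc)))
    return(data.frame(sequence_id = character(), start = integer(),
                      score = integer(), bits = numeric(),
                      p_value = numeric(), passes_threshold = logical(),
                      best = logical()))
  p <- pssm$null$tail(sc)
  p[is.na(sc)] <- NA_real_
  n_win <- length(sc)
  p_eff <- if (length_correct) 1 - (1 - p)^n_win else p
  pass <- !is.na(p_eff) & p_eff < threshold
  best <- which.max(ifelse(is.na(sc), -Inf, sc))
  keep <- which(pass | seq_along(sc) == best)
  out <- data.frame(sequence_id = sequence_id, start = keep - 1L,
                    score = sc[keep], bits = sc[keep] / pssm$lattice_scale,
                    p_value = p[keep], passes_threshold = pass[keep],
                    best = keep == best)
  if (length_correct) out$p_corrected <- p_eff[keep]
  out
}

#' Two-round iterative motif scan
#'
#' Round 1 scans all queries with matrices built from the seed windows.
#' Windows matched at the p-value threshold are pooled with the original
#' seeds, matrices are rebuilt, and round 2 rescans every query; final calls
#' come from the round-2 p-values.
#'
#' @param seeds named list: per motif, a character vector of seed windows
#' @param queries named character vector of query proteins
#' @param rounds number of rounds (>= 1; default 2)
#' @param threshold position p-value threshold (default 1e-6)
#' @param pseudocount,background passed to [build_pssm()]
#' @return list with `hits` (final hit table over all motifs and queries),
#'   `matrices` (final-round PSSM per motif) and `round_hits` (per-round hit
#'   tables)
#' @export
iterative_scan <- function(seeds, queries, rounds = 2, threshold = 1e-6,
                           pseudocount = 1, background = rep(1 / 20, 20)) {
  stopifnot(rounds >= 1)
  cur_seeds <- seeds
  round_hits <- list()
  matrices <- NULL
  hits <- NULL
  for (r in seq_len(rounds)) {
    matrices <- lapply(cur_seeds, build_pssm, pseudocount = pseudocount,
                       background = background)
    tabs <- list()
    for (m in names(matrices)) {
      for (q in names(queries)) {
        h <- scan_sequence(matrices[[m]], queries[[q]], threshold,
                           sequence_id = q)
        if (nrow(h)) h$motif <- m
        tabs[[length(tabs) + 1]] <- h
      }
    }
    hits <- do.call(rbind, tabs[lengths(tabs) > 0])
    round_hits[[r]] <- hits
    if (r < rounds) {
      for (m in names(matrices)) {
        hm <- hits[!is.na(hits$motif) & hits$motif == m &
                     hits$passes_threshold, , drop = FALSE]
        if (nrow(hm)) {
          wins <- vapply(seq_len(nrow(hm)), function(i)
            substr(queries[[hm$sequence_id[i]]], hm$start[i] + 1,
                   hm$start[i] + matrices[[m]]$width), character(1))
          cur_seeds[[m]] <- c(cur_seeds[[m]], unname(wins))
        }
      }
    }
  }
  list(hits = hits, matrices = matrices, round_hits = round_hits)
}

#' Check conservation of a single reference residue across an alignment
#'
#' A residue specification like "R1101" names the expected amino acid and its
#' 1-based position on the ungapped reference protein. The position is mapped
#' through the alignment; each sequence is flagged TRUE iff it carries the
#' specified residue at the mapped column. A gap is reported as FALSE with a
#' gap annotation.
#'
#' @param alignment named character vector of aligned proteins
#' @param residue_spec e.g. "R1101"
#' @param reference name of the reference row
#' @return data.frame with sequence, residue (observed), conserved, is_gap
#' @export
check_residue_conservation <- function(alignment, residue_spec,
                                       reference = "D.melanogaster") {
  m <- regmatches(residue_spec,
                  regexec("^([A-Z])([0-9]+)$", residue_spec))[[1]]
  if (length(m) != 3) stop("bad residue spec: ", residue_spec)
  aa <- m[2]; pos <- as.integer(m[3])
  if (!reference %in% names(alignment)) stop("reference not in alignment")
  cmap <- ref_column_map(alignment[[reference]])
  if (pos > length(cmap)) stop("position beyond ungapped reference length")
  col <- cmap[pos]
  obs <- vapply(alignment, function(s) substr(s, col, col), character(1))
  data.frame(sequence = names(alignment), residue = unname(obs),
             conserved = unname(obs == aa), is_gap = unname(obs == "-"),
             row.names = NULL)
}
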