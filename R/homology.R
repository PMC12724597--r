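## Translated homology search and gene-copy classification.
##
## The search re-implements a tBLASTn-like strategy: exact word seeding in all
## six reading frames, then locally optimal affine-gap extension (full
## Smith-Waterman per seeded frame, iterated with subject masking so several
## HSPs per frame can be reported). Raw-score thresholds are used instead of
## E-values.

#' Default search parameters for the translated homology search
#'
#' tBLASTn-like defaults: BLOSUM62, gap open 11 / extend 1, word size 3.
#' A raw-score threshold replaces E-value statistics.
#'
#' @param substitution_matrix scoring matrix over the amino-acid alphabet
#' @param gap_open,gap_extend affine gap penalties (gap of length k costs
#'   `gap_open + k * gap_extend`)
#' @param word_size exact-word seed length
#' @param min_raw_score minimal reported HSP raw score
#' @param max_hits_per_frame cap on HSPs reported per frame
#' @return a named list of parameters
#' @export
search_params <- function(substitution_matrix = blosum62, gap_open = 11,
                          gap_extend = 1, word_size = 3, min_raw_score = 60,
                          max_hits_per_frame = 25, x_dropoff = 30) {
  list(substitution_matrix = substitution_matrix, gap_open = gap_open,
       gap_extend = gap_extend, word_size = word_size,
       min_raw_score = min_raw_score, max_hits_per_frame = max_hits_per_frame,
       x_dropoff = x_dropoff)
}

#' Six-frame translation
#'
#' Frames +1..+3 translate the forward sequence at offsets 0, 1, 2; frames
#' -1..-3 translate the reverse complement at the same offsets. Codons
#' containing N translate to X; trailing partial codons are dropped.
#'
#' @param dna a nucleotide string over A, C, G, T, N
#' @return named character vector of six protein strings
#'   (names `+1`, `+2`, `+3`, `-1`, `-2`, `-3`)
#' @export
six_frame_translate <- function(dna) {
  dna <- check_dna(dna)
  rc <- revcomp(dna)
  frames <- c(
    `+1` = substring(dna, 1), `+2` = substring(dna, 2), `+3` = substring(dna, 3),
    `-1` = substring(rc, 1), `-2` = substring(rc, 2), `-3` = substring(rc, 3))
  vapply(frames, translate_cds, character(1))
}

## does any exact word of length w from `query` occur in `subject`?
has_word_seed <- function(query, subject, w) {
  nq <- nchar(query)
  if (nq < w || nchar(subject) < w) return(FALSE)
  words <- unique(substring(query, 1:(nq - w + 1), w:nq))
  any(vapply(words, function(x) grepl(x, subject, fixed = TRUE), logical(1)))
}

#' Search a protein query against a nucleotide contig (tBLASTn-like)
#'
#' Translates the contig in six frames, seeds frames containing an exact
#' word match to the query, and reports locally optimal affine-gap HSPs per
#' seeded frame. Subject coordinates are always reported on the forward
#' strand (0-based, half-open) with the frame sign carrying the strand.
#'
#' @param query protein string
#' @param contig nucleotide string
#' @param params list as produced by [search_params()]
#' @return data.frame with columns query_start, query_end, subject_start,
#'   subject_end, frame, raw_score, percent_identity, n_ident, aln_len
#' @export
search_protein_vs_contig <- function(query, contig, params = search_params()) {
  if (!nzchar(query) || !nzchar(contig)) stop("empty query or contig")
  if (nchar(query) < params$word_size)
    stop("query shorter than word size")
  frames <- six_frame_translate(contig)
  L <- nchar(contig)
  ab <- rownames(params$substitution_matrix)
  qenc <- encode_seq(query, ab)
  out <- list()
  for (fr in names(frames)) {
    tr <- frames[[fr]]
    if (!has_word_seed(query, tr, params$word_size)) next
    res <- .sw_local_cpp(qenc, encode_seq(tr, ab),
                         params$substitution_matrix,
                         params$gap_open, params$gap_extend,
                         params$min_raw_score, params$max_hits_per_frame)
    if (!length(res$score)) next
    rows <- frame_hsps(res, query, tr, fr, L, params)
    if (!is.null(rows)) out[[fr]] <- rows
  }
  if (!length(out))
    return(data.frame(query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      frame = integer(), raw_score = numeric(),
                      percent_identity = numeric(), n_ident = integer(),
                      aln_len = integer(), stops = character()))
  hs <- do.call(rbind, out)
  hs <- hs[order(-hs$raw_score), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}

#' Default thresholds for gene-copy classification
#'
#' @param min_coverage_intact minimal query coverage for an intact call
#' @param min_fragment_score minimal chain score to report a fragment
#' @param min_intron between-HSP genomic gaps of at least this many bp are
#'   treated as introns: they are exempt from the frameshift (mod-3) rule and
#'   are not scanned for stop codons
#' @param min_missing_segment minimal missing query segment (residues)
#'   considered when looking for inverted segments
#' @return a named list
#' @export
classify_thresholds <- function(min_coverage_intact = 0.9,
                                min_fragment_score = 35,
                                min_intron = 40,
                                min_missing_segment = 10) {
  list(min_coverage_intact = min_coverage_intact,
       min_fragment_score = min_fragment_score,
       min_intron = min_intron,
       min_missing_segment = min_missing_segment)
}

## Post-process one frame's raw local alignments into HSPs.
##
## A full (non-seeded, non-dropped) local alignment happily aligns *through*
## a low-scoring stretch such as an intron when the flanking similarity pays
## for it; seeded extension with an X-dropoff would have terminated there and
## reported per-exon HSPs. We recover that behavior by splitting each raw
## alignment wherever the running column score falls `x_dropoff` below its
## maximum, keeping sub-segments above the score threshold. In-frame stop
## codons are recorded for aligned (M) columns only.
frame_hsps <- function(res, query, tr, fr, L, params) {
  qc <- s2c(query); trc <- s2c(tr)
  mat <- params$substitution_matrix
  k <- abs(as.integer(fr))
  rows <- list()
  for (i in seq_along(res$score)) {
    ops <- s2c(res$cigar[i])
    n <- length(ops)
    qpos <- spos <- integer(n)  # 0-based positions consumed at each column
    colsc <- numeric(n)
    qp <- res$query_start[i]; sp <- res$subject_start[i]
    in_gap <- FALSE
    for (cidx in seq_len(n)) {
      op <- ops[cidx]
      qpos[cidx] <- qp; spos[cidx] <- sp
      if (op == "M") {
        colsc[cidx] <- mat[qc[qp + 1], trc[sp + 1]]
        qp <- qp + 1; sp <- sp + 1; in_gap <- FALSE
      } else {
        colsc[cidx] <- -params$gap_extend - if (in_gap) 0 else params$gap_open
        in_gap <- TRUE
        if (op == "I") qp <- qp + 1 else sp <- sp + 1
      }
    }
    ## X-dropoff style segmentation of the column-score sequence
    segs <- list()
    cur <- 0; best <- 0; best_j <- 0; start <- 1
    flush <- function(j_end) {
      if (best >= params$min_raw_score && best_j >= start)
        segs[[length(segs) + 1]] <<- c(start, best_j, best)
    }
    for (j in seq_len(n)) {
      cur <- cur + colsc[j]
      if (cur > best) { best <- cur; best_j <- j }
      if (cur < 0 || best - cur >= params$x_dropoff) {
        flush(j); cur <- 0; best <- 0; start <- j + 1; best_j <- j
      }
    }
    flush(n)
    for (sg in segs) {
      a <- sg[1]; b <- sg[2]
      ## trim leading non-M columns
      while (a <= b && ops[a] != "M") a <- a + 1
      if (a > b) next
      sel <- a:b
      msel <- sel[ops[sel] == "M"]
      qs <- qpos[a]; qe <- qpos[b] + (ops[b] != "D")
      ss <- spos[a]; se <- spos[b] + (ops[b] != "I")
      nid <- sum(qc[qpos[msel] + 1] == trc[spos[msel] + 1])
      stop_m <- msel[trc[spos[msel] + 1] == "*"]
      stops <- paste(vapply(stop_m, function(cx) {
        ntpos <- if (startsWith(fr, "-")) L - (k - 1) - 3 * (spos[cx] + 1)
                 else (k - 1) + 3 * spos[cx]
        paste0(qpos[cx], ":", ntpos)
      }, character(1)), collapse = ",")
      sstart <- if (startsWith(fr, "-")) L - (k - 1) - 3 * se
                else (k - 1) + 3 * ss
      send <- if (startsWith(fr, "-")) L - (k - 1) - 3 * ss
              else (k - 1) + 3 * se
      rows[[length(rows) + 1]] <- data.frame(
        query_start = qs, query_end = qe,
        subject_start = sstart, subject_end = send,
        frame = as.integer(fr), raw_score = sg[3],
        percent_identity = 100 * nid / length(sel),
        n_ident = nid, aln_len = length(sel), stops = stops)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Chain HSPs colinearly and classify the gene copy
#'
#' HSPs from one (query, contig) search are chained colinearly by query
#' coordinate on the dominant strand. Small between-HSP genomic offsets that
#' are not a multiple of 3 are called frameshifts; in-frame stop codons
#' (inside HSPs, or in short in-frame gaps between chained HSPs) are called
#' premature stops; either forces status "pseudogene". Large between-HSP gaps
#' are treated as introns. Chains with no disruptions and coverage below the
#' intact threshold are "fragment", unless a missing query segment is
#' recovered on the opposite strand within the chain span, in which case the
#' copy is an "inversion_candidate" (an assembly-artifact signature). A stop
#' codon at the query's terminal position is not a disruption, and a codon
#' spanning a chained-HSP junction is not scanned for stops.
#'
#' @param hsps data.frame from [search_protein_vs_contig()]
#' @param query_length protein query length (residues)
#' @param thresholds list from [classify_thresholds()]
#' @param contig optional contig string; if supplied, HSP subject spans and
#'   short in-frame inter-HSP gaps are scanned for stop codons
#' @return an object of class `gene_copy_call`: list with status
#'   (intact / pseudogene / fragment / inversion_candidate / no_copy),
#'   disruptions (data.frame kind, position), query_coverage, chained_hsps,
#'   subject_span
#' @export
chain_and_classify <- function(hsps, query_length,
                               thresholds = classify_thresholds(),
                               contig = NULL) {
  empty_call <- function() {
    structure(list(status = "no_copy",
                   disruptions = data.frame(kind = character(),
                                            position = integer()),
                   query_coverage = 0, chained_hsps = hsps[0, ],
                   subject_span = c(NA_integer_, NA_integer_)),
              class = "gene_copy_call")
  }
  if (is.null(hsps) || nrow(hsps) == 0) return(empty_call())

  ## dominant strand by total score
  plus <- hsps$frame > 0
  strand <- if (sum(hsps$raw_score[plus]) >= sum(hsps$raw_score[!plus])) 1 else -1
  cand <- hsps[sign(hsps$frame) == strand, , drop = FALSE]
  cand <- cand[order(-cand$raw_score), , drop = FALSE]

  ## greedy chaining: accept HSPs consistent in query and subject order
  chosen <- integer(0)
  consistent <- function(i, j) {
    a <- cand[i, ]; b <- cand[j, ]
    if (a$query_start > b$query_start) { tmp <- a; a <- b; b <- tmp }
    ## exon-boundary alignments overhang into introns, so neighboring HSPs
    ## may overlap by a few dozen residues on the query
    q_ok <- b$query_start >= a$query_end - 60 &&
      b$query_end > a$query_end
    s_ok <- if (strand > 0) b$subject_start >= a$subject_end - 30 &&
              b$subject_end > a$subject_end
            else b$subject_end <= a$subject_start + 30 &&
              b$subject_start < a$subject_start
    q_ok && s_ok
  }
  for (i in seq_len(nrow(cand))) {
    if (all(vapply(chosen, function(j) consistent(i, j), logical(1))))
      chosen <- c(chosen, i)
  }
  chain <- cand[chosen, , drop = FALSE]
  chain <- chain[order(chain$query_start), , drop = FALSE]

  if (sum(chain$raw_score) < thresholds$min_fragment_score) return(empty_call())

  disruptions <- data.frame(kind = character(), position = integer())
  add_disruption <- function(kind, pos) {
    disruptions <<- rbind(disruptions,
                          data.frame(kind = kind, position = as.integer(pos)))
  }

  ## stops inside HSPs, aligned columns only. Exemptions: the query's
  ## terminal position, and junction zones where two chained HSPs overlap on
  ## the query (intron overhangs make those columns ambiguous)
  if ("stops" %in% names(chain)) {
    claimed <- integer(0)
    if (nrow(chain) > 1) {
      cover_count <- rep(0L, query_length)
      for (r in seq_len(nrow(chain))) {
        lo <- chain$query_start[r] + 1
        hi <- min(chain$query_end[r], query_length)
        cover_count[lo:hi] <- cover_count[lo:hi] + 1L
      }
      claimed <- which(cover_count > 1) - 1L  # 0-based
    }
    for (r in seq_len(nrow(chain))) {
      st <- chain$stops[r]
      if (is.na(st) || !nzchar(st)) next
      for (pair in strsplit(st, ",", fixed = TRUE)[[1]]) {
        qn <- as.integer(strsplit(pair, ":", fixed = TRUE)[[1]])
        if (qn[1] >= query_length - 1) next  # stop at the terminal residue
        if (qn[1] %in% claimed) next         # ambiguous junction column
        add_disruption("premature_stop", qn[2])
      }
    }
  }

  ## between-HSP junctions
  if (nrow(chain) >= 2) {
    for (r in seq_len(nrow(chain) - 1)) {
      a <- chain[r, ]; b <- chain[r + 1, ]
      qgap <- b$query_start - a$query_end
      sgap <- if (strand > 0) b$subject_start - a$subject_end
              else a$subject_start - b$subject_end
      off <- sgap - 3 * qgap
      ## overlapping HSPs (intron overhangs): judge the gap size as if the
      ## overlap were trimmed; `off` is invariant under that trimming
      sgap_adj <- sgap + 3 * max(0, -qgap)
      if (sgap_adj >= thresholds$min_intron) next  # intron-scale gap
      if (off %% 3 != 0) {
        add_disruption("frameshift",
                       if (strand > 0) a$subject_end else b$subject_end)
      } else if (!is.null(contig) && sgap >= 3 && qgap >= 0) {
        ## short in-frame gap: scan whole codons strictly inside the gap,
        ## excluding codons spanning the junctions
        gseq <- if (strand > 0) substr(contig, a$subject_end + 1, b$subject_start)
                else revcomp(substr(contig, b$subject_end + 1, a$subject_start))
        ncod <- nchar(gseq) %/% 3
        if (ncod >= 1) {
          aa <- translate_cds(substr(gseq, 1, 3 * ncod))
          if (any(s2c(aa) == "*"))
            add_disruption("premature_stop",
                           if (strand > 0) a$subject_end else b$subject_end)
        }
      }
    }
  }

  ## coverage of the query by the chain
  covered <- rep(FALSE, query_length)
  for (r in seq_len(nrow(chain)))
    covered[seq(chain$query_start[r] + 1, min(chain$query_end[r], query_length))] <- TRUE
  coverage <- mean(covered)

  span <- c(min(chain$subject_start), max(chain$subject_end))

  ## truncation: missing leading/trailing query segments
  status <- if (nrow(disruptions) > 0) "pseudogene"
            else if (coverage >= thresholds$min_coverage_intact) "intact"
            else "fragment"

  ## inversion candidate: a missing internal query segment recovered on the
  ## opposite strand within the chain's subject span
  if (status == "fragment") {
    miss <- rle(covered)
    ends <- cumsum(miss$lengths); starts <- ends - miss$lengths + 1
    gaps <- which(!miss$values & miss$lengths >= thresholds$min_missing_segment)
    opp <- hsps[sign(hsps$frame) == -strand, , drop = FALSE]
    for (g in gaps) {
      seg <- c(starts[g] - 1, ends[g])  # 0-based half-open query interval
      if (nrow(opp)) {
        ov <- pmin(opp$query_end, seg[2]) - pmax(opp$query_start, seg[1])
        inside <- opp$subject_start >= span[1] & opp$subject_end <= span[2]
        if (any(ov > 0.5 * (seg[2] - seg[1]) & inside)) {
          status <- "inversion_candidate"
          break
        }
      }
    }
  }

  structure(list(status = status, disruptions = disruptions,
                 query_coverage = coverage, chained_hsps = chain,
                 subject_span = span),
            class = "gene_copy_call")
}

#' @export
print.gene_copy_call <- function(x, ...) {
  cat("gene copy call:", x$status,
      sprintf("(coverage %.2f, %d HSPs, %d disruptions)\n",
              x$query_coverage, nrow(x$chained_hsps), nrow(x$disruptions)))
  invisible(x)
}

#' Annotate transposable-element intervals on a contig
#'
#' Locally aligns every library element against the contig on both strands
#' (match +2 / mismatch -3, gap open 5 / extend 2 by default) and merges hits
#' scoring at least `min_score` into maximal non-overlapping intervals.
#'
#' @param contig nucleotide string
#' @param te_library named character vector of TE nucleotide sequences
#' @param min_score minimal raw alignment score for a hit
#' @param match,mismatch,gap_open,gap_extend nucleotide scoring parameters
#' @return list with `intervals` (two-column matrix, 0-based half-open) and
#'   `families` (TE family label per merged interval, comma-joined)
#' @export
annotate_tes <- function(contig, te_library, min_score = 50,
                         match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2) {
  if (length(te_library) == 0) stop("empty TE library")
  contig <- check_dna(contig)
  mat <- nt_score_matrix(match, mismatch)
  ab <- rownames(mat)
  senc <- encode_seq(contig, ab)
  raw <- list()
  for (i in seq_along(te_library)) {
    fam <- names(te_library)[i] %||% paste0("TE", i)
    for (el in c(te_library[[i]], revcomp(te_library[[i]]))) {
      res <- .sw_local_cpp(encode_seq(el, ab), senc, mat, gap_open,
                           gap_extend, min_score, 50L)
      if (length(res$score))
        raw[[length(raw) + 1]] <- data.frame(start = res$subject_start,
                                             end = res$subject_end,
                                             family = fam)
    }
  }
  if (!length(raw))
    return(list(intervals = matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("start", "end"))),
                families = character(0)))
  hits <- do.call(rbind, raw)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  ## merge overlapping intervals
  ms <- me <- numeric(0); fams <- list()
  for (r in seq_len(nrow(hits))) {
    if (length(ms) && hits$start[r] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], hits$end[r])
      fams[[length(fams)]] <- union(fams[[length(fams)]], hits$family[r])
    } else {
      ms <- c(ms, hits$start[r]); me <- c(me, hits$end[r])
      fams[[length(fams) + 1]] <- hits$family[r]
    }
  }
  list(intervals = cbind(start = ms, end = me),
       families = vapply(fams, paste, character(1), collapse = ","))
}

#' TE fraction of a gene span
#'
#' @param gene_span numeric length-2 vector (start, end), 0-based half-open
#' @param te TE annotation from [annotate_tes()]
#' @return list with `percent` (one decimal) and `bp` covered
#' @export
te_fraction <- function(gene_span, te) {
  if (gene_span[2] <= gene_span[1]) stop("degenerate gene span")
  iv <- te$intervals
  bp <- 0
  if (nrow(iv)) {
    s <- pmax(iv[, 1], gene_span[1]); e <- pmin(iv[, 2], gene_span[2])
    keep <- e > s
    if (any(keep)) {
      ## intervals from annotate_tes are already disjoint; be safe anyway
      segs <- cbind(s[keep], e[keep])
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      last <- -Inf
      for (r in seq_len(nrow(segs))) {
        a <- max(segs[r, 1], last); b <- segs[r, 2]
        if (b > a) bp <- bp + (b - a)
        last <- max(last, b)
      }
    }
  }
  list(percent = round(100 * bp / (gene_span[2] - gene_span[1]), 1),
       bp = as.integer(bp))
}

#' Percent identity between two sequences
#'
#' For aligned inputs (equal length, possibly gapped) identity is the number
#' of identical column pairs divided by the number of columns where both
#' sequences are non-gap. For unaligned inputs of equal length, positions are
#' compared directly; unaligned inputs of unequal length are globally aligned
#' first.
#'
#' @param a,b sequences (character strings)
#' @param aligned are the inputs rows of one alignment?
#' @return identity percentage (0-100)
#' @export
percent_identity <- function(a, b, aligned = FALSE) {
  if (aligned && nchar(a) != nchar(b))
    stop("aligned sequences must have equal length")
  if (!aligned && nchar(a) != nchar(b)) {
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global")
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
  }
  ca <- s2c(a); cb <- s2c(b)
  comp <- ca != "-" & cb != "-"
  if (!any(comp)) stop("no comparable (non-gap) columns")
  100 * sum(ca[comp] == cb[comp]) / sum(comp)
}
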