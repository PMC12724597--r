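## Locus-history simulator.
##
## A root genome carries one focal gene family (multi-exon, ~4 kb CDS) and a
## set of neighbor families on three contigs. Along each branch of a species
## tree at most one structural event of the focal family occurs (relocation
## of a 1-4 gene block, duplication with alternate retention, duplication
## with co-retention, tandem duplication, pseudogenization), plus optional
## neighbor acquisitions, decay-driven deletion of pseudogene vestiges, TE
## insertions, and sequence evolution (codon-aware for intact focal CDS,
## neutral elsewhere; intergenic spacers are held fixed). Every random choice
## is recorded in a truth log; replaying the log from the root genome
## reproduces the extant genomes exactly.

#' Simulator configuration
#'
#' Event rates are per-branch probabilities; at most one structural event of
#' the focal family happens per branch, which keeps histories identifiable.
#' `vestige_decay_rate` is a per-unit-time hazard: an existing pseudogene
#' vestige is fully deleted on a branch of length t with probability
#' 1 - exp(-rate * t).
#'
#' @param seed root RNG seed; per-stage child seeds derive from it
#' @param event_rates named list of per-branch probabilities: relocation,
#'   dup_alt_retention, dup_coretention, tandem_dup, pseudogenization,
#'   neighbor_acquisition
#' @param vestige_decay_rate hazard of complete vestige deletion per unit
#'   branch length
#' @param te_insertion_rate expected TE insertions per focal locus per branch
#' @param omega dN/dS for intact focal CDS evolution
#' @param kappa transition/transversion ratio
#' @param theta population-scaled polymorphism level (per gene)
#' @param n_strains haplotypes per population sample
#' @param n_neighbor_families number of neighbor gene families
#' @param focal_cds_codons focal CDS length in codons
#' @param n_exons focal exon count
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       event_rates = list(relocation = 0.025,
                                          dup_alt_retention = 0.025,
                                          dup_coretention = 0.01,
                                          tandem_dup = 0.015,
                                          pseudogenization = 0.01,
                                          neighbor_acquisition = 0.01),
                       vestige_decay_rate = 20,
                       te_insertion_rate = 0.1,
                       omega = 0.2, kappa = 2,
                       theta = 15, n_strains = 10,
                       n_neighbor_families = 48,
                       focal_cds_codons = 1333, n_exons = 4) {
  needed <- c("relocation", "dup_alt_retention", "dup_coretention",
              "tandem_dup", "pseudogenization", "neighbor_acquisition")
  miss <- setdiff(needed, names(event_rates))
  if (length(miss)) stop("missing event rates: ", paste(miss, collapse = ", "))
  er <- unlist(event_rates[needed])
  if (any(er < 0) || any(er > 1)) stop("event rates must lie in [0, 1]")
  structural <- sum(er[c("relocation", "dup_alt_retention", "dup_coretention",
                         "tandem_dup", "pseudogenization")])
  if (structural > 1)
    stop("event rates imply more than one expected structural event per ",
         "branch; histories become unidentifiable")
  stopifnot(vestige_decay_rate >= 0, te_insertion_rate >= 0, omega >= 0,
            kappa > 0, theta >= 0, n_strains >= 2,
            n_neighbor_families >= 10, focal_cds_codons >= 50, n_exons >= 1)
  structure(list(seed = as.integer(seed), event_rates = as.list(er),
                 vestige_decay_rate = vestige_decay_rate,
                 te_insertion_rate = te_insertion_rate,
                 omega = omega, kappa = kappa, theta = theta,
                 n_strains = as.integer(n_strains),
                 n_neighbor_families = as.integer(n_neighbor_families),
                 focal_cds_codons = as.integer(focal_cds_codons),
                 n_exons = as.integer(n_exons)),
            class = "sim_config")
}

FOCAL_FAMILY <- "focal"

## ---- root genome ----------------------------------------------------------

new_gene <- function(id, family, strand, status, seq, exons, is_focal) {
  list(id = id, family = family, strand = strand, status = status,
       seq = seq, exons = exons, is_focal = is_focal)
}

build_root_genome <- function(cfg) {
  nfam <- cfg$n_neighbor_families
  fams <- sprintf("N%02d", seq_len(nfam))
  genes <- list()
  mk_neighbor <- function(id, fam) {
    len <- sample(300:600, 1)
    new_gene(id, fam, sample(c("+", "-"), 1), "intact",
             random_dna(len), matrix(c(0, len), 1), FALSE)
  }
  ## focal gene: CDS split into exons with introns between
  cds <- random_cds(cfg$focal_cds_codons)
  Lc <- nchar(cds)
  cuts <- sort(sample(seq(30, Lc - 30, by = 3), cfg$n_exons - 1))
  bounds <- c(0, cuts, Lc)
  seq <- ""
  exons <- matrix(0, cfg$n_exons, 2)
  off <- 0
  for (e in seq_len(cfg$n_exons)) {
    ex <- substr(cds, bounds[e] + 1, bounds[e + 1])
    exons[e, ] <- c(off, off + nchar(ex))
    seq <- paste0(seq, ex)
    off <- off + nchar(ex)
    if (e < cfg$n_exons) {
      intr <- random_dna(sample(60:150, 1))
      seq <- paste0(seq, intr)
      off <- off + nchar(intr)
    }
  }
  focal <- new_gene("g_focal", FOCAL_FAMILY, "+", "intact", seq, exons, TRUE)

  ids <- sprintf("g%02d", seq_len(nfam))
  for (i in seq_len(nfam)) genes[[ids[i]]] <- mk_neighbor(ids[i], fams[i])
  genes[[focal$id]] <- focal

  ## the focal contig carries 3 neighbors per side; the remaining families
  ## are spread over four further contigs so that relocation/duplication
  ## destinations have well-separated candidate landing sites (emulating the
  ## sparsity of insertion sites in a genome-scale gene complement)
  rest <- ids[-(1:6)]
  parts <- split(rest, cut(seq_along(rest), 4, labels = FALSE))
  layout <- c(list(c1 = c(ids[1:3], focal$id, ids[4:6])),
              setNames(parts, paste0("c", 2:5)))
  spacers <- lapply(layout, function(g)
    vapply(seq_len(length(g) + 1), function(i) random_dna(sample(150:400, 1)),
           character(1)))
  ## small TE library for insertion events
  te_lib <- setNames(lapply(1:3, function(i) random_dna(sample(400:700, 1))),
                     sprintf("TEfam%d", 1:3))
  structure(list(genes = genes, contigs = layout, spacers = spacers,
                 te_library = te_lib, next_id = 1L),
            class = "sim_genome")
}

## ---- genome accessors -----------------------------------------------------

#' Gene table of a simulated genome
#'
#' One row per gene in genomic order: contig, order_index, gene_id, family,
#' strand, status, is_focal.
#'
#' @param genome a simulator genome
#' @return data.frame
#' @export
genes_table <- function(genome) {
  rows <- list()
  for (ct in names(genome$contigs)) {
    ids <- genome$contigs[[ct]]
    for (i in seq_along(ids)) {
      g <- genome$genes[[ids[i]]]
      rows[[length(rows) + 1]] <-
        data.frame(contig = ct, order_index = i, gene_id = g$id,
                   family = g$family, strand = g$strand, status = g$status,
                   is_focal = g$is_focal, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

gene_location <- function(genome, id) {
  for (ct in names(genome$contigs)) {
    i <- match(id, genome$contigs[[ct]])
    if (!is.na(i)) return(list(contig = ct, index = i))
  }
  NULL
}

focal_ids <- function(genome, status = NULL) {
  ids <- names(genome$genes)[vapply(genome$genes, function(g) g$is_focal,
                                    logical(1))]
  ids <- ids[ids %in% unlist(genome$contigs)]
  if (!is.null(status))
    ids <- ids[vapply(ids, function(i) genome$genes[[i]]$status %in% status,
                      logical(1))]
  ids
}

## ---- event application (shared by simulation and replay) ------------------

insert_ids <- function(vec, ids, slot) append(vec, ids, after = slot)

remove_ids <- function(genome, ids) {
  for (ct in names(genome$contigs)) {
    keep <- !(genome$contigs[[ct]] %in% ids)
    if (!all(keep)) {
      ## merge spacers around removed genes
      sp <- genome$spacers[[ct]]
      newsp <- sp[1]
      for (i in seq_along(keep)) {
        if (keep[i]) newsp <- c(newsp, sp[i + 1])
        else newsp[length(newsp)] <- paste0(newsp[length(newsp)], sp[i + 1])
      }
      genome$contigs[[ct]] <- genome$contigs[[ct]][keep]
      genome$spacers[[ct]] <- newsp
    }
  }
  genome
}

insert_genes <- function(genome, gene_objs, contig, slot) {
  ids <- vapply(gene_objs, `[[`, character(1), "id")
  for (g in gene_objs) genome$genes[[g$id]] <- g
  genome$contigs[[contig]] <- insert_ids(genome$contigs[[contig]], ids, slot)
  sp <- genome$spacers[[contig]]
  ## split the spacer at the insertion slot into len(ids)+1 pieces
  old <- sp[slot + 1]
  half <- nchar(old) %/% 2
  pieces <- c(substr(old, 1, half), rep("", length(ids) - 1),
              substr(old, half + 1, nchar(old)))
  genome$spacers[[contig]] <- append(sp[-(slot + 1)], pieces, after = slot)
  genome
}

apply_frameshift <- function(gene, fs) {
  s <- gene$seq
  if (fs$kind == "ins") {
    gene$seq <- paste0(substr(s, 1, fs$pos), fs$ins_seq,
                       substr(s, fs$pos + 1, nchar(s)))
  } else {
    gene$seq <- paste0(substr(s, 1, fs$pos),
                       substr(s, fs$pos + fs$len + 1, nchar(s)))
  }
  gene$status <- "pseudogene"
  gene
}

apply_sim_event <- function(genome, ev) {
  switch(ev$type,
    relocation = {
      objs <- lapply(ev$genes, function(i) genome$genes[[i]])
      genome <- remove_ids(genome, ev$genes)
      genome <- insert_genes(genome, objs, ev$dest_contig, ev$dest_slot)
      genome
    },
    dup_alt_retention = {
      src <- genome$genes[[ev$src_gene]]
      copy <- src; copy$id <- ev$new_id
      genome <- insert_genes(genome, list(copy), ev$dest_contig, ev$dest_slot)
      genome$genes[[ev$src_gene]] <- apply_frameshift(genome$genes[[ev$src_gene]],
                                                      ev$frameshift)
      genome
    },
    dup_coretention = {
      src <- genome$genes[[ev$src_gene]]
      copy <- src; copy$id <- ev$new_id
      insert_genes(genome, list(copy), ev$dest_contig, ev$dest_slot)
    },
    tandem_dup = {
      loc <- gene_location(genome, ev$src_gene)
      copy <- genome$genes[[ev$src_gene]]; copy$id <- ev$new_id
      insert_genes(genome, list(copy), loc$contig, loc$index)
    },
    pseudogenization = {
      genome$genes[[ev$gene]] <- apply_frameshift(genome$genes[[ev$gene]],
                                                  ev$frameshift)
      genome
    },
    neighbor_acquisition = {
      src <- genome$genes[[ev$src_gene]]
      copy <- src; copy$id <- ev$new_id
      genome <- insert_genes(genome, list(copy), ev$dest_contig, ev$dest_slot)
      if (isTRUE(ev$remove_source)) genome <- remove_ids(genome, ev$src_gene)
      genome
    },
    vestige_deletion = {
      genome <- remove_ids(genome, ev$gene)
      genome$genes[[ev$gene]] <- NULL
      genome
    },
    te_insertion = {
      sp <- genome$spacers[[ev$contig]]
      s <- sp[ev$spacer_index]
      off <- min(ev$offset, nchar(s))
      sp[ev$spacer_index] <- paste0(substr(s, 1, off), ev$te_seq,
                                    substr(s, off + 1, nchar(s)))
      genome$spacers[[ev$contig]] <- sp
      genome
    },
    stop("unknown event type: ", ev$type))
}

apply_mutations <- function(genome, muts) {
  if (is.null(muts) || nrow(muts) == 0) return(genome)
  for (id in unique(muts$gene_id)) {
    m <- muts[muts$gene_id == id, , drop = FALSE]
    ch <- s2c(genome$genes[[id]]$seq)
    ch[m$pos] <- m$base
    genome$genes[[id]]$seq <- c2s(ch)
  }
  genome
}

apply_branch_record <- function(genome, rec) {
  for (ev in rec$events) genome <- apply_sim_event(genome, ev)
  apply_mutations(genome, rec$mutations)
}

## ---- branch simulation ----------------------------------------------------

## candidate destination slots: intergenic positions on another contig whose
## +-3-gene neighborhood contains neither a focal copy nor a previously used
## landing site (tracked globally in `registry` across the whole history, so
## independent events land in distinguishable contexts, as they would in a
## genome-scale gene complement)
valid_dest_slots <- function(genome, exclude_contig, registry) {
  out <- list()
  for (ct in setdiff(names(genome$contigs), exclude_contig)) {
    ids <- genome$contigs[[ct]]
    if (length(ids) < 6) next
    ## interior slots only: at least 3 resident genes on each side, so a
    ## relocated block always acquires a distinguishable set of new flanks
    for (s in 3:(length(ids) - 3)) {
      near <- ids[max(1, s - 2):min(length(ids), s + 3)]
      if (any(near %in% registry$blocked)) next
      if (any(vapply(near, function(i) genome$genes[[i]]$is_focal,
                     logical(1)))) next
      out[[length(out) + 1]] <- list(contig = ct, slot = s, near = near)
    }
  }
  out
}

block_dest <- function(registry, slot_info) {
  registry$blocked <- union(registry$blocked, slot_info$near)
  invisible(registry)
}

## draw one branch's record of events and mutations (mutates a working
## genome; returns list(genome, record))
simulate_branch <- function(genome, t, cfg, branch_tag, registry) {
  events <- list()
  counter <- 0
  fresh_id <- function(stem) {
    counter <<- counter + 1
    sprintf("%s.%s%d", stem, branch_tag, counter)
  }
  er <- cfg$event_rates

  ## 1. at most one structural event of the focal family
  intact <- focal_ids(genome, "intact")
  u <- runif(1)
  kinds <- c("relocation", "dup_alt_retention", "dup_coretention",
             "tandem_dup", "pseudogenization")
  cum <- cumsum(unlist(er[kinds]))
  kind <- kinds[match(TRUE, u < cum)]
  if (!is.na(kind) && length(intact) > 0) {
    target <- sample(intact, 1)
    loc <- gene_location(genome, target)
    ## a vacated focal site stays off-limits as a landing site: in a
    ## genome-scale gene complement a later event would never land exactly
    ## in the ancestral locus by chance
    src_near <- genome$contigs[[loc$contig]][
      max(1, loc$index - 3):min(length(genome$contigs[[loc$contig]]),
                                loc$index + 3)]
    registry$blocked <- union(registry$blocked, setdiff(src_near, target))
    other_contigs <- setdiff(names(genome$contigs), loc$contig)
    ## intact focal copies at the source locus (within 3 genes of the target)
    near_ids <- genome$contigs[[loc$contig]][
      max(1, loc$index - 3):min(length(genome$contigs[[loc$contig]]),
                                loc$index + 3)]
    n_intact_src <- sum(vapply(near_ids, function(i)
      genome$genes[[i]]$is_focal && genome$genes[[i]]$status == "intact",
      logical(1)))
    ev <- NULL
    slots <- valid_dest_slots(genome, loc$contig, registry)
    if (kind == "relocation") {
      bs <- sample(1:4, 1, prob = c(0.5, 0.2, 0.2, 0.1))
      ids <- genome$contigs[[loc$contig]]
      lo <- max(1, loc$index - sample.int(bs, 1) + 1)
      hi <- min(length(ids), lo + bs - 1)
      block <- ids[lo:hi]
      if (length(slots)) {
        d <- slots[[sample.int(length(slots), 1)]]
        block_dest(registry, d)
        ev <- list(type = "relocation", genes = block, dest_contig = d$contig,
                   dest_slot = d$slot, n_genes = length(block))
      }
    } else if (kind %in% c("dup_alt_retention", "dup_coretention")) {
      if (length(slots)) {
        d <- slots[[sample.int(length(slots), 1)]]
        block_dest(registry, d)
        ev <- list(type = kind, src_gene = target, new_id = fresh_id(target),
                   dest_contig = d$contig, dest_slot = d$slot)
        if (kind == "dup_alt_retention")
          ev$frameshift <- draw_frameshift(genome$genes[[target]])
      }
    } else if (kind == "tandem_dup") {
      ev <- list(type = "tandem_dup", src_gene = target,
                 new_id = fresh_id(target))
    } else if (kind == "pseudogenization") {
      if (length(intact) >= 2)  # the focal gene is essential: keep one intact
        ev <- list(type = "pseudogenization", gene = target,
                   frameshift = draw_frameshift(genome$genes[[target]]))
    }
    if (!is.null(ev)) {
      ev$n_intact_src <- n_intact_src
      ev$n_intact_total <- length(intact)
      events[[length(events) + 1]] <- ev
      genome <- apply_sim_event(genome, ev)
    }
  }

  ## 2. neighbor acquisition: copy a non-local family next to a focal locus
  if (runif(1) < er$neighbor_acquisition) {
    foc <- focal_ids(genome, "intact")
    if (length(foc)) {
      f <- sample(foc, 1)
      floc <- gene_location(genome, f)
      near <- genome$contigs[[floc$contig]][
        pmax(1, floc$index - 3):pmin(length(genome$contigs[[floc$contig]]),
                                     floc$index + 3)]
      cand <- setdiff(unlist(genome$contigs), c(near, focal_ids(genome)))
      if (length(cand)) {
        src <- sample(cand, 1)
        ev <- list(type = "neighbor_acquisition", src_gene = src,
                   new_id = fresh_id(src), dest_contig = floc$contig,
                   dest_slot = floc$index, remove_source = runif(1) < 0.5)
        events[[length(events) + 1]] <- ev
        genome <- apply_sim_event(genome, ev)
      }
    }
  }

  ## 3. vestige decay
  p_del <- 1 - exp(-cfg$vestige_decay_rate * t)
  for (id in focal_ids(genome, "pseudogene")) {
    if (runif(1) < p_del) {
      ev <- list(type = "vestige_deletion", gene = id)
      events[[length(events) + 1]] <- ev
      genome <- apply_sim_event(genome, ev)
    }
  }

  ## 4. TE insertions near focal loci
  n_te <- rpois(1, cfg$te_insertion_rate * length(focal_ids(genome)))
  if (n_te > 0) for (i in seq_len(n_te)) {
    foc <- focal_ids(genome)
    if (!length(foc)) break
    f <- sample(foc, 1)
    floc <- gene_location(genome, f)
    side <- sample(0:1, 1)  # spacer before or after the focal gene
    fam <- sample(names(genome$te_library), 1)
    ev <- list(type = "te_insertion", contig = floc$contig,
               spacer_index = floc$index + side,
               offset = sample.int(200, 1), te_seq = genome$te_library[[fam]],
               te_family = fam)
    events[[length(events) + 1]] <- ev
    genome <- apply_sim_event(genome, ev)
  }

  ## 5. sequence evolution
  muts <- list()
  for (id in unlist(genome$contigs)) {
    g <- genome$genes[[id]]
    if (g$is_focal && g$status == "intact") {
      ## codon-aware on the CDS, neutral on introns
      cmap <- unlist(lapply(seq_len(nrow(g$exons)), function(e)
        (g$exons[e, 1] + 1):g$exons[e, 2]))
      cds <- c2s(s2c(g$seq)[cmap])
      res <- evolve_cds_branch(cds, t, cfg$omega, cfg$kappa)
      if (nrow(res$muts))
        muts[[length(muts) + 1]] <- data.frame(gene_id = id,
                                               pos = cmap[res$muts$pos],
                                               base = res$muts$base)
      intron_pos <- setdiff(seq_len(nchar(g$seq)), cmap)
      if (length(intron_pos)) {
        n <- rpois(1, length(intron_pos) * t)
        if (n > 0) {
          ch <- s2c(g$seq)
          pos <- sample(intron_pos, min(n, length(intron_pos)))
          base <- vapply(pos, function(p) draw_base(ch[p], cfg$kappa),
                         character(1))
          muts[[length(muts) + 1]] <- data.frame(gene_id = id, pos = pos,
                                                 base = base)
        }
      }
    } else {
      res <- evolve_neutral_branch(g$seq, t, cfg$kappa)
      if (nrow(res$muts))
        muts[[length(muts) + 1]] <- data.frame(gene_id = id,
                                               pos = res$muts$pos,
                                               base = res$muts$base)
    }
  }
  mutdf <- if (length(muts)) do.call(rbind, muts)
           else data.frame(gene_id = character(), pos = integer(),
                           base = character())
  genome <- apply_mutations(genome, mutdf)
  list(genome = genome, record = list(events = events, mutations = mutdf))
}

draw_frameshift <- function(gene) {
  L <- nchar(gene$seq)
  pos <- sample.int(L - 2, 1)
  if (runif(1) < 0.5) {
    len <- sample(1:2, 1)
    list(kind = "ins", pos = pos, len = len, ins_seq = random_dna(len))
  } else {
    list(kind = "del", pos = pos, len = sample(1:2, 1), ins_seq = "")
  }
}

## ---- full history ---------------------------------------------------------

#' Simulate a locus history on a species tree
#'
#' Builds a root genome, then walks the tree in preorder applying per-branch
#' structural events, vestige decay, TE insertions and sequence evolution
#' (see the module header). Everything random is logged; the truth log can be
#' replayed with [replay_truth()] to reproduce the extant genomes exactly.
#'
#' @param tree rooted `phylo` species tree with branch lengths
#' @param cfg a [sim_config()] object
#' @return object of class `locus_history`: list with `genomes` (per tip),
#'   `truth` (tree, root genome, per-branch records, event summary, cfg)
#' @export
simulate_locus_history <- function(tree, cfg = sim_config()) {
  if (length(tree$tip.label) < 3) stop("tree needs at least 3 tips")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nE <- nrow(tree$edge)
  root <- tree$edge[nE, 1]
  desc <- descendant_tips(tree)
  genomes_at <- vector("list", max(tree$edge))
  branches <- vector("list", nE)
  summary_rows <- list()
  registry <- new.env(parent = emptyenv())
  registry$blocked <- character(0)
  with_seed(cfg$seed, {
    genomes_at[[root]] <- build_root_genome(cfg)
    for (k in rev(seq_len(nE))) {  # preorder
      p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
      res <- simulate_branch(genomes_at[[p]], tree$edge.length[k], cfg,
                             branch_tag = sprintf("b%d", k),
                             registry = registry)
      genomes_at[[v]] <- res$genome
      branches[[k]] <- res$record
      for (ev in res$record$events) {
        evf <- function(f) if (f %in% names(ev)) ev[[f]] else NULL
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          type = ev$type, branch = k,
          clade = paste(sort(desc[[v]]), collapse = ","),
          n_genes = evf("n_genes") %||% 1L,
          src_gene = evf("src_gene") %||% (evf("gene") %||% NA_character_),
          new_id = evf("new_id") %||% NA_character_,
          genes = if (!is.null(evf("genes")))
                    paste(ev[["genes"]], collapse = ",") else NA_character_,
          dest_contig = evf("dest_contig") %||% NA_character_,
          n_intact_src = evf("n_intact_src") %||% NA_integer_,
          n_intact_total = evf("n_intact_total") %||% NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  })
  genomes <- setNames(genomes_at[seq_len(ntip)], tree$tip.label)
  events <- if (length(summary_rows)) do.call(rbind, summary_rows)
            else data.frame(type = character(), branch = integer(),
                            clade = character(), n_genes = integer(),
                            detail = character())
  truth <- structure(list(tree = tree, root_genome = genomes_at[[root]],
                          branches = branches, events = events, cfg = cfg),
                     class = "truth_log")
  structure(list(genomes = genomes, truth = truth), class = "locus_history")
}

#' @export
print.locus_history <- function(x, ...) {
  cat(sprintf("locus history: %d tip genomes, %d logged events\n",
              length(x$genomes), nrow(x$truth$events)))
  invisible(x)
}

#' Replay a truth log from the root genome
#'
#' Mechanically re-applies every logged event and mutation along the tree.
#' The result must equal the simulated extant genomes exactly.
#'
#' @param truth a `truth_log` from [simulate_locus_history()]
#' @return named list of tip genomes
#' @export
replay_truth <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  nE <- nrow(tree$edge)
  root <- tree$edge[nE, 1]
  genomes_at <- vector("list", max(tree$edge))
  genomes_at[[root]] <- truth$root_genome
  for (k in rev(seq_len(nE))) {
    p <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    genomes_at[[v]] <- apply_branch_record(genomes_at[[p]],
                                           truth$branches[[k]])
  }
  setNames(genomes_at[seq_len(ntip)], tree$tip.label)
}

## ---- emission -------------------------------------------------------------

#' Assemble contig sequences and coordinate tables for a genome
#'
#' Reverse-strand genes are emitted as the reverse complement of their stored
#' coding-orientation sequence; all coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param genome a simulator genome
#' @return list with `contigs` (named character vector), `genes`
#'   (data.frame with contig, start, end, strand, gene_id, family, status,
#'   is_focal) and `exons` (data.frame gene_id, exon_index, start, end for
#'   intact focal genes)
#' @export
emit_genome <- function(genome) {
  contigs <- character(0)
  gene_rows <- list(); exon_rows <- list()
  for (ct in names(genome$contigs)) {
    ids <- genome$contigs[[ct]]
    sp <- genome$spacers[[ct]]
    seqparts <- character(0)
    pos <- 0
    for (i in seq_along(ids)) {
      seqparts <- c(seqparts, sp[i])
      pos <- pos + nchar(sp[i])
      g <- genome$genes[[ids[i]]]
      gl <- nchar(g$seq)
      emitted <- if (g$strand == "+") g$seq else revcomp(g$seq)
      seqparts <- c(seqparts, emitted)
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        contig = ct, start = pos, end = pos + gl, strand = g$strand,
        gene_id = g$id, family = g$family, status = g$status,
        is_focal = g$is_focal, stringsAsFactors = FALSE)
      if (g$is_focal && g$status == "intact") {
        for (e in seq_len(nrow(g$exons))) {
          ex <- g$exons[e, ]
          if (g$strand == "+") { s0 <- pos + ex[1]; e0 <- pos + ex[2] }
          else { s0 <- pos + gl - ex[2]; e0 <- pos + gl - ex[1] }
          exon_rows[[length(exon_rows) + 1]] <- data.frame(
            gene_id = g$id, exon_index = e, start = s0, end = e0,
            stringsAsFactors = FALSE)
        }
      }
      pos <- pos + gl
    }
    seqparts <- c(seqparts, sp[length(sp)])
    contigs[ct] <- paste0(seqparts, collapse = "")
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows)
           else data.frame()
  exons <- if (length(exon_rows)) do.call(rbind, exon_rows)
           else data.frame(gene_id = character(), exon_index = integer(),
                           start = integer(), end = integer())
  list(contigs = contigs, genes = genes, exons = exons)
}

## ---- fixture I/O ----------------------------------------------------------

write_fasta <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  ln <- readLines(path)
  hdr <- grepl("^>", ln)
  ids <- sub("^>\\s*", "", ln[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(ln[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  setNames(as.character(seqs), ids)
}

#' Write a simulated history to plain-text fixture files
#'
#' Emits, per species, a FASTA of contigs and a GFF3 of gene (and focal exon)
#' annotations (1-based inclusive), plus the species tree in newick and a
#' JSON truth file with the event summary. `read_fixture()` on the output
#' directory reproduces the emitted objects.
#'
#' @param history a `locus_history` (or a named list of genomes plus `truth`)
#' @param out_dir output directory (created if needed)
#' @return invisibly, the directory path
#' @export
write_fixture <- function(history, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  for (sp in names(history$genomes)) {
    em <- emit_genome(history$genomes[[sp]])
    write_fasta(em$contigs, file.path(out_dir, paste0(sp, ".fa")))
    g <- em$genes
    rows <- sprintf("%s\tsyntrace\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_family=%s;status=%s",
                    g$contig, g$start + 1, g$end, g$strand, g$gene_id,
                    g$family, g$status)
    if (nrow(em$exons)) {
      ex <- merge(em$exons, g[, c("gene_id", "contig", "strand")],
                  by = "gene_id")
      rows <- c(rows, sprintf(
        "%s\tsyntrace\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        ex$contig, ex$start + 1, ex$end, ex$strand, ex$gene_id,
        ex$exon_index, ex$gene_id))
    }
    writeLines(c("##gff-version 3", rows),
               file.path(out_dir, paste0(sp, ".gff3")))
  }
  ape::write.tree(history$truth$tree, file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(list(events = history$truth$events,
                            species = names(history$genomes)),
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory
#' @return list with `genomes` (per species: contigs, genes, exons), `tree`,
#'   `events`
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  species <- truth$species
  genomes <- list()
  for (sp in species) {
    contigs <- read_fasta(file.path(dir, paste0(sp, ".fa")))
    ln <- readLines(file.path(dir, paste0(sp, ".gff3")))
    ln <- ln[!grepl("^#", ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    typ <- vapply(f, `[[`, character(1), 3)
    attr_field <- vapply(f, `[[`, character(1), 9)
    getattr <- function(a, key) {
      m <- regmatches(a, regexec(paste0(key, "=([^;]+)"), a))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
             character(1))
    }
    gi <- typ == "gene"
    genes <- data.frame(
      contig = vapply(f[gi], `[[`, character(1), 1),
      start = as.integer(vapply(f[gi], `[[`, character(1), 4)) - 1L,
      end = as.integer(vapply(f[gi], `[[`, character(1), 5)),
      strand = vapply(f[gi], `[[`, character(1), 7),
      gene_id = getattr(attr_field[gi], "ID"),
      family = getattr(attr_field[gi], "gene_family"),
      status = getattr(attr_field[gi], "status"),
      stringsAsFactors = FALSE)
    genes$is_focal <- genes$family == FOCAL_FAMILY
    ei <- typ == "exon"
    exons <- if (any(ei)) data.frame(
      gene_id = getattr(attr_field[ei], "Parent"),
      exon_index = as.integer(sub("^.*\\.e", "",
                                  getattr(attr_field[ei], "ID"))),
      start = as.integer(vapply(f[ei], `[[`, character(1), 4)) - 1L,
      end = as.integer(vapply(f[ei], `[[`, character(1), 5)),
      stringsAsFactors = FALSE)
    else data.frame(gene_id = character(), exon_index = integer(),
                    start = integer(), end = integer())
    genomes[[sp]] <- list(contigs = contigs, genes = genes, exons = exons)
  }
  list(genomes = genomes,
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       events = truth$events)
}
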