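## Locus contexts, syntenic-locus clustering, and tree-aware inference of the
## per-branch event chronology (block translocation vs duplication/alternate
## retention vs co-retention vs tandem duplication).
##
## A locus context is the ordered, stranded neighbor-family signature around
## one focal-family gene copy. Contexts are clustered across species by
## single-linkage on Jaccard similarity of their neighbor-family sets; loci
## are then mapped onto the species tree under Dollo parsimony (single gain,
## unlimited losses) and gains are paired with losses into events, using
## surviving pseudogene vestiges and co-moved neighbor families as evidence.

#' Read a locus-context gene table
#'
#' Tab-separated columns: species, contig, gene_family, order_index, strand,
#' status (optional extra columns are kept). Lines starting with `#` are
#' comments.
#'
#' @param path file path
#' @return data.frame of genes in genomic order per (species, contig)
#' @export
read_context_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species", "contig", "gene_family", "order_index", "strand",
            "status")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- d[order(d$species, d$contig, d$order_index), ]
  if (!"gene_id" %in% names(d))
    d$gene_id <- sprintf("%s:%s:%d", d$species, d$contig, d$order_index)
  rownames(d) <- NULL
  d
}

#' Write a locus-context gene table
#'
#' Tab-separated counterpart of [read_context_table()].
#'
#' @param gene_table data.frame with at least species, contig, gene_family,
#'   order_index, strand, status
#' @param path output file
#' @return invisibly, the path
#' @export
write_context_table <- function(gene_table, path) {
  keep <- intersect(c("species", "contig", "gene_family", "order_index",
                      "strand", "status", "gene_id", "identity"),
                    names(gene_table))
  write.table(gene_table[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## gene table for one species from a simulator genome (adds species column)
species_gene_table <- function(genome, species) {
  gt <- genes_table(genome)
  gt$species <- species
  gt$gene_family <- gt$family
  gt
}

#' Extract the locus context of one focal gene copy
#'
#' The k nearest annotated neighbors per side in genomic order, with strands,
#' skipping other copies of the focal family (neighbor lists exclude the
#' focal family). `edge_truncated` is set when the contig ends before k
#' neighbors are found.
#'
#' @param gene_table data.frame with species, contig, order_index,
#'   gene_family, strand, status, gene_id
#' @param focal_gene_id gene_id of the focal copy
#' @param k neighbors per side
#' @param focal_family name of the focal gene family
#' @param species species of the focal copy (needed when the same gene_id
#'   occurs in several species)
#' @return object of class `locus_context`
#' @export
extract_locus_context <- function(gene_table, focal_gene_id, k = 3,
                                  focal_family = FOCAL_FAMILY,
                                  species = NULL) {
  row <- which(gene_table$gene_id == focal_gene_id &
                 (if (is.null(species)) TRUE else gene_table$species == species))
  if (length(row) == 0) stop("focal copy not found: ", focal_gene_id)
  if (length(row) > 1) stop("ambiguous focal copy (supply species): ",
                            focal_gene_id)
  fr <- gene_table[row, ]
  ct <- gene_table[gene_table$species == fr$species &
                     gene_table$contig == fr$contig, , drop = FALSE]
  ct <- ct[order(ct$order_index), ]
  i <- which(ct$gene_id == focal_gene_id)
  nonfocal_up <- ct[seq_len(i - 1), , drop = FALSE]
  nonfocal_up <- nonfocal_up[nonfocal_up$gene_family != focal_family, ,
                             drop = FALSE]
  nonfocal_dn <- if (i < nrow(ct)) ct[(i + 1):nrow(ct), , drop = FALSE]
                 else ct[0, ]
  nonfocal_dn <- nonfocal_dn[nonfocal_dn$gene_family != focal_family, ,
                             drop = FALSE]
  up <- tail(nonfocal_up, k)          # nearest last; reverse to nearest-first
  up <- up[rev(seq_len(nrow(up))), , drop = FALSE]
  dn <- head(nonfocal_dn, k)
  truncated <- nrow(up) < k || nrow(dn) < k
  structure(list(
    species = fr$species, contig = fr$contig, gene_id = fr$gene_id,
    status = fr$status, strand = fr$strand, k = k,
    upstream = data.frame(family = up$gene_family, strand = up$strand,
                          stringsAsFactors = FALSE),
    downstream = data.frame(family = dn$gene_family, strand = dn$strand,
                            stringsAsFactors = FALSE),
    signature = unique(c(up$gene_family, dn$gene_family)),
    edge_truncated = truncated), class = "locus_context")
}

#' @export
print.locus_context <- function(x, ...) {
  cat(sprintf("locus context %s [%s] %s: [%s] < focal(%s) > [%s]%s\n",
              x$species, x$contig, x$gene_id,
              paste(rev(x$upstream$family), collapse = ","), x$status,
              paste(x$downstream$family, collapse = ","),
              if (x$edge_truncated) " (edge-truncated)" else ""))
  invisible(x)
}

#' Extract contexts for every focal-family copy in a multi-species table
#'
#' @param gene_table combined gene table (see [read_context_table()])
#' @param k neighbors per side
#' @param focal_family focal family name
#' @return list of `locus_context` objects
#' @export
extract_all_contexts <- function(gene_table, k = 3,
                                 focal_family = FOCAL_FAMILY) {
  idx <- which(gene_table$gene_family == focal_family)
  lapply(idx, function(i)
    extract_locus_context(gene_table, gene_table$gene_id[i], k, focal_family,
                          species = gene_table$species[i]))
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)  # two empty signatures never merge
  length(intersect(a, b)) / length(u)
}

#' Cluster locus contexts into shared syntenic loci
#'
#' Single-linkage clustering (connected components of the graph joining
#' contexts with Jaccard similarity of their neighbor-family sets at or
#' above `min_jaccard`). Strand- and order-insensitive; invariant to input
#' permutation.
#'
#' @param contexts list of `locus_context` objects
#' @param min_jaccard similarity threshold (default 0.34: one shared family
#'   of two 3-per-side windows is not enough, two generally are)
#' @return list of clusters: each has `id`, `members` (indices into
#'   `contexts`), `species`, `sig_union`, `sig_core` (families in at least
#'   half the member contexts)
#' @export
match_loci_across_species <- function(contexts, min_jaccard = 0.34) {
  n <- length(contexts)
  if (n == 0) stop("no contexts supplied")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (jaccard(contexts[[i]]$signature, contexts[[j]]$signature) >=
          min_jaccard) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ## deterministic ordering: by sorted (species, contig, gene_id) of members
  keyfun <- function(idx) {
    ks <- vapply(idx, function(i)
      paste(contexts[[i]]$species, contexts[[i]]$contig,
            contexts[[i]]$gene_id), character(1))
    min(sort(ks))
  }
  groups <- split(seq_len(n), comp)
  groups <- groups[order(vapply(groups, keyfun, character(1)))]
  out <- list()
  for (g in seq_along(groups)) {
    idx <- sort(unlist(groups[[g]]))
    sigs <- lapply(idx, function(i) contexts[[i]]$signature)
    allf <- sort(unique(unlist(sigs)))
    cnt <- vapply(allf, function(f)
      sum(vapply(sigs, function(s) f %in% s, logical(1))), numeric(1))
    out[[g]] <- list(id = sprintf("L%d", g), members = idx,
                     species = unique(vapply(idx, function(i)
                       contexts[[i]]$species, character(1))),
                     sig_union = allf,
                     sig_core = allf[cnt >= length(idx) / 2])
  }
  out
}

## ---- presence on the tree -------------------------------------------------

## internal: canonical tree bookkeeping (postorder edges, descendant tips,
## parent lookup)
tree_index <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  desc <- descendant_tips(tr)
  parent_edge <- integer(max(tr$edge))  # edge index above each node (0 = root)
  for (k in seq_len(nrow(tr$edge))) parent_edge[tr$edge[k, 2]] <- k
  list(tree = tr, ntip = ntip, nE = nrow(tr$edge), desc = desc,
       root = tr$edge[nrow(tr$edge), 1], parent_edge = parent_edge)
}

## Dollo placement of one presence vector: single gain, minimal losses
dollo_place <- function(ti, carriers) {
  if (!length(carriers)) return(list(gain = NA, losses = integer(0)))
  tipidx <- match(carriers, ti$tree$tip.label)
  node <- if (length(tipidx) == 1) tipidx
          else ape::getMRCA(ti$tree, tipidx)
  gain <- if (node == ti$root) "root" else ti$parent_edge[node]
  ## minimal losses below the gain node
  losses <- integer(0)
  recurse <- function(v) {
    kids <- which(ti$tree$edge[, 1] == v)
    for (k in kids) {
      child <- ti$tree$edge[k, 2]
      if (!any(carriers %in% ti$desc[[child]])) losses <<- c(losses, k)
      else if (child > ti$ntip) recurse(child)
    }
  }
  recurse(node)
  list(gain = gain, losses = losses, gain_node = node)
}

#' Map per-cluster presence onto the species tree (Dollo parsimony)
#'
#' For every cluster, places the unique most-recent gain branch (the stem of
#' the carriers' MRCA, or the root) and the minimal set of loss branches
#' under single-gain / unlimited-loss parsimony.
#'
#' @param presence logical matrix, species x clusters
#' @param tree `phylo` tree containing all species as tips
#' @return list per cluster: `gain` (edge index in the postorder tree, or
#'   "root"), `gain_clade` (tip labels below the gain), `losses` (edge
#'   indices), `loss_clades`
#' @export
map_presence_on_tree <- function(presence, tree) {
  miss <- setdiff(rownames(presence), tree$tip.label)
  if (length(miss)) stop("species missing from tree: ",
                         paste(miss, collapse = ", "))
  ti <- tree_index(tree)
  out <- list()
  for (cl in colnames(presence)) {
    carriers <- rownames(presence)[presence[, cl]]
    dp <- dollo_place(ti, carriers)
    out[[cl]] <- list(
      gain = dp$gain,
      gain_clade = if (identical(dp$gain, "root")) ti$tree$tip.label
                   else if (is.na(dp$gain[1])) character(0)
                   else ti$desc[[ti$tree$edge[dp$gain, 2]]],
      losses = dp$losses,
      loss_clades = lapply(dp$losses, function(k)
        ti$desc[[ti$tree$edge[k, 2]]]))
  }
  out
}

## ---- locus presence scan --------------------------------------------------

## best sliding-window Jaccard match of a cluster signature in one species'
## gene table; returns max similarity and the families found in that window
best_locus_window <- function(sp_table, sig, k = 3,
                              focal_family = FOCAL_FAMILY) {
  best <- list(j = 0, fams = character(0), contig = NA, center = NA,
               has_focal = FALSE, focal_status = NA_character_)
  if (!length(sig)) return(best)
  for (ct in unique(sp_table$contig)) {
    rows <- sp_table[sp_table$contig == ct, , drop = FALSE]
    rows <- rows[order(rows$order_index), ]
    nf <- rows[rows$gene_family != focal_family, , drop = FALSE]
    foc_all <- rows[rows$gene_family == focal_family, , drop = FALSE]
    n <- nrow(nf)
    if (n == 0) next
    ## windows of up to 2k non-focal genes (k per side of a putative focal
    ## site); focal copies do not consume window slots
    win <- 2 * k
    starts <- if (n <= win) 1 else 1:(n - win + 1)
    for (s in starts) {
      e <- min(n, s + win - 1)
      sel <- nf[s:e, , drop = FALSE]
      fams <- unique(sel$gene_family)
      j <- jaccard(fams, sig)
      if (j > best$j) {
        span <- range(sel$order_index)
        foc <- foc_all[foc_all$order_index >= span[1] - 1 &
                         foc_all$order_index <= span[2] + 1, , drop = FALSE]
        st <- if (nrow(foc)) {
          if (any(foc$status == "intact")) "intact"
          else if (any(foc$status == "fragment")) "fragment"
          else "pseudogene"
        } else NA_character_
        best <- list(j = j, fams = fams, contig = ct,
                     center = s, has_focal = nrow(foc) > 0,
                     focal_status = st, span = span)
      }
    }
  }
  best
}

#' Build the species x cluster presence structure
#'
#' For every species and cluster: the focal-copy status at that locus (from
#' the clustered contexts), whether the locus itself (its neighbor-family
#' signature) is present in the species, and which signature families are
#' found at the best-matching window.
#'
#' @param gene_table combined multi-species gene table
#' @param contexts contexts from [extract_all_contexts()]
#' @param clusters clusters from [match_loci_across_species()]
#' @param k window half-width
#' @param min_jaccard locus-presence threshold
#' @param focal_family focal family name
#' @return object of class `locus_presence`
#' @export
locus_presence <- function(gene_table, contexts, clusters, k = 3,
                           min_jaccard = 0.34,
                           focal_family = FOCAL_FAMILY) {
  species <- sort(unique(gene_table$species))
  cl_ids <- vapply(clusters, `[[`, character(1), "id")
  focal_status <- matrix("absent", length(species), length(clusters),
                         dimnames = list(species, cl_ids))
  locus_here <- matrix(FALSE, length(species), length(clusters),
                       dimnames = list(species, cl_ids))
  fam_at <- array(list(), c(length(species), length(clusters)),
                  dimnames = list(species, cl_ids))
  win_at <- array(list(), c(length(species), length(clusters)),
                  dimnames = list(species, cl_ids))
  j_at <- matrix(0, length(species), length(clusters),
                 dimnames = list(species, cl_ids))
  rank <- c(absent = 0, pseudogene = 1, fragment = 2, intact = 3)
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    for (m in cl$members) {
      cx <- contexts[[m]]
      cur <- focal_status[cx$species, ci]
      st <- if (cx$status %in% names(rank)) cx$status else "fragment"
      if (rank[st] > rank[cur]) focal_status[cx$species, ci] <- st
      locus_here[cx$species, ci] <- TRUE
    }
    sig <- cl$sig_core
    if (!length(sig)) sig <- cl$sig_union
    for (sp in species) {
      spt <- gene_table[gene_table$species == sp, , drop = FALSE]
      bw <- best_locus_window(spt, sig, k, focal_family)
      fam_at[[sp, ci]] <- bw$fams
      j_at[sp, ci] <- bw$j
      if (!is.null(bw$span))
        win_at[[sp, ci]] <- list(contig = bw$contig, span = bw$span)
      if (bw$j >= min_jaccard) {
        locus_here[sp, ci] <- TRUE
        if (bw$has_focal &&
              rank[bw$focal_status] > rank[focal_status[sp, ci]])
          focal_status[sp, ci] <- bw$focal_status
      }
    }
  }
  structure(list(species = species, clusters = clusters,
                 contexts = contexts, focal_status = focal_status,
                 locus_here = locus_here, fam_at = fam_at, win_at = win_at,
                 j_at = j_at,
                 gene_table = gene_table, focal_family = focal_family,
                 k = k, min_jaccard = min_jaccard),
            class = "locus_presence")
}

#' @export
print.locus_presence <- function(x, ...) {
  cat("locus presence:", length(x$species), "species x",
      length(x$clusters), "clusters\n")
  print(x$focal_status)
  invisible(x)
}

## ---- tandem detection -----------------------------------------------------

#' Find tandem focal-copy pairs
#'
#' Two focal-family copies on the same contig separated by at most
#' `max_intervening` genes, with nucleotide identity at or above
#' `min_identity` percent (when sequences are supplied; an `identity` column
#' in the gene table may supply it instead).
#'
#' @param gene_table combined gene table
#' @param seqs optional nested list: `seqs[[species]][[gene_id]]` nucleotide
#'   sequence
#' @param max_intervening maximal number of genes between the copies
#' @param min_identity identity threshold in percent
#' @param focal_family focal family name
#' @return data.frame with species, contig, gene1, gene2, identity
#' @export
find_tandem_copies <- function(gene_table, seqs = NULL, max_intervening = 2,
                               min_identity = 97,
                               focal_family = FOCAL_FAMILY) {
  out <- list()
  for (sp in unique(gene_table$species)) {
    for (ct in unique(gene_table$contig[gene_table$species == sp])) {
      rows <- gene_table[gene_table$species == sp & gene_table$contig == ct, ]
      rows <- rows[order(rows$order_index), ]
      foc <- which(rows$gene_family == focal_family &
                     rows$status == "intact")
      if (length(foc) < 2) next
      for (a in seq_len(length(foc) - 1)) for (b in (a + 1):length(foc)) {
        if (foc[b] - foc[a] - 1 > max_intervening) next
        id1 <- rows$gene_id[foc[a]]; id2 <- rows$gene_id[foc[b]]
        ident <- if (!is.null(seqs) && !is.null(seqs[[sp]][[id1]]) &&
                       !is.null(seqs[[sp]][[id2]]))
          percent_identity(seqs[[sp]][[id1]], seqs[[sp]][[id2]])
        else if ("identity" %in% names(rows)) {
          v <- suppressWarnings(as.numeric(rows$identity[foc[b]]))
          if (is.na(v)) NA_real_ else v
        } else NA_real_
        if (!is.na(ident) && ident >= min_identity)
          out[[length(out) + 1]] <- data.frame(
            species = sp, contig = ct, gene1 = id1, gene2 = id2,
            identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(species = character(), contig = character(),
                  gene1 = character(), gene2 = character(),
                  identity = numeric())
}

## ---- event inference ------------------------------------------------------

new_event <- function(type, branch, clade, source = NA, dest = NA,
                      genes_moved = character(0), vestige_found = FALSE,
                      n_genes_comoved = length(genes_moved),
                      both_loci_occupied = FALSE, branch_uncertain = FALSE) {
  list(type = type, branch = branch, clade = clade, source = source,
       dest = dest, genes_moved = genes_moved,
       evidence = list(vestige_found = vestige_found,
                       n_genes_comoved = n_genes_comoved,
                       both_loci_occupied = both_loci_occupied),
       branch_uncertain = branch_uncertain)
}

#' Infer the per-branch event chronology
#'
#' Pairs Dollo gains and losses of focal-bearing locus clusters into moves
#' and duplications and classifies them: at least two co-moved families with
#' no vestige give a block translocation; a surviving vestige (a pseudogene
#' or fragment of the focal family at the source locus, or a pseudogene copy
#' of a source family at the destination while the source copy stays intact)
#' gives duplication with alternate retention; both loci intact in one
#' species gives duplication with co-retention; a single moved gene with no
#' vestige is ambiguous (relocation and duplication/alternate retention
#' cannot be distinguished). Neighbor families gained at a pre-existing
#' focal locus from elsewhere in the genome are neighbor acquisitions;
#' flagged adjacent near-identical copies are tandem duplications.
#'
#' @param tree species tree (`phylo`)
#' @param presence a [locus_presence()] object
#' @param tandem data.frame from [find_tandem_copies()] (may be empty)
#' @return object of class `chronology`: list with `events` (ordered
#'   ancestral-first), `presence_matrix` (species x cluster status), `tree`
#' @export
infer_events <- function(tree, presence, tandem = NULL, verbose = FALSE) {
  vcat <- function(...) if (verbose) cat(...)
  ti <- tree_index(tree)
  sp_all <- presence$species
  miss <- setdiff(sp_all, ti$tree$tip.label)
  if (length(miss)) stop("species missing from tree: ",
                         paste(miss, collapse = ", "))
  fs <- presence$focal_status
  cl_ids <- colnames(fs)
  intactish <- fs == "intact" | fs == "fragment"
  anyfocal <- fs != "absent"

  ## Dollo layers. dollo_focal is re-derived iteratively below: a species
  ## that once held a cluster but moved its focal copy onward still counts
  ## toward the cluster's gain placement (its own move explains the loss).
  dollo_focal <- map_presence_on_tree(intactish, tree)
  dollo_locus <- map_presence_on_tree(presence$locus_here, tree)

  edge_clade <- function(k) {
    if (identical(k, "root")) ti$tree$tip.label else ti$desc[[ti$tree$edge[k, 2]]]
  }
  clade_str <- function(x) paste(sort(x), collapse = ",")
  is_ancestor_edge <- function(a, b) {  # is edge a a strict ancestor of edge b?
    if (identical(a, "root")) return(!identical(b, "root"))
    if (identical(b, "root")) return(FALSE)
    ca <- edge_clade(a); cb <- edge_clade(b)
    length(cb) < length(ca) && all(cb %in% ca)
  }

  ## occupied nodes per cluster given a set of Dollo placements
  build_occupied <- function(dollo_eff, strong = FALSE) {
    occupied <- matrix(FALSE, max(ti$tree$edge), length(cl_ids),
                       dimnames = list(NULL, cl_ids))
    for (cl in cl_ids) {
      dp <- dollo_eff[[cl]]
      if (is.na(dp$gain[1])) next
      start_node <- if (identical(dp$gain, "root")) ti$root
                    else ti$tree$edge[dp$gain, 2]
      nodes <- start_node
      stack <- start_node
      occ_losses <- if (strong) dp$losses_strong %||% dp$losses
                    else dp$losses_occ %||% dp$losses
      loss_children <- vapply(occ_losses, function(k) ti$tree$edge[k, 2],
                              integer(1))
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        kids <- ti$tree$edge[ti$tree$edge[, 1] == v, 2]
        kids <- setdiff(kids, loss_children)
        nodes <- c(nodes, kids)
        stack <- c(stack, kids[kids > ti$ntip])
      }
      occupied[nodes, cl] <- TRUE
    }
    occupied
  }

  events <- list()
  consumed_losses <- list()  # cluster -> edge indices explained by moves
  move_sources <- character(0)  # cluster ids that act as a source of a move

  ## helper: families present at cluster X's locus in a species
  fam_here <- function(sp, cl) presence$fam_at[[sp, cl]]

  ## vestige evidence for a move X -> Y on clade `cl_sp`; species whose
  ## X-vestige is already claimed by another event are excluded
  vestige_for <- function(X, Y, cl_sp, claimed = character(0)) {
    ## focal pseudogene/fragment at the source locus in a descendant
    wit <- setdiff(intersect(cl_sp, sp_all), claimed)
    v1 <- any(fs[wit, X] %in% c("pseudogene", "fragment"))
    if (v1) return(TRUE)
    ## a pseudogene copy of a source-signature family inside the destination
    ## window while the source keeps an intact copy: a co-duplicated vestige
    ## (duplication, not translocation, of the source region)
    Xsig <- presence$clusters[[match(X, cl_ids)]]$sig_core
    gt <- presence$gene_table
    for (sp in intersect(cl_sp, sp_all)) {
      w <- presence$win_at[[sp, Y]]
      if (is.null(w)) next
      spt <- gt[gt$species == sp, , drop = FALSE]
      inwin <- spt$contig == w$contig &
        spt$order_index >= w$span[1] - 1 & spt$order_index <= w$span[2] + 1
      ydead <- spt$gene_family[inwin &
                                 spt$status %in% c("pseudogene", "fragment") &
                                 spt$gene_family %in% Xsig]
      for (f in ydead) {
        if (f %in% fam_here(sp, X) &&
              any(spt$status == "intact" & spt$gene_family == f & !inwin))
          return(TRUE)
      }
    }
    FALSE
  }

  ## does species sp's best window for cluster cl belong to cl, or does
  ## another cluster claim the same window more strongly?
  owns_window <- function(sp, cl) {
    w <- presence$win_at[[sp, cl]]
    if (is.null(w)) return(FALSE)
    !any(vapply(setdiff(cl_ids, cl), function(Z) {
      wz <- presence$win_at[[sp, Z]]
      !is.null(wz) && wz$contig == w$contig &&
        wz$span[1] <= w$span[2] && wz$span[2] >= w$span[1] &&
        presence$j_at[sp, Z] > presence$j_at[sp, cl]
    }, logical(1)))
  }

  ## moved families for a move X -> Y with descendants `cl_sp`
  moved_families <- function(X, Y, cl_sp) {
    inside <- intersect(cl_sp, sp_all)
    outside <- setdiff(sp_all, cl_sp)
    Ysig <- presence$clusters[[match(Y, cl_ids)]]$sig_union
    moved <- presence$focal_family
    ## "was at the old locus" must hold broadly, not just in a few outside
    ## species (a recent local acquisition elsewhere is not ancestral cargo)
    out_with_X <- outside[presence$locus_here[outside, X]]
    ## a family already resident at the destination region in outside
    ## genomes is a landing-site flank, not cargo
    out_with_Y <- outside[presence$locus_here[outside, Y]]
    out_with_Y <- out_with_Y[vapply(out_with_Y, owns_window, logical(1),
                                    cl = Y)]
    for (f in Ysig) {
      at_Y_inside <- any(vapply(inside, function(sp) f %in% fam_here(sp, Y),
                                logical(1)))
      at_X_outside <- length(out_with_X) > 0 &&
        mean(vapply(out_with_X, function(sp) f %in% fam_here(sp, X),
                    logical(1))) >= 0.4
      resident_at_Y <- any(vapply(out_with_Y, function(sp)
        f %in% fam_here(sp, Y), logical(1)))
      still_at_X_inside <- any(vapply(inside, function(sp)
        f %in% fam_here(sp, X) &&
          !isTRUE(all.equal(fam_here(sp, X), fam_here(sp, Y))),
        logical(1)))
      ## a family counts as moved if it is at the new locus in descendants,
      ## was at the old locus outside, and left the old locus in descendants
      if (at_Y_inside && at_X_outside && !resident_at_Y &&
            !still_at_X_inside)
        moved <- c(moved, f)
    }
    unique(moved)
  }

  ## pass 1 (iterated): gains of focal-bearing clusters -> moves and
  ## duplications. A species that moved its focal copy onward from Y is
  ## re-counted as a past carrier of Y on the next iteration, so chained
  ## moves anchor each event on the branch where the copy first arrived.
  intact_carriers <- setNames(lapply(cl_ids, function(cl)
    sp_all[intactish[, cl]]), cl_ids)
  ext_carriers <- intact_carriers
  dollo_eff <- dollo_focal
  ## gain anchored on the extended carriers; losses (the pairing signal)
  ## from the intact carriers below that gain; occupancy losses additionally
  ## honor vestige traces (a pseudogene at the locus proves the lineage
  ## held it until recently)
  min_losses <- function(node, carriers) {
    losses <- integer(0)
    recurse <- function(v) {
      kids <- which(ti$tree$edge[, 1] == v)
      for (k in kids) {
        child <- ti$tree$edge[k, 2]
        if (!any(carriers %in% ti$desc[[child]])) losses <<- c(losses, k)
        else if (child > ti$ntip) recurse(child)
      }
    }
    recurse(node)
    losses
  }
  dollo_place_mixed <- function(ext, intact, traced) {
    if (!length(ext)) return(list(gain = NA, losses = integer(0),
                                  losses_occ = integer(0),
                                  losses_strong = integer(0)))
    dp <- dollo_place(ti, ext)
    node <- if (identical(dp$gain, "root")) ti$root
            else ti$tree$edge[dp$gain, 2]
    list(gain = dp$gain, losses = min_losses(node, intact),
         losses_occ = min_losses(node, union(traced, ext)),
         losses_strong = min_losses(node, union(traced, intact)))
  }

  traced_carriers <- setNames(lapply(cl_ids, function(cl)
    sp_all[anyfocal[, cl]]), cl_ids)
  for (iter in 1:4) {
    dollo_eff <- setNames(lapply(cl_ids, function(cl)
      dollo_place_mixed(ext_carriers[[cl]], intact_carriers[[cl]],
                        traced_carriers[[cl]])), cl_ids)
    ## the focal family is assumed present in the root ancestor: if
    ## parsimony leaves the root unoccupied, the most ancestral cluster is
    ## the ancestral locus and its gain is pulled up to the root
    has_gain <- vapply(cl_ids, function(cl)
      !is.na(dollo_eff[[cl]]$gain[1]), logical(1))
    if (any(has_gain) &&
          !any(vapply(cl_ids[has_gain], function(cl)
            identical(dollo_eff[[cl]]$gain, "root"), logical(1)))) {
      sizes <- vapply(cl_ids, function(cl) {
        if (!has_gain[cl]) return(-1)
        g <- dollo_eff[[cl]]$gain
        length(ti$desc[[ti$tree$edge[g, 2]]]) +
          length(ext_carriers[[cl]]) / (ti$ntip + 1)
      }, numeric(1))
      anc <- cl_ids[which.max(sizes)]
      dollo_eff[[anc]] <- list(
        gain = "root",
        losses = min_losses(ti$root, intact_carriers[[anc]]),
        losses_occ = min_losses(ti$root, union(traced_carriers[[anc]],
                                               ext_carriers[[anc]])),
        losses_strong = min_losses(ti$root,
                                   union(traced_carriers[[anc]],
                                         intact_carriers[[anc]])))
    }
    occupied <- build_occupied(dollo_eff)
    occupied_strong <- build_occupied(dollo_eff, strong = TRUE)
    occ_tips <- setNames(lapply(cl_ids, function(cl)
      ti$tree$tip.label[occupied[seq_len(ti$ntip), cl]]), cl_ids)
    events <- list()
    consumed_losses <- list()
    move_sources <- character(0)
    gained_cls <- cl_ids[vapply(cl_ids, function(cl)
      !is.na(dollo_eff[[cl]]$gain[1]) && !identical(dollo_eff[[cl]]$gain,
                                                    "root"), logical(1))]

    ## the source of a gain: walking rootward from the gain, the first node
    ## where another cluster is occupied -- either at the node itself or in
    ## a cousin subtree (the ancestral state may have decayed away in the
    ## direct ancestors)
    ## Collect candidate sources along the whole rootward walk, then rank by
    ## move-specific evidence: co-moved cargo families and vestiges tie a
    ## destination to its true source; among evidence ties, occupancy of the
    ## ancestral lineage itself ("here") beats cousin-only occupancy, then a
    ## loss on/adjacent to the gain branch, then the most specific occupied
    ## region.
    ## species whose surviving vestige at X is already accounted for by a
    ## previously built duplication/alternate-retention event out of X
    claimed_for <- function(X, Y) {
      out <- character(0)
      for (m in ev_by_dest) {
        if (is.null(m) || !identical(m$source, X) || identical(m$dest, Y))
          next
        if (m$type == "dup_alt_retention")
          out <- union(out, intersect(m$clade, sp_all))
      }
      out
    }

    find_source <- function(Y, gY, exclude = character(0)) {
      cl_sp <- edge_clade(gY)
      node <- ti$tree$edge[gY, 1]
      cands <- character(0); here_flag <- logical(0); depth <- numeric(0)
      strong_flag <- logical(0)
      d <- 0
      repeat {
        d <- d + 1
        here <- occupied[node, ]
        strong <- occupied_strong[node, ]
        cousin <- vapply(cl_ids, function(cl)
          length(intersect(occ_tips[[cl]],
                           setdiff(ti$desc[[node]], cl_sp))) > 0, logical(1))
        found <- setdiff(cl_ids[here | cousin], c(Y, exclude, cands))
        if (length(found)) {
          cands <- c(cands, found)
          here_flag <- c(here_flag, setNames(here[found], found))
          strong_flag <- c(strong_flag, setNames(strong[found], found))
          depth <- c(depth, rep(d, length(found)))
        }
        pe <- ti$parent_edge[node]
        if (pe == 0) break
        node <- ti$tree$edge[pe, 1]
      }
      if (!length(cands)) return(NA_character_)
      sc <- vapply(seq_along(cands), function(i) {
        cl <- cands[i]
        evid <- length(moved_families(cl, Y, cl_sp)) - 1 +
          2 * vestige_for(cl, Y, cl_sp, claimed_for(cl, Y))
        lp <- dollo_eff[[cl]]$losses
        loss_rank <- if (gY %in% lp) 2
        else if (any(vapply(lp, function(e) is_ancestor_edge(e, gY) ||
                              is_ancestor_edge(gY, e), logical(1)))) 1
        else 0
        ## a loss exactly on the gain branch is the strongest pairing signal
        ## after move-specific evidence; then attested occupancy of the
        ## ancestral lineage, then proximity
        1e7 * evid + 1e5 * (loss_rank == 2) + 4e4 * strong_flag[i] +
          1e4 * here_flag[i] - 100 * depth[i] + 10 * (loss_rank == 1) -
          length(occ_tips[[cl]]) / ti$ntip
      }, numeric(1))
      vcat("    cands for", Y, ":", paste(sprintf("%s(%s%s,d%d,%.0f)", cands,
           ifelse(here_flag, "here", "cousin"),
           ifelse(strong_flag, "+", ""), depth, sc), collapse = " "),
           "\n")
      cands[which.max(sc)]
    }

    ## build the event for a gain of Y sourced from X
    build_event <- function(X, Y, gY) {
      cl_sp <- edge_clade(gY)
      X_lost_below <- !any(intactish[intersect(cl_sp, sp_all), X])
      if (!X_lost_below) {
        both <- any(intactish[intersect(cl_sp, sp_all), X] &
                      intactish[intersect(cl_sp, sp_all), Y])
        return(new_event("dup_coretention", gY, cl_sp, source = X, dest = Y,
                         genes_moved = presence$focal_family,
                         both_loci_occupied = both))
      }
      ## a move (species that carried Y but moved the copy onward are folded
      ## into the gain clade by the carrier-extension iteration)
      b <- gY
      cl_b <- edge_clade(b)
      fams <- moved_families(X, Y, cl_b)
      vest <- vestige_for(X, Y, cl_b, claimed_for(X, Y))
      loss_edges <- dollo_eff[[X]]$losses
      uncertain <- !(b %in% loss_edges) &&
        !any(vapply(loss_edges, function(e)
          is_ancestor_edge(e, b) || is_ancestor_edge(b, e), logical(1)))
      type <- if (vest) "dup_alt_retention"
              else if (length(fams) >= 2) "block_translocation"
              else "single_gene_move_ambiguous"
      new_event(type, b, cl_b, source = X, dest = Y, genes_moved = fams,
                vestige_found = vest, branch_uncertain = uncertain)
    }

    ## ancestral-first processing
    ord <- order(vapply(gained_cls, function(cl)
      -length(edge_clade(dollo_eff[[cl]]$gain)), numeric(1)))
    ev_by_dest <- list()
    for (Y in gained_cls[ord]) {
      gY <- dollo_eff[[Y]]$gain
      X <- find_source(Y, gY)
      vcat("iter", iter, "gain", Y, "at {",
           paste(edge_clade(gY), collapse = ","), "} source:", X, "\n")
      if (is.na(X)) next  # no source: independent origin, leave unpaired
      ev_by_dest[[Y]] <- build_event(X, Y, gY)
      vcat("   ->", ev_by_dest[[Y]]$type, "\n")
    }

    ## resolve mutually sourced pairs (A from B and B from A): keep the
    ## direction carrying more co-moved cargo (or a vestige), re-source the
    ## other without its partner
    for (Y in names(ev_by_dest)) {
      e1 <- ev_by_dest[[Y]]
      if (is.null(e1) || is.na(e1$source)) next
      A <- e1$source
      e2 <- ev_by_dest[[A]]
      if (is.null(e2) || !identical(e2$source, Y)) next
      keep_e1 <- if (e1$evidence$vestige_found != e2$evidence$vestige_found)
        e1$evidence$vestige_found
      else if (e1$evidence$n_genes_comoved != e2$evidence$n_genes_comoved)
        e1$evidence$n_genes_comoved > e2$evidence$n_genes_comoved
      else if (length(e1$clade) != length(e2$clade))
        length(e1$clade) < length(e2$clade)  # the younger locus is the dest
      else Y > A  # deterministic tie-break
      loser <- if (keep_e1) A else Y
      partner <- if (keep_e1) Y else A
      vcat("iter", iter, "mutual pair", Y, "<->", A, ": keep dest",
           if (keep_e1) Y else A, "\n")
      gL <- dollo_eff[[loser]]$gain
      X2 <- find_source(loser, gL, exclude = partner)
      ev_by_dest[[loser]] <- if (is.na(X2)) NULL
                             else build_event(X2, loser, gL)
    }

    for (Y in names(ev_by_dest)) {
      e <- ev_by_dest[[Y]]
      if (is.null(e)) next
      events[[length(events) + 1]] <- e
      move_sources <- c(move_sources, e$source)
      if (e$type != "dup_coretention") {
        loss_edges <- dollo_eff[[e$source]]$losses
        consumed_losses[[e$source]] <-
          union(consumed_losses[[e$source]] %||% integer(0),
                loss_edges[vapply(loss_edges, function(ed)
                  identical(ed, e$branch) ||
                    is_ancestor_edge(ed, e$branch) ||
                    is_ancestor_edge(e$branch, ed), logical(1))])
      }
    }

    ## extend carriers through the moves found in this iteration
    new_ext <- intact_carriers
    for (e in events) {
      if (is.na(e$source) ||
            !e$type %in% c("block_translocation",
                           "single_gene_move_ambiguous",
                           "dup_alt_retention")) next
      new_ext[[e$source]] <- union(new_ext[[e$source]],
                                   intersect(e$clade, sp_all))
    }
    if (identical(lapply(new_ext, sort), lapply(ext_carriers, sort))) break
    ext_carriers <- new_ext
  }
  dollo_focal <- dollo_eff  # later passes use the final placements

  ## pass 2: neighbor acquisitions at focal loci that pre-date the family
  move_list <- Filter(function(e)
    e$type %in% c("block_translocation", "single_gene_move_ambiguous",
                  "dup_alt_retention", "dup_coretention"), events)
  gt <- presence$gene_table
  acq <- list()  # key: branch clade string + dest -> families
  for (ci in seq_along(cl_ids)) {
    Y <- cl_ids[ci]
    gL <- dollo_locus[[Y]]$gain
    if (is.na(gL[1])) next
    ## families that arrived at Y as part of a move/duplication into Y are
    ## move cargo, not acquisitions
    cargo <- unique(unlist(lapply(move_list, function(m)
      if (identical(m$dest, Y)) m$genes_moved else character(0))))
    ## candidate families: everything ever observed at this locus's windows
    fam_universe <- unique(c(presence$clusters[[ci]]$sig_union,
                             unlist(presence$fam_at[, ci])))
    for (f in setdiff(fam_universe, cargo)) {
      direct <- sp_all[vapply(sp_all, function(sp)
        f %in% fam_here(sp, Y) && owns_window(sp, Y), logical(1))]
      ## project presence through moves out of Y that carried f
      proj <- direct
      for (m in move_list) {
        if (!identical(m$source, Y)) next
        if (f %in% m$genes_moved)
          proj <- union(proj, intersect(m$clade, sp_all))
      }
      if (!length(proj)) next
      dp <- dollo_place(ti, proj)
      gf <- dp$gain
      if (identical(gf, "root") || is.na(gf[1])) next
      if (identical(gf, gL) || is_ancestor_edge(gf, gL)) next  # locus flank
      if (!is_ancestor_edge(gL, gf) && !identical(gL, "root")) next
      ## the family must exist elsewhere in at least one non-descendant genome
      outside <- setdiff(sp_all, edge_clade(gf))
      src_elsewhere <- any(vapply(outside, function(sp)
        f %in% gt$gene_family[gt$species == sp], logical(1)))
      if (!src_elsewhere) next
      key <- paste(clade_str(edge_clade(gf)), Y, sep = "|")
      acq[[key]] <- list(branch = gf, clade = edge_clade(gf), dest = Y,
                         fams = c(acq[[key]]$fams, f))
    }
  }
  for (a in acq) {
    events[[length(events) + 1]] <-
      new_event("neighbor_acquisition", a$branch, a$clade, dest = a$dest,
                genes_moved = a$fams)
  }

  ## pass 3: tandem duplications
  if (!is.null(tandem) && nrow(tandem)) {
    gt2 <- presence$gene_table
    byc <- split(tandem, vapply(seq_len(nrow(tandem)), function(i) {
      ## cluster of the first copy's context
      ctx_i <- which(vapply(presence$contexts, function(cx)
        cx$gene_id == tandem$gene1[i] && cx$species == tandem$species[i],
        logical(1)))
      if (!length(ctx_i)) return("?")
      hit <- which(vapply(presence$clusters, function(cl)
        ctx_i[1] %in% cl$members, logical(1)))
      if (length(hit)) cl_ids[hit[1]] else "?"
    }, character(1)))
    ## split flagged species into clade-consistent groups: independent
    ## tandems in different subtrees are separate events
    clade_groups <- function(spp) {
      if (length(spp) <= 1) return(list(spp))
      node <- ape::getMRCA(ti$tree, match(spp, ti$tree$tip.label))
      inclade <- ti$desc[[node]]
      if (setequal(spp, inclade)) return(list(spp))
      kids <- ti$tree$edge[ti$tree$edge[, 1] == node, 2]
      out <- list()
      for (kd in kids) {
        sub <- intersect(spp, ti$desc[[kd]])
        if (length(sub)) out <- c(out, clade_groups(sub))
      }
      out
    }
    for (cl in names(byc)) {
      spp <- unique(byc[[cl]]$species)
      for (grp in clade_groups(spp)) {
        dp <- dollo_place(ti, grp)
        events[[length(events) + 1]] <-
          new_event("tandem_dup",
                    if (identical(dp$gain, "root")) "root" else dp$gain,
                    if (identical(dp$gain, "root")) ti$tree$tip.label
                    else edge_clade(dp$gain),
                    source = if (cl == "?") NA else cl,
                    dest = if (cl == "?") NA else cl,
                    genes_moved = presence$focal_family)
      }
    }
  }

  ## pass 4: unexplained losses -> pseudogenization or loss
  for (X in cl_ids) {
    dp <- dollo_focal[[X]]
    if (is.na(dp$gain[1])) {
      ## never intact anywhere: pseudogene-only cluster
      carriers <- sp_all[anyfocal[, X]]
      if (length(carriers)) {
        d2 <- dollo_place(ti, carriers)
        events[[length(events) + 1]] <-
          new_event("pseudogenization",
                    if (identical(d2$gain, "root")) "root" else d2$gain,
                    if (identical(d2$gain, "root")) ti$tree$tip.label
                    else edge_clade(d2$gain),
                    source = X, dest = X)
      }
      next
    }
    for (e in dp$losses) {
      if (e %in% (consumed_losses[[X]] %||% integer(0))) next
      ## a move event below this loss with source X also explains it
      below_move <- any(vapply(move_list, function(m)
        identical(m$source, X) &&
          (identical(m$branch, e) || is_ancestor_edge(e, m$branch)),
        logical(1)))
      if (below_move) next
      cl_sp <- edge_clade(e)
      pseudo_here <- any(fs[intersect(cl_sp, sp_all), X] == "pseudogene")
      events[[length(events) + 1]] <-
        new_event(if (pseudo_here) "pseudogenization" else "loss",
                  e, cl_sp, source = X, dest = X)
    }
  }

  ## order: ancestral branches first (larger clades first, then by clade)
  ev_sizes <- vapply(events, function(e) length(e$clade), numeric(1))
  ev_keys <- vapply(events, function(e) clade_str(e$clade), character(1))
  events <- events[order(-ev_sizes, ev_keys)]

  structure(list(events = events, presence_matrix = fs, tree = ti$tree,
                 clusters = presence$clusters),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat("event chronology (", length(x$events), " events)\n", sep = "")
  for (e in x$events) {
    cat(sprintf("- %-26s %s -> %s  [%d gene(s)%s%s] clade: %s\n",
                e$type,
                ifelse(is.na(e$source), "?", e$source),
                ifelse(is.na(e$dest), "?", e$dest),
                e$evidence$n_genes_comoved,
                if (e$evidence$vestige_found) ", vestige" else "",
                if (e$evidence$both_loci_occupied) ", both loci" else "",
                paste(head(sort(e$clade), 4), collapse = ",")))
  }
  invisible(x)
}

#' Count transposition/duplication events in a chronology
#'
#' Counts events of the move/duplication classes (block translocation,
#' ambiguous single-gene move, duplication with alternate retention or
#' co-retention, tandem duplication, neighbor acquisition); losses and
#' pseudogenizations are bookkeeping, not transposition events.
#'
#' @param chronology a [infer_events()] result
#' @param species optional species subset: only events whose clade lies
#'   within this set are counted
#' @return integer count
#' @export
count_transposition_events <- function(chronology, species = NULL) {
  types <- c("block_translocation", "single_gene_move_ambiguous",
             "dup_alt_retention", "dup_coretention", "tandem_dup",
             "neighbor_acquisition")
  sum(vapply(chronology$events, function(e) {
    if (!e$type %in% types) return(FALSE)
    if (!is.null(species) && !all(e$clade %in% species)) return(FALSE)
    TRUE
  }, logical(1)))
}

#' Intron retention check across gene copies
#'
#' Projects intron positions to CDS coordinates (cumulative exon length at
#' the intron, in transcription order). A copy is `retained` iff it shares at
#' least one intron position with the family consensus (positions present in
#' at least half the copies); an intronless copy in a multi-intron family is
#' flagged retro-like.
#'
#' @param copies named list; per copy a list with `exons` (two-column matrix
#'   of genomic start/end, 0-based half-open) and `strand`
#' @return data.frame with copy, n_introns, retained, retro_like; attribute
#'   `consensus` holds the shared intron CDS positions
#' @export
check_intron_retention <- function(copies) {
  if (length(copies) < 2) stop("need at least 2 copies")
  intron_pos <- lapply(copies, function(cp) {
    ex <- cp$exons[order(cp$exons[, 1]), , drop = FALSE]
    if (identical(cp$strand, "-")) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    lens <- ex[, 2] - ex[, 1]
    if (length(lens) <= 1) return(integer(0))
    cumsum(lens)[-length(lens)]
  })
  if (all(lengths(intron_pos) == 0))
    stop("all copies are single-exon: intron retention undecidable")
  allpos <- sort(unique(unlist(intron_pos)))
  support <- vapply(allpos, function(p)
    sum(vapply(intron_pos, function(x) p %in% x, logical(1))), numeric(1))
  consensus <- allpos[support >= length(copies) / 2]
  multi <- sum(lengths(intron_pos) > 0) >= 1
  res <- data.frame(
    copy = names(copies),
    n_introns = lengths(intron_pos),
    retained = vapply(intron_pos, function(x) any(x %in% consensus),
                      logical(1)),
    retro_like = lengths(intron_pos) == 0 & multi,
    row.names = NULL)
  attr(res, "consensus") <- consensus
  res
}
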