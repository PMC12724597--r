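## End-to-end chronology inference on simulated histories, and scoring of
## event recovery against the truth log.

#' Run the synteny inference chain on a combined gene table
#'
#' Contexts -> clustering -> presence -> tandem detection -> event inference.
#'
#' @param gene_table combined multi-species gene table
#' @param tree species tree
#' @param k neighbor window per side
#' @param min_jaccard clustering / locus-presence threshold
#' @param focal_family focal family name
#' @param seqs optional nested list `seqs[[species]][[gene_id]]` for tandem
#'   identity
#' @param tandem optional precomputed tandem table (overrides `seqs`)
#' @param tandem_min_identity tandem identity threshold (percent)
#' @return a `chronology` (see [infer_events()])
#' @export
infer_chronology <- function(gene_table, tree, k = 3, min_jaccard = 0.34,
                             focal_family = FOCAL_FAMILY, seqs = NULL,
                             tandem = NULL, tandem_min_identity = 97) {
  cx <- extract_all_contexts(gene_table, k, focal_family)
  cl <- match_loci_across_species(cx, min_jaccard)
  pr <- locus_presence(gene_table, cx, cl, k, min_jaccard, focal_family)
  if (is.null(tandem))
    tandem <- find_tandem_copies(gene_table, seqs,
                                 min_identity = tandem_min_identity,
                                 focal_family = focal_family)
  infer_events(tree, pr, tandem)
}

#' Combined gene table of a simulated history
#'
#' @param history a `locus_history`
#' @return data.frame over all tip genomes
#' @export
history_gene_table <- function(history) {
  do.call(rbind, lapply(names(history$genomes), function(sp)
    species_gene_table(history$genomes[[sp]], sp)))
}

## per-species gene_id -> sequence lookup for tandem identity
history_seqs <- function(history) {
  lapply(history$genomes, function(g)
    lapply(g$genes, function(x) x$seq))
}

#' Infer the chronology of a simulated history
#'
#' @param history a `locus_history`
#' @param ... passed to [infer_chronology()]
#' @return a `chronology`
#' @export
infer_history_events <- function(history, ...) {
  infer_chronology(history_gene_table(history), history$truth$tree,
                   seqs = history_seqs(history), ...)
}

## status of a gene id in a tip genome ("absent" if not on a contig)
tip_gene_status <- function(genome, id) {
  if (!id %in% unlist(genome$contigs)) return("absent")
  genome$genes[[id]]$status
}

#' Score inferred events against the truth log of a simulated history
#'
#' Each logged structural event is assigned the evidence class it is
#' identifiable as from the extant genomes alone:
#' a multi-gene relocation is identifiable as a block translocation; a
#' duplication/alternate-retention whose source vestige survives in at least
#' one descendant is identifiable as such; a co-retention with both copies
#' intact somewhere is identifiable; a tandem duplication whose copies remain
#' adjacent and near-identical (>= `tandem_min_identity`) is identifiable.
#' A single-gene move whose vestige never existed or fully decayed must be
#' labeled ambiguous and never given a definite type. Events whose evidence
#' was destroyed or confounded by later events (source locus holding several
#' intact copies at event time, destination not surviving to any tip, or
#' survivors no longer spanning the event branch) are not scoreable and are
#' excluded.
#'
#' @param history a `locus_history`
#' @param chronology optional precomputed chronology (default: inferred with
#'   [infer_history_events()])
#' @param tandem_min_identity tandem identity threshold (percent)
#' @return data.frame with one row per logged structural event: type, clade,
#'   identifiable, expected_type, recovered
#' @export
score_event_recovery <- function(history, chronology = NULL,
                                 tandem_min_identity = 97) {
  if (is.null(chronology)) chronology <- infer_history_events(history)
  truth <- history$truth$events
  tips <- history$genomes
  tipnames <- names(tips)
  ev_inf <- chronology$events
  inf_key <- vapply(ev_inf, function(e)
    paste(e$type, paste(sort(e$clade), collapse = ","), sep = "|"),
    character(1))
  inf_clades <- vapply(ev_inf, function(e)
    paste(sort(e$clade), collapse = ","), character(1))
  inf_types <- vapply(ev_inf, `[[`, character(1), "type")
  definite <- c("block_translocation", "dup_alt_retention", "dup_coretention")

  carriers_of <- function(id, status = "intact") {
    tipnames[vapply(tipnames, function(sp)
      tip_gene_status(tips[[sp]], id) == status, logical(1))]
  }
  ## clades of the two root children: a trace-free move spanning exactly one
  ## of them has no witness to which locus is ancestral (no outgroup), so
  ## its direction is not identifiable
  tr0 <- ape::reorder.phylo(history$truth$tree, "postorder")
  root_kids <- tr0$edge[tr0$edge[, 1] == tr0$edge[nrow(tr0$edge), 1], 2]
  desc0 <- descendant_tips(tr0)
  root_clades <- lapply(root_kids, function(v) sort(desc0[[v]]))
  is_root_child_clade <- function(clade)
    any(vapply(root_clades, function(x) setequal(x, clade), logical(1)))
  rows <- list()
  st_rows <- truth[truth$type %in% c("relocation", "dup_alt_retention",
                                     "dup_coretention", "tandem_dup"), ,
                   drop = FALSE]
  for (i in seq_len(nrow(st_rows))) {
    tr <- st_rows[i, ]
    clade <- sort(strsplit(tr$clade, ",")[[1]])
    ckey <- paste(clade, collapse = ",")
    identifiable <- TRUE
    expected <- NA_character_
    if (tr$type == "relocation") {
      ids <- strsplit(tr$genes, ",")[[1]]
      foc_ids <- ids[grepl("^g_focal", ids)]
      nonfoc <- setdiff(ids, foc_ids)
      ## destination must survive: a moved focal copy intact at the
      ## destination contig in every clade tip and nowhere truncated (gene
      ## ids recur across genomes, so the location pins the moved copy)
      carr <- tipnames[vapply(tipnames, function(sp) {
        any(vapply(foc_ids, function(id) {
          if (tip_gene_status(tips[[sp]], id) != "intact") return(FALSE)
          gene_location(tips[[sp]], id)$contig == tr$dest_contig
        }, logical(1)))
      }, logical(1))]
      carr <- intersect(carr, clade)  # outside copies are unrelated homonyms
      if (tr$n_intact_src > 1 || !length(carr) || !setequal(carr, clade)) {
        identifiable <- FALSE
      } else if (is_root_child_clade(clade)) {
        identifiable <- FALSE  # direction has no witness (no outgroup)
      } else if (length(nonfoc) == 0 && tr$n_intact_total > 1) {
        ## a clean single-gene move in a genome that co-retains another
        ## intact copy: equally parsimonious as an independent duplication
        identifiable <- FALSE
      } else {
        expected <- if (length(nonfoc) >= 1) "block_translocation"
                    else "single_gene_move_ambiguous"
      }
    } else if (tr$type == "dup_alt_retention") {
      carr <- carriers_of(tr$new_id)
      ## the copy must still sit at this event's destination: a later move
      ## that relocated it elsewhere destroys this event's branch evidence
      carr <- carr[vapply(carr, function(sp)
        gene_location(tips[[sp]], tr$new_id)$contig == tr$dest_contig,
        logical(1))]
      vest <- intersect(carriers_of(tr$src_gene, "pseudogene"), clade)
      if (tr$n_intact_src > 1 || !length(carr) || !setequal(carr, clade)) {
        identifiable <- FALSE
      } else if (!length(vest) && is_root_child_clade(clade)) {
        identifiable <- FALSE  # direction has no witness (no outgroup)
      } else if (!length(vest) && tr$n_intact_total > 1) {
        identifiable <- FALSE  # confounded by a co-retained intact copy
      } else {
        expected <- if (length(vest)) "dup_alt_retention"
                    else "single_gene_move_ambiguous"
      }
    } else if (tr$type == "dup_coretention") {
      both <- tipnames[vapply(tipnames, function(sp)
        tip_gene_status(tips[[sp]], tr$src_gene) == "intact" &&
          tip_gene_status(tips[[sp]], tr$new_id) == "intact", logical(1))]
      carr <- carriers_of(tr$new_id)
      carr <- carr[vapply(carr, function(sp)
        gene_location(tips[[sp]], tr$new_id)$contig == tr$dest_contig,
        logical(1))]
      if (!length(both) || !length(carr) || !setequal(carr, clade))
        identifiable <- FALSE
      else expected <- "dup_coretention"
    } else if (tr$type == "tandem_dup") {
      qual <- tipnames[vapply(tipnames, function(sp) {
        g <- tips[[sp]]
        if (tip_gene_status(g, tr$src_gene) != "intact" ||
              tip_gene_status(g, tr$new_id) != "intact") return(FALSE)
        l1 <- gene_location(g, tr$src_gene); l2 <- gene_location(g, tr$new_id)
        if (l1$contig != l2$contig || abs(l1$index - l2$index) - 1 > 2)
          return(FALSE)
        percent_identity(g$genes[[tr$src_gene]]$seq,
                         g$genes[[tr$new_id]]$seq) >= tandem_min_identity
      }, logical(1))]
      if (!length(qual) || !setequal(qual, clade)) identifiable <- FALSE
      else expected <- "tandem_dup"
    }
    recovered <- NA
    if (identifiable && !is.na(expected)) {
      hit <- paste(expected, ckey, sep = "|") %in% inf_key
      if (expected == "single_gene_move_ambiguous") {
        mislabeled <- any(inf_clades == ckey & inf_types %in% definite)
        recovered <- hit && !mislabeled
      } else recovered <- hit
    }
    rows[[length(rows) + 1]] <- data.frame(
      type = tr$type, clade = ckey, identifiable = identifiable,
      expected_type = expected, recovered = recovered,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(type = character(), clade = character(),
                  identifiable = logical(), expected_type = character(),
                  recovered = logical())
}
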