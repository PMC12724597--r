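## Packaged locus-context fixture: a transcription of the published Cenp-C
## locus arrangements across the montium species group and four outgroups,
## with the corresponding species tree. The "fig4" variant restricts the
## table to the scope of the five-step event chronology (no D. burlai, no
## D. birchii tandem copies).

#' Load the packaged Cenp-C locus-context fixture
#'
#' @param variant "full" (all reported loci and fragments) or "fig4" (the
#'   five-step chronology scope: D. burlai and the D. birchii tandem copies
#'   excluded)
#' @return gene table (see [read_context_table()])
#' @export
paper_contexts <- function(variant = c("full", "fig4")) {
  variant <- match.arg(variant)
  f <- if (variant == "fig4") "paper_contexts_fig4.tsv" else "paper_contexts.tsv"
  read_context_table(system.file("extdata", f, package = "syntrace",
                                 mustWork = TRUE))
}

#' Load the packaged montium-group species tree
#'
#' @return `phylo` tree with the 18 montium species and 4 outgroups
#' @export
montium_tree <- function() {
  ape::read.tree(system.file("extdata", "montium_tree.nwk",
                             package = "syntrace", mustWork = TRUE))
}

#' Names of the montium-group species in the packaged fixture
#' @return character vector
#' @export
montium_species <- function() {
  setdiff(montium_tree()$tip.label,
          c("D.melanogaster", "D.ananassae", "D.virilis", "S.lebanonensis"))
}

#' Infer the Cenp-C event chronology from the packaged fixture
#'
#' Runs context extraction, locus clustering, presence mapping, tandem
#' detection (using the fixture's identity column) and event inference.
#'
#' @param variant fixture variant, see [paper_contexts()]
#' @param k,min_jaccard clustering parameters
#' @return a `chronology`
#' @export
paper_chronology <- function(variant = c("fig4", "full"), k = 3,
                             min_jaccard = 0.34) {
  variant <- match.arg(variant)
  gt <- paper_contexts(variant)
  tr <- ape::keep.tip(montium_tree(), unique(gt$species))
  infer_chronology(gt, tr, k = k, min_jaccard = min_jaccard,
                   focal_family = "Cenp-C")
}

#' Load the packaged synthetic reference protein alignment
#'
#' A synthetic stand-in for a curated reference alignment of the focal
#' protein across ten melanogaster-group species: motif windows are highly
#' conserved, the remainder diverged, the critical arginine (position 1101
#' of the ungapped reference) invariant. Generated once with a fixed seed;
#' it emulates the structure, not the sequence, of real data.
#'
#' @return named character vector of aligned protein strings
#' @export
reference_msa <- function() {
  read_fasta(system.file("extdata", "synthetic_ref_msa.fasta",
                         package = "syntrace", mustWork = TRUE))
}

#' Load the packaged motif definition table
#'
#' Eight motif windows on the ungapped reference protein (1-based,
#' inclusive): the 45-residue N-terminal Mis12C-binding window fixed at
#' 1-45, plus R-rich, DH, AT1, AT2, NLS, the CenH3-binding Cenp-C motif
#' (containing the invariant R1101) and the C-terminal Cupin dimerization
#' domain. Coordinates of the seven classical motifs are package defaults,
#' overridable by supplying another table.
#'
#' @return data.frame with name, start, end, width
#' @export
motif_definitions <- function() {
  read_motif_defs(system.file("extdata", "motif_defs.tsv",
                              package = "syntrace", mustWork = TRUE))
}

#' Count focal-gene-bearing locus clusters
#'
#' Number of locus clusters in which at least one of the given species
#' carries a focal copy of an accepted status (intact or undisrupted
#' fragment by default; decayed pseudogenes do not define a locus).
#'
#' @param presence a [locus_presence()] object
#' @param species species subset (default all)
#' @param statuses statuses that count as a bona fide copy
#' @return integer count
#' @export
count_focal_bearing_clusters <- function(presence, species = NULL,
                                         statuses = c("intact", "fragment")) {
  fs <- presence$focal_status
  if (!is.null(species))
    fs <- fs[intersect(rownames(fs), species), , drop = FALSE]
  sum(apply(fs, 2, function(col) any(col %in% statuses)))
}
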