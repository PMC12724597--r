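#' Simulate a species tree
#'
#' Rooted binary ultrametric tree under a pure-birth (Yule) process, rescaled
#' to a fixed root-to-tip height in expected substitutions per site.
#' Identical inputs give identical output.
#'
#' @param n_taxa number of tips (>= 3)
#' @param birth_rate speciation rate of the Yule process
#' @param seed RNG seed
#' @param height root-to-tip depth after rescaling (substitutions/site)
#' @param labels optional tip labels (default sp01, sp02, ...)
#' @param min_internal if positive, redraw (deterministically from the seed)
#'   until every internal branch is at least this long after rescaling --
#'   emulating a strongly supported, well-resolved species phylogeny with no
#'   effectively-zero internal edges
#' @return rooted ultrametric `phylo` tree
#' @export
generate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1,
                                  height = 0.08, labels = NULL,
                                  min_internal = 0) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  stopifnot(birth_rate > 0, height > 0)
  for (attempt in 0:500) {
    tr <- with_seed(child_seed(seed, attempt),
                    ape::rphylo(n_taxa, birth = birth_rate, death = 0))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth * height
    internal <- tr$edge[, 2] > n_taxa
    if (!any(internal) || min(tr$edge.length[internal]) >= min_internal)
      break
  }
  tr$tip.label <- labels %||% sprintf("sp%02d", seq_len(n_taxa))
  tr
}
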