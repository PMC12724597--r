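---
title: "Tracing gene relocation histories from synteny, motifs, trees and polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gene relocation histories from synteny, motifs, trees and polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An essential single-copy gene can change its genomic address over evolutionary
time without ever changing its function: it may translocate to a new locus
(alone or with neighboring genes), or duplicate into a new locus with the
ancestral copy subsequently lost ("alternate retention"). Across a species
group this produces the confusing signature of one orthologous gene sitting in
several distinct syntenic locations. The centromeric protein gene Cenp-C in
the montium group of *Drosophila* is the motivating case: most species carry a
single functional copy, but at five different syntenic loci, with one species
retaining two intact paralogs and one carrying a young tandem pair.

`syntrace` re-implements, as a tested and reusable pipeline, the inference
chain needed to reconstruct such a history:

1. translated (tBLASTn-style) homology search with pseudogene calling,
2. locus-context extraction and syntenic-locus clustering,
3. tree-aware inference of per-branch events,
4. PSSM motif scanning with exact null p-values and two-round refinement,
5. GTR+G+I phylogenetics with bootstrap and concordance tests,
6. unpolarized McDonald-Kreitman (MK) tests,

together with a locus-history simulator whose truth log makes every stage
testable end to end without any external data.

# Locus contexts and event inference

## Contexts and clustering

A **locus context** is the ordered, stranded list of up to `k = 3` annotated
neighbor families on each side of a focal-gene copy (other focal copies do not
consume window slots). Two contexts belong to the same **syntenic locus** when
the Jaccard similarity of their neighbor-family sets reaches `min_jaccard =
0.34`; clusters are single-linkage components, which makes the clustering
invariant to input order. The threshold encodes "one shared family out of two
3-per-side windows is not enough, two generally are": two windows sharing a
single family score at most 1/3 < 0.34, while two sharing half their families
score well above it.

## Presence, Dollo parsimony and occupancy

For every species x cluster pair the package records the focal-copy status
(intact / undisrupted fragment / pseudogene / absent) and whether the locus
itself -- its neighbor-family signature -- is present anywhere in the genome
(best sliding-window Jaccard match). Cluster gains are placed by Dollo
parsimony (single gain, unlimited losses): independent re-emergence of a gene
at the same syntenic context is biologically implausible at this scale. The
focal family is assumed present in the root ancestor; if parsimony leaves the
root unoccupied (the ancestral locus lost an entire root-child subtree), the
most ancestral cluster is pulled up to the root.

Three refinements matter in practice:

* **Carrier extension.** A species that once held a locus but moved its copy
  onward must still count toward the locus's gain placement. Event inference
  therefore iterates: moves found in one pass extend the carrier sets of
  their source clusters, and Dollo placements are recomputed, so chained
  moves anchor each event on the branch where the copy first arrived.
* **Graded occupancy.** For source attribution, candidates are ranked first
  by move-specific evidence (co-moved cargo families, vestiges), then by a
  loss falling exactly on the gain branch (the strongest pairing signal),
  then by occupancy attested by intact copies or surviving vestiges over
  occupancy implied only by the extension, then by proximity. Two guards
  keep the evidence honest: a vestige already accounted for by a previously
  inferred duplication out of the same source is not re-used as evidence
  for a nested move, and a family already resident at the destination
  region in outside genomes is a landing-site flank, not cargo (nor is a
  family found at the source in only a minority of the outside species that
  still carry the source locus -- that is a local acquisition, not
  ancestral content).
* **Evidence classes.** A gain paired with a source loss is classified by the
  event-record invariants: two or more co-moved families with no vestige give
  a *block translocation*; a surviving vestige -- a focal pseudogene at the
  source, or a pseudogene copy of a source family inside the destination
  window while the source copy stays intact -- gives *duplication with
  alternate retention*; both loci intact in one species give *co-retention*;
  a single moved gene with no vestige is *ambiguous*, because relocation and
  duplication/alternate retention cannot be distinguished once the vestige
  has decayed. Adjacent near-identical copies (at most 2 intervening genes,
  nucleotide identity at or above 97%) are *tandem duplications*. Neighbor
  families gained at a pre-existing focal locus from elsewhere in the genome
  are *neighbor acquisitions*; families that arrived as move cargo are
  excluded, and a family only counts as acquired if it exists elsewhere in
  at least one non-descendant genome.

## What the packaged fixture is

`paper_contexts()` transcribes published locus arrangements for 18 montium
species and 4 outgroups into the package's plain-text gene-table format,
including the ancestral locus, the five derived loci, the pseudogene
fragments, and the tandem pair (99.7% identity). Unnamed conserved flanking
genes at the ancestral locus are represented by synthetic padding families
(`pad1..pad4`), so that the outgroup whose 5' flank was replaced by a
lineage-specific rearrangement still clusters with the other outgroup
contexts, as the full contigs would. The `fig4` variant restricts the table to
the scope of the five-step chronology. `paper_chronology("fig4")` reproduces
that chronology: a two-gene neighbor acquisition at the ancestral locus, an
ambiguous single-gene move, a four-gene block translocation, a duplication
with alternate retention evidenced by the co-duplicated pseudogene, and a
co-retention -- five transposition/duplication events.

# The locus-history simulator

`simulate_locus_history()` evolves a root genome (one multi-exon focal gene of
1333 codons with 4 exons, plus 48 neighbor families over five contigs) along a
species tree. Per branch, at most one structural event of the focal family
occurs (keeping histories identifiable, matching the parsimony assumption of
the reconstruction): relocation of a 1-4 gene block, duplication with
alternate retention (the source copy is frameshifted into a vestige),
duplication with co-retention, tandem duplication, or pseudogenization
(only where a second intact copy exists -- the gene is essential). Vestiges
are fully deleted with hazard `vestige_decay_rate = 20` per unit branch
length (pseudogene decay is fast on this timescale); TE copies from a small
synthetic library insert near focal loci; intact focal CDS evolve under a
codon model with `omega = 0.2`, `kappa = 2`, neighbors and introns neutrally;
intergenic spacers are held fixed (no inference stage reads them). The default
tree height is 0.08 substitutions/site, a montium-like divergence depth.

Two generator choices deserve emphasis because they emulate genome scale with
a toy gene complement:

* landing sites for relocations/duplications are drawn from interior
  intergenic positions at least 3 genes away from every previously used
  landing site and from any vacated focal locus (tracked globally across the
  history). In a real genome two independent events essentially never land
  within one context window of each other; without this, window collisions
  would create cluster mergers that are artifacts of the 53-gene genome, not
  of the method.
* `generate_species_tree(min_internal = ...)` redraws (deterministically in
  the seed) until every internal branch exceeds a floor, emulating a strongly
  supported, fully resolved species phylogeny.

Every random choice is written to a truth log; `replay_truth()` re-applies
the logged events and mutations and must reproduce the extant genomes
byte-identically -- the suite checks this for multiple seeds.

What passing simulation tests do **not** show about real data: the generator
has no indel evolution inside intact CDS, no recombination within population
samples, no TE sequence evolution, stable gene families (no birth/death of
neighbor families except via the modeled events), and identifiable single-event
branches. Real assemblies add fragmentation, annotation error, and gene
conversion, none of which are modeled.

## Scoring recovery

`score_event_recovery()` compares inferred chronologies with the truth log.
Each logged event is first assigned the evidence class it is *identifiable*
as from extant genomes alone: a multi-gene relocation should be recovered as
a block translocation; a duplication/alternate-retention with a surviving
vestige as such; a co-retention with both copies intact somewhere; a tandem
whose copies remain adjacent and >= 97% identical. A single-gene move whose
vestige never existed or fully decayed must be labeled ambiguous and never
given a definite type. Events whose evidence was destroyed or confounded --
several intact copies at the source when the event fired, no surviving
destination copy, survivors no longer spanning the event branch, or a
trace-free move spanning exactly one root-child subtree (with no outgroup
there is no witness to which locus is ancestral) -- are excluded as
unscoreable rather than counted either way.

# The tBLASTn-style search

The search translates the contig in all six frames, seeds frames containing
an exact 3-mer word match, and computes locally optimal affine-gap alignments
(Smith-Waterman, BLOSUM62, gap open 11 / extend 1) per seeded frame,
iterating with subject masking to report multiple HSPs. Two departures from a
naive full alignment recover the behavior of seeded extension:

* an **X-dropoff segmentation** (default 30) splits each raw alignment
  wherever the running column score falls that far below its maximum. A full
  local alignment otherwise happily aligns *through* an intron or a
  reverse-strand shadow segment whenever the flanking similarity pays for
  the bridge; real seeded extension would have terminated there and reported
  per-exon HSPs.
* in-frame **stop codons** are recorded for aligned columns only, never for
  gapped-out subject stretches, never at the query's terminal position, and
  never in junction zones where neighboring chained HSPs overlap on the
  query (exon-boundary alignments overhang into introns, making those
  columns ambiguous).

Chaining is colinear and strand-consistent with intron-scale gaps (>= 40 bp
after trimming query overlaps) exempt from the frameshift rule. Classification
follows the stated thresholds: disruptions force `pseudogene`; coverage >= 0.9
with none gives `intact`; below that `fragment`, unless a missing internal
query segment is recovered on the opposite strand inside the chain span, which
flags an `inversion_candidate` (the assembly-artifact signature). The default
raw-score floor is 60; at the package's typical search-space size (a ~1300
residue query against a ~15 kb contig) lower floors admit abundant random
hits. E-value statistics are deliberately out of scope; all cutoffs sit in
`search_params()`.

# Motif scanning

Matrices are seeded from windows of a reference alignment located through the
ungapped reference row. Sequences with an indel inside the window (a gap at a
reference-residue column or a residue at a reference-gap column) are excluded;
so are sequences below 60% identity to the reference window, computed over the
window's reference columns. Column probabilities are `(count + pseudocount x
background) / (n + pseudocount)` with pseudocount 1 and uniform background by
default; entries are `log2(prob/background)` discretized to a 1/1000-bit
integer lattice. The null distribution of a window score -- an i.i.d.
background word -- is computed by exact convolution over the lattice, so the
position p-value of every observed score is exact; the suite checks the tails
against brute-force enumeration. A hit passes at `p < 1e-6`, strictly, with
both sides of the lattice boundary tested. The two-round procedure pools
round-1 matches with the original seeds, rebuilds the matrices, and rescans
everything; the final calls come from round-2 p-values. The packaged
reference alignment is synthetic (generated once, fixed seed): it emulates
the *structure* of a curated reference family -- conserved motif windows, a
diverged backbone, an invariant arginine at ungapped position 1101 -- not any
real sequence, and the motif coordinate table it ships with is a package
default meant to be overridden when real coordinates are available.

# Phylogenetics

Exon-level column masking removes every column of any exon flagged absent or
duplicated in at least one species -- masking granularity is whole exons.
Distances offer p, JC69, K80 (closed forms) and a pairwise GTR-ML mode
(scalar likelihood optimization); saturated pairs are flagged and capped, not
infinite. The likelihood engine is Felsenstein pruning under GTR with 4
equal-probability discrete gamma categories (category rate = bin mean) plus
an invariant class; gamma rates are rescaled by 1/(1 - p_inv) so the expected
rate stays one substitution per site per unit branch length. Gaps and
ambiguity codes are missing data. Branch lengths are optimized by per-branch
Brent search against cached partials, sweeping until the per-sweep gain drops
below 1e-6; the reported likelihood trace is forced monotone (a sweep that
fails to improve the exact likelihood is reverted and the search stops). Full
ML topology search is out of scope: trees come from NJ starting topologies,
which the concordance experiments show suffice at the alignment lengths used.
Bootstrap support resamples columns with replacement and reports, per
reference split, the percentage of replicates containing it.

# MK tests

Counting is codon-aware and unpolarized: polymorphism between each minor
allele and the majority allele, divergence between the population consensus
and the single outgroup sequence, with a nucleotide position that is both
polymorphic and divergent counted as polymorphism only. Multi-step codon
differences are averaged over all minimal mutational pathways, excluding
paths through stop codons when a stop-free path exists. Codons containing a
gap, ambiguity or stop anywhere are excluded entirely. The exact two-sided
test (summing all tables with probability at most the observed) runs on
half-to-even rounded counts; NI = (Pn x Ds)/(Ps x Dn) and alpha = 1 - NI use
the unrounded counts and are flagged undefined when Ps = 0 or Dn = 0.

The population sampler is infinite-sites with the neutral frequency spectrum
(derived-allele count i with probability proportional to 1/i) and applies the
same selective constraint as the divergence simulator: nonsynonymous
placements are kept with probability min(1, omega), synonymous with
min(1, 1/omega), rejected placements redrawn, so the segregating-site count
keeps its Watterson expectation theta x a_n while the composition reflects
omega. Without this, purifying-selection data produce a strong spurious MK
signal (NI >> 1), which is a property of real constrained genes too -- the MK
contrast is only null when polymorphism and divergence are equally
constrained.

A caveat the experiments quantify: at higher divergence, pathway averaging
and codon-context shifts slightly inflate counted nonsynonymous divergence,
pushing pooled NI a few percent below 1. The purifying-selection
non-significance property is therefore evaluated at close-sister divergence
(0.5% total), where the measured rejection rate is ~2-3%; the neutral
calibration uses 4% total divergence and theta = 15 on the 1333-codon focal
gene, where the exact test's rejection rate sits near its nominal 5%.

# Problem sizes used by the suite

The suite and the acceptance script use desk-scale sizes chosen once: 100
simulated histories of 20 taxa for event recovery; 20 ortholog replicates of
23 taxa at 4.5 kb (3.9 kb after masking one flagged exon) for concordance,
with tree height 0.3 substitutions/site and internal branches of at least
0.012; 100 synthetic proteins at 25% backbone divergence for motif recovery;
500 neutral replicates plus 3 x 200 selection replicates for MK calibration.
The oracle suites run exhaustive checks at the largest sizes where exhaustive
computation is exact and fast (PSSM widths to 4 over the full alphabet,
trees to 5 tips and 10 sites, queries to 15 residues, all 2x2 tables).

# Known limitations

* Clustering is gene-content based (order- and strand-insensitive Jaccard);
  wholesale relocation of a locus with most of its context genes is
  indistinguishable from the locus staying put, and two loci sharing most
  neighbors merge.
* Event inference assumes at most one focal structural event per branch and a
  single ancestral locus; dense event histories degrade branch placement.
* The homology module does not predict gene models (no spliced alignment,
  no splice-site scoring); HSP chaining approximates exon structure.
* The MK module's configurable low-frequency-variant cutoff is a stub with
  default off; polarized variants and asymptotic-alpha extensions are out of
  scope.
* No E-value calibration: raw-score thresholds are tuned to the package's
  fixture scale and surfaced in configuration.
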