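Package: syntrace
Title: Synteny-Based Tracing of Gene Relocation, Duplication and Retention Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the history of a gene family that has
    moved between genomic locations across a species group. Implements a
    translated (six-frame) homology search with HSP chaining and pseudogene
    calling, locus-context extraction and clustering of syntenic loci across
    species, tree-aware inference of per-branch events (block translocation,
    duplication with alternate retention, co-retention, tandem duplication),
    PSSM-based protein motif scanning with exact null p-values and a two-round
    iterative refinement, unpolarized McDonald-Kreitman tests with codon
    pathway averaging, and GTR+G+I phylogenetics (Felsenstein pruning,
    neighbor joining, branch-length optimization, bootstrap support,
    Robinson-Foulds concordance). A locus-history simulator generates species
    trees, genomes, coding evolution and population samples with a replayable
    truth log, so every inference stage can be validated end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
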