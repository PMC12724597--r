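#' @useDynLib syntrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize rbinom rexp rpois runif setNames rgamma qgamma pgamma fisher.test na.omit
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

AMINO_ACIDS <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
DNA_BASES <- c("A","C","G","T")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seeds: stages draw from independent streams derived
## from one root seed by fixed offsets, so any stage can be re-run alone.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 7919 + 12345) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## string <-> character vector helpers
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste0(x, collapse = "")

check_dna <- function(dna) {
  ch <- s2c(toupper(dna))
  bad <- setdiff(unique(ch), c(DNA_BASES, "N"))
  if (length(bad))
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  c2s(ch)
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

## Codon table (standard code); stops translate to '*'
GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

codon_aa <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- GENETIC_CODE_STD[[codon]]
  if (is.null(aa)) "X" else aa
}

translate_cds <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  c2s(vapply(codons, codon_aa, character(1)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c2s(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

## Random CDS of n_codons codons with no internal stop, ending in a sense codon
random_cds <- function(n_codons) {
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  c2s(sample(sense, n_codons, replace = TRUE))
}

is_stop <- function(codon) !is.na(GENETIC_CODE_STD[codon]) && GENETIC_CODE_STD[[codon]] == "*"

## BLOSUM62 over the 20 amino acids plus X and * (tBLASTn-style defaults).
## Values are the standard published matrix.
blosum62 <- local({
  aas <- c(AMINO_ACIDS, "X", "*")
  txt <- "
 4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0 -1 -4
-1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3 -1 -4
-2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3 -1 -4
-2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3 -1 -4
 0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1 -1 -4
-1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2 -1 -4
-1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2 -1 -4
 0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3 -1 -4
-2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3 -1 -4
-1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3 -1 -4
-1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1 -1 -4
-1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2 -1 -4
-1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1 -1 -4
-2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1 -1 -4
-1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2 -1 -4
 1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2 -1 -4
 0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0 -1 -4
-3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3 -1 -4
-2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1 -1 -4
 0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4 -1 -4
-1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -1 -4
-4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  1"
  m <- matrix(scan(text = txt, quiet = TRUE), nrow = 22, byrow = TRUE)
  dimnames(m) <- list(aas, aas)
  m
})

## Simple nucleotide match/mismatch matrix over A,C,G,T,N
nt_score_matrix <- function(match = 2, mismatch = -3) {
  ab <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

encode_seq <- function(x, alphabet) {
  idx <- match(s2c(x), alphabet)
  idx[is.na(idx)] <- match("X", alphabet, nomatch = length(alphabet))
  idx - 1L
}
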