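#' Amino-acid alphabet and codon utilities
#'
#' The package works on the 20 canonical amino acids in alphabetical
#' one-letter order, plus `"*"` for stop. `'X'` and other ambiguity codes are
#' rejected everywhere.
#'
#' @format `AA20` is a character vector of length 20; `AA21` appends `"*"`.
#' @name aa-alphabet
NULL

#' @rdname aa-alphabet
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa-alphabet
#' @export
AA21 <- c(AA20, "*")

# standard genetic code, named by codon (from Biostrings)
.genetic_code <- function() Biostrings::GENETIC_CODE

# fixed back-translation table: one codon per amino acid.  Used for the
# synthetic framework DNA and for fixed-set sites in the simulator; the
# choice of codon is irrelevant to every downstream statistic, which is
# computed at the amino-acid level.
.CODON_OF <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

.check_aa <- function(x) {
  bad <- setdiff(unique(x), AA21)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Translate DNA strings to protein
#'
#' Thin vectorised wrapper around [Biostrings::translate()] for in-frame
#' sequences whose length is a multiple of three.
#'
#' @param dna character vector of DNA sequences (A/C/G/T).
#' @return character vector of protein sequences; stops encoded as `"*"`.
#' @export
translate_dna <- function(dna) {
  if (!length(dna)) return(character(0))
  stopifnot(all(nchar(dna) %% 3 == 0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# split equal-length strings into a character matrix (rows = strings)
.char_matrix <- function(x) {
  if (!length(x)) return(matrix(character(0), 0, 0))
  n <- unique(nchar(x))
  stopifnot(length(n) == 1)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}
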