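#' The vertebrate mitochondrial genetic code
#'
#' Returns the codon-to-amino-acid map used throughout the package
#' (NCBI translation table 2): AUA translates to Met, UGA to Trp, and
#' AGA/AGG are stop codons. Codons are written in DNA alphabet (T, not U).
#'
#' @param code_id NCBI genetic-code id as a string. Defaults to "2"
#'   (vertebrate mitochondrial); any id accepted by
#'   \code{Biostrings::getGeneticCode} may be supplied, but analyses of
#'   vertebrate mitogenomes should not change it.
#' @return Named character vector of 64 one-letter amino acids ('*' = stop),
#'   names are DNA codons.
#' @examples
#' code <- mito_code()
#' code[["ATA"]]  # "M"
#' code[["TGA"]]  # "W"
#' @export
mito_code <- function(code_id = "2") {
  code <- Biostrings::getGeneticCode(code_id)
  out <- as.character(code)
  names(out) <- names(code)
  out
}

#' Translate an in-frame DNA sequence
#'
#' Translates codon by codon under the supplied genetic code. A trailing
#' partial codon (1 or 2 bases, e.g. an incomplete stop completed by
#' polyadenylation in mitochondrial transcripts) is dropped. Codons
#' containing N or '-' translate to 'X'.
#'
#' @param seq DNA string.
#' @param code codon table from [mito_code()].
#' @return Amino-acid string (one-letter, '*' for stop).
#' @export
translate_dna <- function(seq, code = mito_code()) {
  seq <- toupper(seq)
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  chars_seq(aa)
}

# translate a single codon; NA for codons with N/gap
translate_codon <- function(codon, code = mito_code()) {
  unname(code[toupper(codon)])
}

# synonymous-family index: amino acid for each codon, stops flagged
codon_families <- function(code = mito_code()) {
  split(names(code), unname(code))
}
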