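#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (N and '-' map to themselves) and reverses the
#' sequence. Input and output are plain uppercase character scalars.
#'
#' @param seq DNA string over \{A,C,G,T,N,-\}.
#' @return Reverse-complemented string.
#' @examples
#' reverse_complement("AAAT")  # "ATTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTacgt", "TGCAtgca", paste(rev(seq_chars(seq)), collapse = ""))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

# collapse a base vector back to a string
chars_seq <- function(x) paste(x, collapse = "")

# uppercase and validate a DNA string against an allowed alphabet
check_dna <- function(seq, allow = c("A", "C", "G", "T", "N"), what = "sequence") {
  seq <- toupper(seq)
  bad <- setdiff(unique(seq_chars(seq)), allow)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  seq
}

# positions are 1-based inclusive throughout the package (R convention);
# GenBank I/O is also 1-based inclusive, so no conversion happens at the
# boundary.  A feature with end < start wraps the origin of a circular
# molecule.

#' @keywords internal
"_PACKAGE"
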