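#' AT skew
#'
#' Strand-asymmetry statistic (A - T) / (A + T). Undefined (NA) when
#' A + T is zero; never coerced to 0.
#'
#' @param a_count,t_count non-negative base counts.
#' @return Skew in [-1, 1], or NA when undefined.
#' @export
at_skew <- function(a_count, t_count) {
  s <- a_count + t_count
  ifelse(s == 0, NA_real_, (a_count - t_count) / s)
}

#' GC skew
#'
#' Strand-asymmetry statistic (G - C) / (G + C). Undefined (NA) when
#' G + C is zero.
#'
#' @param g_count,c_count non-negative base counts.
#' @return Skew in [-1, 1], or NA when undefined.
#' @export
gc_skew <- function(g_count, c_count) {
  s <- g_count + c_count
  ifelse(s == 0, NA_real_, (g_count - c_count) / s)
}

#' Base composition profile of a sequence
#'
#' Counts A/C/G/T (N excluded from the denominator), percentages, AT and GC
#' content, and both strand skews. Computation is kept in full precision;
#' round only at reporting time.
#'
#' @param seq DNA string over \{A,C,G,T,N\} (gaps tolerated and ignored).
#' @param region region label carried into the profile.
#' @return A one-row data.frame: region, A, C, G, T, A_pct, C_pct, G_pct,
#'   T_pct, at_content, gc_content, at_skew, gc_skew.
#' @examples
#' base_composition("ACGT")  # 25% each, both skews 0
#' @export
base_composition <- function(seq, region = "sequence") {
  seq <- check_dna(seq, allow = c("A", "C", "G", "T", "N", "-"))
  x <- seq_chars(seq)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(x == b), integer(1L))
  tot <- sum(cnt)
  if (tot == 0L) stop("no countable bases", call. = FALSE)
  pct <- 100 * cnt / tot
  data.frame(
    region = region,
    A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
    A_pct = pct[["A"]], C_pct = pct[["C"]], G_pct = pct[["G"]], T_pct = pct[["T"]],
    at_content = pct[["A"]] + pct[["T"]],
    gc_content = pct[["G"]] + pct[["C"]],
    at_skew = at_skew(cnt[["A"]], cnt[["T"]]),
    gc_skew = gc_skew(cnt[["G"]], cnt[["C"]]),
    stringsAsFactors = FALSE)
}

#' Per-gene composition and skew table
#'
#' One row per annotated feature plus a whole-genome row. Per-gene skews are
#' computed on each feature's sense strand (light-strand genes are
#' reverse-complemented first), which is why a light-strand gene such as ND6
#' can show a positive GC skew against a genome-wide negative one. The
#' whole-genome row (and the control region, which has no sense strand) is
#' computed on the heavy strand.
#'
#' @param record a [mitogenome_record()].
#' @return data.frame with columns of [base_composition()] plus
#'   \code{strand}.
#' @export
per_gene_skew_table <- function(record) {
  rows <- base_composition(record$sequence, region = "whole-genome")
  rows$strand <- "+"
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    p <- base_composition(extract_gene(record, i), region = ft$name[i])
    p$strand <- ft$strand[i]
    rows <- rbind(rows, p)
  }
  rows
}

#' Write a composition table as TSV
#'
#' Percentages and skews are reported at 2 decimals (full precision is kept
#' in the in-memory table).
#'
#' @param tab output of [per_gene_skew_table()] or [base_composition()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_composition_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1L)) & !(names(tab) %in% c("A", "C", "G", "T"))
  tab[num] <- lapply(tab[num], round, digits = 2L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
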