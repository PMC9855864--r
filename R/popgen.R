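#' Number of segregating sites
#'
#' Columns with at least two distinct bases among the non-missing samples.
#' Gaps and N are missing; by default they are skipped per column
#' (pairwise-deletion style); with \code{complete_deletion} any column
#' containing missing data is excluded entirely.
#'
#' @param aln an [alignment_set()] with >= 2 rows.
#' @param complete_deletion drop columns with any missing data.
#' @return integer count.
#' @export
segregating_sites <- function(aln, complete_deletion = FALSE) {
  m <- aln$seqs
  if (nrow(m) < 2L) stop("need >= 2 sequences", call. = FALSE)
  miss <- m == "N" | m == "-"
  if (complete_deletion) {
    keep <- colSums(miss) == 0L
    m <- m[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  seg <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[!miss[, j], j])) >= 2L
  }, logical(1L))
  sum(seg)
}

#' Haplotype count and diversity
#'
#' Haplotypes are distinct full-length sequences; diversity uses the
#' small-sample-corrected estimator Hd = n (1 - sum p_i^2) / (n - 1).
#'
#' @param aln an [alignment_set()] with >= 2 rows.
#' @return list with \code{h} (count) and \code{Hd} (diversity in [0,1]).
#' @export
haplotype_diversity <- function(aln) {
  m <- aln$seqs
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  haps <- apply(m, 1L, paste, collapse = "")
  p <- as.numeric(table(haps)) / n
  list(h = length(p), Hd = n * (1 - sum(p^2)) / (n - 1))
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites over all C(n,2) pairs,
#' with pairwise deletion of missing sites (or complete deletion).
#'
#' @param aln an [alignment_set()] with >= 2 rows.
#' @param complete_deletion drop columns with any missing data first.
#' @return numeric in [0,1].
#' @export
nucleotide_diversity <- function(aln, complete_deletion = FALSE) {
  pw <- pairwise_diff_stats(aln, complete_deletion)
  mean(ifelse(pw$sites > 0, pw$diffs / pw$sites, 0))
}

# per-pair difference counts and comparable-site counts
pairwise_diff_stats <- function(aln, complete_deletion = FALSE) {
  m <- aln$seqs
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  miss <- m == "N" | m == "-"
  if (complete_deletion) {
    keep <- colSums(miss) == 0L
    m <- m[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  pairs <- utils::combn(n, 2L)
  diffs <- numeric(ncol(pairs)); sites <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- !miss[i, ] & !miss[j, ]
    sites[k] <- sum(ok)
    diffs[k] <- sum(m[i, ok] != m[j, ok])
  }
  list(diffs = diffs, sites = sites)
}

#' Tajima's D
#'
#' Neutrality statistic contrasting mean pairwise differences (k-bar,
#' absolute counts, not per site) with the segregating-site estimate of
#' theta, using the standard constants a1 = sum 1/i, a2 = sum 1/i^2,
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2+a2), and
#' D = (k-bar - S/a1) / sqrt(e1 S + e2 S (S-1)).
#' Undefined (NA) when S = 0 or n < 4.
#'
#' @param aln an [alignment_set()].
#' @param complete_deletion drop columns with any missing data first.
#' @return numeric, or NA when undefined.
#' @export
tajimas_d <- function(aln, complete_deletion = FALSE) {
  n <- nrow(aln$seqs)
  S <- segregating_sites(aln, complete_deletion)
  if (n < 4L || S == 0L) return(NA_real_)
  pw <- pairwise_diff_stats(aln, complete_deletion)
  kbar <- mean(pw$diffs)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Diversity statistics for one alignment
#'
#' @param aln an [alignment_set()].
#' @param region,species labels carried into the output row.
#' @param complete_deletion missing-data policy flag.
#' @return One-row data.frame: species, region, n, L, S, h, Hd, pi,
#'   tajima_d.
#' @export
diversity_stats <- function(aln, region = aln$region, species = "all",
                            complete_deletion = FALSE) {
  hd <- haplotype_diversity(aln)
  data.frame(
    species = species, region = region,
    n = nrow(aln$seqs), L = ncol(aln$seqs),
    S = segregating_sites(aln, complete_deletion),
    h = hd$h, Hd = hd$Hd,
    pi = nucleotide_diversity(aln, complete_deletion),
    tajima_d = tajimas_d(aln, complete_deletion),
    stringsAsFactors = FALSE)
}

#' Per-region, per-species diversity table
#'
#' Runs [diversity_stats()] on every alignment, for all samples pooled and
#' (where a species has >= 2 samples) within each species.
#'
#' @param alns named list of [alignment_set()] objects (names = regions).
#' @param complete_deletion missing-data policy flag.
#' @return data.frame, one row per region x (all + each species).
#' @export
diversity_table <- function(alns, complete_deletion = FALSE) {
  out <- NULL
  for (rg in names(alns)) {
    aln <- alns[[rg]]
    out <- rbind(out, diversity_stats(aln, region = rg, species = "all",
                                      complete_deletion = complete_deletion))
    for (sp in unique(aln$species)) {
      ids <- aln$ids[aln$species == sp]
      if (length(ids) < 2L) next
      sub <- alignment_set(aln$seqs[ids, , drop = FALSE],
                           aln$species[ids], region = rg)
      out <- rbind(out, diversity_stats(sub, region = rg, species = sp,
                                        complete_deletion = complete_deletion))
    }
  }
  out
}

#' Write a diversity table as TSV
#'
#' Note: Tajima's D significance is not assessed here (the beta
#' approximation of its null distribution is out of scope); only D itself
#' is reported.
#'
#' @param tab output of [diversity_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_diversity_tsv <- function(tab, path) {
  num <- c("Hd", "pi", "tajima_d")
  tab[num] <- lapply(tab[num], round, digits = 5L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
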