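#' Count codon usage over a set of coding sequences
#'
#' Each CDS is read in-frame from its \code{codon_start} offset on its sense
#' strand. A trailing partial codon (an incomplete stop completed by
#' polyadenylation) is dropped; codons containing N or '-' are skipped;
#' stop codons are tallied but excluded from the coding total.
#'
#' @param cds_list character vector (or list) of CDS sequences on their
#'   sense strands.
#' @param codon_starts integer vector of frame offsets (1, 2 or 3),
#'   recycled to the number of CDS.
#' @param code codon table from [mito_code()].
#' @return list with \code{counts} (named integer vector over all 64
#'   codons, stops included), \code{total} (coding codons, stops excluded)
#'   and \code{stop_total}.
#' @examples
#' count_codons("ATGAAATAA")  # ATG 1, AAA 1, TAA 1 (stop); total 2
#' @export
count_codons <- function(cds_list, codon_starts = 1L, code = mito_code()) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  if (length(cds_list) == 0L) stop("empty CDS list", call. = FALSE)
  codon_starts <- rep_len(as.integer(codon_starts), length(cds_list))
  counts <- stats::setNames(integer(64L), names(code))
  for (i in seq_along(cds_list)) {
    s <- toupper(cds_list[[i]])
    s <- substr(s, codon_starts[i], nchar(s))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) next
    starts <- seq.int(1L, by = 3L, length.out = n_codon)
    codons <- substring(s, starts, starts + 2L)
    codons <- codons[codons %in% names(counts)]  # drops codons with N/-
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  is_stop <- unname(code[names(counts)]) == "*"
  list(counts = counts,
       total = sum(counts[!is_stop]),
       stop_total = sum(counts[is_stop]))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c with count x_c in a synonymous family of size k is
#' k * x_c / sum of counts over the family: 1 means no bias, >1 preferred,
#' <1 avoided. Families with zero total usage get NA (undefined), not 0.
#'
#' @param codon_counts named integer vector over the 64 codons (e.g.
#'   \code{count_codons()$counts}).
#' @param code codon table from [mito_code()].
#' @param include_stops count the stop "family" too (default FALSE; the
#'   vertebrate mito code has 4 stop codons).
#' @return Named numeric vector of RSCU values (NA where undefined); stop
#'   codons are NA unless \code{include_stops}.
#' @export
rscu <- function(codon_counts, code = mito_code(), include_stops = FALSE) {
  out <- stats::setNames(rep(NA_real_, length(code)), names(code))
  fams <- codon_families(code)
  if (!include_stops) fams[["*"]] <- NULL
  for (fam in fams) {
    tot <- sum(codon_counts[fam])
    if (tot > 0L) out[fam] <- length(fam) * codon_counts[fam] / tot
  }
  out
}

#' Classify an RSCU value as biased, unbiased or rare
#'
#' Values within \code{tol} of 1 show no bias; above are biased (preferred),
#' below rare (avoided). The default tolerance 0.005 treats values that
#' would print as 1.00 at 2 decimals as unbiased.
#'
#' @param rscu_value numeric vector of RSCU values.
#' @param tol half-width of the no-bias band around 1.
#' @return character vector in \{"biased", "none", "rare"\} (NA propagated).
#' @export
classify_bias <- function(rscu_value, tol = 0.005) {
  out <- rep(NA_character_, length(rscu_value))
  ok <- !is.na(rscu_value)
  out[ok & rscu_value > 1 + tol] <- "biased"
  out[ok & abs(rscu_value - 1) <= tol] <- "none"
  out[ok & rscu_value < 1 - tol] <- "rare"
  out
}

#' Cluster codons into usage groups by mean RSCU
#'
#' Codons are ranked by their cross-species mean RSCU and clustered in one
#' dimension (Ward linkage) into \code{n_subgroups} groups, labelled in
#' descending mean order H1, H2, M1, M2, M3, L1, L2 for the default seven
#' subgroups (G1..Gk otherwise). Ties are broken by codon lexicographic
#' order, so the grouping is deterministic.
#'
#' @param per_species_rscu numeric matrix of RSCU values, rows = codons
#'   (rownames required), columns = species (at least 2). Codons with no
#'   defined RSCU in any species are dropped.
#' @param n_subgroups number of clusters (default 7).
#' @return data.frame: codon, mean_rscu, group, plus the per-group RSCU
#'   range as attribute \code{"group_ranges"}.
#' @export
cluster_rscu <- function(per_species_rscu, n_subgroups = 7L) {
  stopifnot(is.matrix(per_species_rscu), ncol(per_species_rscu) >= 2L)
  m <- rowMeans(per_species_rscu, na.rm = TRUE)
  m <- m[!is.nan(m) & !is.na(m)]
  if (length(m) < n_subgroups) {
    stop("fewer codons with defined RSCU than subgroups", call. = FALSE)
  }
  ord <- order(-m, names(m))
  m <- m[ord]
  labels7 <- c("H1", "H2", "M1", "M2", "M3", "L1", "L2")
  labs <- if (n_subgroups == 7L) labels7 else paste0("G", seq_len(n_subgroups))
  if (diff(range(m)) == 0) {
    warning("all mean RSCU values equal; clustering degenerate, one group used",
            call. = FALSE)
    out <- data.frame(codon = names(m), mean_rscu = unname(m),
                      group = labs[1L], stringsAsFactors = FALSE)
    attr(out, "group_ranges") <- data.frame(group = labs[1L],
                                            min = m[1L], max = m[1L])
    return(out)
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_subgroups)
  # label clusters in descending order of their mean value
  cl_means <- tapply(m, cl, mean)
  rank_of <- stats::setNames(rank(-cl_means, ties.method = "first"),
                             names(cl_means))
  grp <- labs[rank_of[as.character(cl)]]
  out <- data.frame(codon = names(m), mean_rscu = unname(m), group = grp,
                    stringsAsFactors = FALSE)
  rng <- do.call(rbind, lapply(labs[sort(unique(rank_of[as.character(cl)]))],
    function(g) data.frame(group = g,
                           min = min(out$mean_rscu[out$group == g]),
                           max = max(out$mean_rscu[out$group == g]))))
  attr(out, "group_ranges") <- rng
  out
}

#' Full codon-usage report for a set of species
#'
#' Counts codons over each species' protein-coding genes, computes per-
#' species and mean RSCU, bias class and usage subgroup.
#'
#' @param cds_by_species named list (one element per species) of character
#'   vectors of sense-strand CDS sequences.
#' @param codon_starts_by_species optional list of frame offsets parallel
#'   to \code{cds_by_species} (default all 1).
#' @param code codon table.
#' @param include_stops include the stop-codon family (default FALSE).
#' @return data.frame: codon, aa, count (summed over species), freq_pct,
#'   one RSCU column per species, mean_rscu, bias, group.
#' @export
codon_usage_report <- function(cds_by_species, codon_starts_by_species = NULL,
                               code = mito_code(), include_stops = FALSE) {
  species <- names(cds_by_species)
  stopifnot(length(species) >= 1L)
  counts <- lapply(species, function(sp) {
    cs <- if (is.null(codon_starts_by_species)) 1L else codon_starts_by_species[[sp]]
    count_codons(cds_by_species[[sp]], codon_starts = cs, code = code)$counts
  })
  names(counts) <- species
  rs <- vapply(counts, rscu, numeric(64L), code = code,
               include_stops = include_stops)
  rownames(rs) <- names(code)
  total_counts <- Reduce(`+`, counts)
  out <- data.frame(codon = names(code), aa = unname(code),
                    count = unname(total_counts),
                    freq_pct = 100 * unname(total_counts) / sum(total_counts),
                    stringsAsFactors = FALSE)
  for (sp in species) out[[paste0("rscu_", sp)]] <- unname(rs[, sp])
  out$mean_rscu <- rowMeans(rs, na.rm = TRUE)
  out$mean_rscu[is.nan(out$mean_rscu)] <- NA_real_
  out$bias <- classify_bias(out$mean_rscu)
  out$group <- NA_character_
  if (length(species) >= 2L) {
    cl <- tryCatch(cluster_rscu(rs), error = function(e) NULL)
    if (!is.null(cl)) out$group[match(cl$codon, out$codon)] <- cl$group
  }
  out
}

#' Write a codon-usage report as TSV (2-decimal rounding)
#' @param report output of [codon_usage_report()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_codon_usage_tsv <- function(report, path) {
  num <- vapply(report, is.numeric, logical(1L)) & names(report) != "count"
  report[num] <- lapply(report[num], round, digits = 2L)
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
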