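#' Call SNP and indel columns in an alignment
#'
#' Deterministic column classification: every polymorphic column emits a
#' call. N is treated as missing for the samples carrying it. A column with
#' both gaps and base variation emits one indel call and one SNP call
#' restricted to the non-gap samples.
#'
#' @param aln an [alignment_set()] with at least 2 rows.
#' @return list of class \code{variant_calls}; each element has
#'   \code{column} (1-based), \code{kind} ("SNP"/"indel") and
#'   \code{alleles} (named per-sample base/gap, NA where missing; SNP calls
#'   in mixed columns carry NA for the gapped samples).
#' @export
call_variants <- function(aln) {
  m <- aln$seqs
  if (nrow(m) < 2L) stop("alignment must have >= 2 rows", call. = FALSE)
  calls <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col[col == "N"] <- NA_character_
    obs <- col[!is.na(col)]
    if (length(obs) < 2L) next
    has_gap <- any(obs == "-")
    bases <- obs[obs != "-"]
    if (has_gap && length(bases) >= 1L) {
      calls[[length(calls) + 1L]] <-
        list(column = j, kind = "indel", alleles = col)
      if (length(unique(bases)) >= 2L) {
        snp_col <- col
        snp_col[!is.na(snp_col) & snp_col == "-"] <- NA_character_
        calls[[length(calls) + 1L]] <-
          list(column = j, kind = "SNP", alleles = snp_col)
      }
    } else if (!has_gap && length(unique(bases)) >= 2L) {
      calls[[length(calls) + 1L]] <-
        list(column = j, kind = "SNP", alleles = col)
    }
  }
  structure(calls, class = "variant_calls")
}

#' Classify a variant call as intra- or inter-specific
#'
#' Operational definitions (total and disjoint over all polymorphic
#' columns):
#' \itemize{
#'   \item \strong{intra}: exactly one species segregates and every other
#'     species is fixed for one common allele.
#'   \item \strong{inter, type i}: at least one species segregates and at
#'     least one species is fixed (and the column is not intra).
#'   \item \strong{inter, type ii}: every species segregates.
#'   \item \strong{inter, type iii}: no species segregates; species are
#'     fixed for at least two distinct alleles.
#' }
#' Species with only missing data at the column are ignored; multi-allelic
#' columns follow the same rules on the full allele partition.
#'
#' @param call one element of [call_variants()] output (or any list with
#'   an \code{alleles} field).
#' @param species_of named character vector sample id -> species.
#' @return list with \code{scope} ("intra"/"inter") and \code{inter_type}
#'   ("i", "ii", "iii", or "none" for intra columns).
#' @export
classify_scope <- function(call, species_of) {
  al <- call$alleles
  sp <- species_of[names(al)]
  keep <- !is.na(al)
  al <- al[keep]; sp <- sp[keep]
  by_sp <- split(al, sp)
  n_alleles <- vapply(by_sp, function(a) length(unique(a)), integer(1L))
  fixed_allele <- vapply(by_sp, function(a) unique(a)[1L], character(1L))
  poly <- names(by_sp)[n_alleles > 1L]
  fixed <- names(by_sp)[n_alleles == 1L]
  if (length(unique(al)) < 2L) {
    return(list(scope = NA_character_, inter_type = "none"))
  }
  if (length(poly) == 1L &&
      length(unique(fixed_allele[fixed])) <= 1L) {
    return(list(scope = "intra", inter_type = "none", species = poly))
  }
  type <- if (length(poly) == 0L) "iii"
          else if (length(fixed) == 0L) "ii"
          else "i"
  list(scope = "inter", inter_type = type, species = NA_character_)
}

#' Tabulate variant calls with scope classification
#'
#' @param calls output of [call_variants()].
#' @param species_of named character vector sample id -> species.
#' @param regions optional character vector giving a region label per
#'   alignment column (e.g. from [column_regions()]).
#' @return data.frame: column, kind, scope, inter_type, species (the
#'   segregating species for intra calls), region.
#' @export
classify_variants <- function(calls, species_of, regions = NULL) {
  if (length(calls) == 0L) {
    return(data.frame(column = integer(), kind = character(),
                      scope = character(), inter_type = character(),
                      species = character(), region = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(calls, function(cl) {
    sc <- classify_scope(cl, species_of)
    data.frame(column = cl$column, kind = cl$kind,
               scope = sc$scope, inter_type = sc$inter_type,
               species = if (!is.null(sc$species)) sc$species else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$region <- if (is.null(regions)) NA_character_ else regions[out$column]
  out
}

#' Summarise variant calls
#'
#' Totals, SNP/indel and intra/inter splits with percentages, per-species
#' intra counts, inter counts by type, pairwise fixed-difference counts
#' (columns where two species are each fixed for different alleles), and a
#' per-region histogram when region labels are present.
#'
#' @param calls output of [call_variants()].
#' @param species_of named character vector sample id -> species.
#' @param regions optional per-column region labels.
#' @return list: totals, intra_by_species, inter_by_type, pairwise_fixed,
#'   by_region, table (the [classify_variants()] data.frame).
#' @export
variant_summary <- function(calls, species_of, regions = NULL) {
  tab <- classify_variants(calls, species_of, regions)
  species <- sort(unique(species_of))
  snp <- tab[tab$kind == "SNP" & !is.na(tab$scope), , drop = FALSE]
  intra_by_species <- stats::setNames(
    vapply(species, function(s) sum(snp$scope == "intra" & snp$species == s,
                                    na.rm = TRUE), numeric(1L)), species)
  inter_by_type <- stats::setNames(
    vapply(c("i", "ii", "iii"), function(t) sum(snp$inter_type == t), numeric(1L)),
    c("i", "ii", "iii"))
  n_snp <- nrow(snp)
  totals <- list(
    calls = nrow(tab), snps = n_snp,
    indels = sum(tab$kind == "indel"),
    intra = sum(snp$scope == "intra"),
    inter = sum(snp$scope == "inter"),
    intra_pct = if (n_snp) 100 * sum(snp$scope == "intra") / n_snp else 0,
    inter_pct = if (n_snp) 100 * sum(snp$scope == "inter") / n_snp else 0)
  # pairwise fixed differences among SNP columns
  pairs <- utils::combn(species, 2L, simplify = FALSE)
  pw <- stats::setNames(numeric(length(pairs)),
                        vapply(pairs, paste, character(1L), collapse = "|"))
  for (cl in calls) {
    if (cl$kind != "SNP") next
    al <- cl$alleles[!is.na(cl$alleles)]
    by_sp <- split(al, species_of[names(al)])
    fx <- vapply(by_sp, function(a) {
      u <- unique(a); if (length(u) == 1L) u else NA_character_
    }, character(1L))
    for (k in seq_along(pairs)) {
      a <- fx[pairs[[k]][1L]]; b <- fx[pairs[[k]][2L]]
      if (!is.na(a) && !is.na(b) && a != b) pw[k] <- pw[k] + 1
    }
  }
  by_region <- if (!is.null(regions)) {
    as.data.frame(table(region = snp$region), stringsAsFactors = FALSE)
  } else NULL
  list(totals = totals, intra_by_species = intra_by_species,
       inter_by_type = inter_by_type, pairwise_fixed = pw,
       by_region = by_region, table = tab)
}

#' Region label per alignment column from a reference annotation
#'
#' Maps each alignment column to the feature of the reference record at the
#' corresponding ungapped reference position ("IGS" where unannotated, NA
#' at reference gap columns).
#'
#' @param aln an [alignment_set()] containing the reference row.
#' @param record the reference [mitogenome_record()].
#' @param reference_id row id of the reference in \code{aln}.
#' @return character vector, one label per column.
#' @export
column_regions <- function(aln, record, reference_id) {
  if (!reference_id %in% aln$ids) stop("reference row not in alignment", call. = FALSE)
  row <- aln$seqs[reference_id, ]
  region_of <- rep("IGS", record$length)
  ft <- record$features
  for (i in rev(seq_len(nrow(ft)))) {  # earlier features take precedence
    region_of[feature_positions(ft$start[i], ft$end[i], record$length)] <- ft$name[i]
  }
  out <- rep(NA_character_, length(row))
  pos <- cumsum(row != "-")
  nongap <- row != "-"
  out[nongap] <- region_of[pos[nongap]]
  out
}

#' Write variant calls as a minimal VCF
#'
#' CHROM is the alignment's region label, POS the 1-based ungapped
#' reference coordinate, REF the reference row's allele and ALT the other
#' observed alleles. SNP calls where the reference row is gapped or missing
#' are skipped.
#'
#' @param calls output of [call_variants()].
#' @param aln the [alignment_set()] the calls came from.
#' @param reference_id reference row id.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(calls, aln, reference_id, path) {
  row <- aln$seqs[reference_id, ]
  pos <- cumsum(row != "-")
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##reference=%s", reference_id),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (cl in calls) {
    if (cl$kind != "SNP") next
    ref <- row[cl$column]
    if (is.na(ref) || ref == "-" || ref == "N") next
    alt <- setdiff(unique(stats::na.omit(cl$alleles)), ref)
    if (length(alt) == 0L) next
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                              aln$region, pos[cl$column], ref,
                              paste(alt, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
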