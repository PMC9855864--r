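#' Classify a single-base substitution as synonymous or nonsynonymous
#'
#' Substitutes \code{alt_base} at \code{offset} into the reference codon
#' and compares the two translations under the (mitochondrial) code.
#'
#' @param ref_codon reference codon (3 bases).
#' @param offset position within the codon, 1, 2 or 3.
#' @param alt_base replacement base, different from the reference base at
#'   \code{offset}.
#' @param code codon table from [mito_code()].
#' @return "synonymous" or "nonsynonymous"; NA with a warning when either
#'   codon contains N or a gap.
#' @examples
#' classify_site_substitution("CTT", 3, "C")  # synonymous (Leu -> Leu)
#' @export
classify_site_substitution <- function(ref_codon, offset, alt_base,
                                       code = mito_code()) {
  stopifnot(offset %in% 1:3)
  ref_codon <- toupper(ref_codon)
  alt_base <- toupper(alt_base)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_base
  aa_ref <- translate_codon(ref_codon, code)
  aa_alt <- translate_codon(alt_codon, code)
  if (is.na(aa_ref) || is.na(aa_alt)) {
    warning("codon containing N or gap skipped", call. = FALSE)
    return(NA_character_)
  }
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Apply the dN/dS ratio convention to substitution counts
#'
#' omega = nonsyn/syn when syn > 0; 0 whenever nonsyn = 0 (including the
#' 0/0 case); undefined (NA) when syn = 0 with nonsyn > 0.
#'
#' @param syn,nonsyn non-negative substitution counts (vectorised).
#' @return numeric vector of omega values.
#' @export
omega_from_counts <- function(syn, nonsyn) {
  ifelse(nonsyn == 0, 0, ifelse(syn > 0, nonsyn / syn, NA_real_))
}

#' Count synonymous/nonsynonymous substitutions against a reference
#'
#' For an in-frame, codon-aware alignment of one gene, every position where
#' the query differs from the reference is classified independently against
#' the full reference codon (substitute the query base into the reference
#' codon and compare translations). Counts are summed over the gene and
#' omega derived with [omega_from_counts()]. Codons containing N or gaps in
#' either row are skipped; a trailing partial codon (incomplete stop) is
#' trimmed.
#'
#' @param cds_aln an [alignment_set()] of the gene (in frame).
#' @param reference_id,query_id row ids to compare.
#' @param code codon table.
#' @param gene gene label carried into the output.
#' @return One-row data.frame: gene, species (query's species), syn_count,
#'   nonsyn_count, omega, reference_id.
#' @export
count_gene_substitutions <- function(cds_aln, reference_id, query_id,
                                     code = mito_code(), gene = cds_aln$region) {
  m <- cds_aln$seqs
  if (!all(c(reference_id, query_id) %in% rownames(m))) {
    stop("reference or query row missing from alignment", call. = FALSE)
  }
  L <- ncol(m)
  Luse <- L - (L %% 3L)  # trim incomplete terminal codon
  if (Luse < 3L) stop("frame violation: alignment shorter than one codon", call. = FALSE)
  ref <- m[reference_id, seq_len(Luse)]
  qry <- m[query_id, seq_len(Luse)]
  syn <- 0L; nonsyn <- 0L
  for (cs in seq.int(1L, Luse, by = 3L)) {
    idx <- cs:(cs + 2L)
    rc <- ref[idx]; qc <- qry[idx]
    if (any(rc %in% c("N", "-")) || any(qc %in% c("N", "-"))) next
    dif <- which(rc != qc)
    for (o in dif) {
      cls <- classify_site_substitution(chars_seq(rc), o, qc[o], code)
      if (is.na(cls)) next
      if (cls == "synonymous") syn <- syn + 1L else nonsyn <- nonsyn + 1L
    }
  }
  data.frame(gene = gene,
             species = unname(cds_aln$species[query_id]),
             syn_count = syn, nonsyn_count = nonsyn,
             omega = omega_from_counts(syn, nonsyn),
             reference_id = reference_id, stringsAsFactors = FALSE)
}

#' Cross-species averages of per-gene substitution counts
#'
#' Arithmetic mean of synonymous count, nonsynonymous count and omega per
#' gene across species.
#'
#' @param per_species_counts data.frame with columns gene, species,
#'   syn_count, nonsyn_count, omega (rows = gene x species).
#' @return data.frame: gene, mean_syn, mean_nonsyn, mean_omega.
#' @export
substitution_rate_summary <- function(per_species_counts) {
  x <- per_species_counts
  genes <- unique(x$gene)
  data.frame(
    gene = genes,
    mean_syn = vapply(genes, function(g) mean(x$syn_count[x$gene == g]), numeric(1L)),
    mean_nonsyn = vapply(genes, function(g) mean(x$nonsyn_count[x$gene == g]), numeric(1L)),
    mean_omega = vapply(genes, function(g) mean(x$omega[x$gene == g]), numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Translate every row of a codon-aware CDS alignment
#'
#' @param cds_aln an [alignment_set()] (in frame; trailing partial codon
#'   trimmed).
#' @param code codon table.
#' @return character matrix of amino acids (rows = samples); codons with
#'   N/gap give 'X'.
#' @export
translate_alignment <- function(cds_aln, code = mito_code()) {
  m <- cds_aln$seqs
  Luse <- ncol(m) - (ncol(m) %% 3L)
  t(vapply(rownames(m), function(id) {
    seq_chars(translate_dna(chars_seq(m[id, seq_len(Luse)]), code))
  }, character(Luse %/% 3L)))
}

#' Amino-acid change spectrum relative to an outgroup
#'
#' At each residue column where ingroup samples differ from the outgroup,
#' changes are tallied per species relative to the outgroup residue.
#' Columns where every ingroup sample carries the same non-outgroup residue
#' (a 100%-frequency variant, informative only about the reference) are
#' excluded. Direction is anchored on the outgroup residue via the ingroup
#' majority: samples carrying the majority derived residue count as forward
#' changes (outgroup -> derived) and samples retaining the outgroup residue
#' at such columns count as reverse changes (derived -> outgroup).
#'
#' @param protein_alns named list of amino-acid matrices (one per gene,
#'   rows = samples including the outgroup; see [translate_alignment()]).
#' @param outgroup_id row id of the outgroup.
#' @param species_of named character vector sample id -> species.
#' @return list with \code{changes} (data.frame: gene, position, from, to,
#'   direction, species, count) and \code{pair_imbalance} (data.frame:
#'   pair, forward, reverse, imbalance).
#' @export
amino_acid_change_spectrum <- function(protein_alns, outgroup_id, species_of) {
  changes <- NULL
  for (gene in names(protein_alns)) {
    m <- protein_alns[[gene]]
    if (!outgroup_id %in% rownames(m)) {
      stop(sprintf("outgroup row '%s' missing from %s", outgroup_id, gene),
           call. = FALSE)
    }
    ing <- setdiff(rownames(m), outgroup_id)
    for (j in seq_len(ncol(m))) {
      o <- m[outgroup_id, j]
      if (o %in% c("X", "-", "*")) next
      r <- m[ing, j]
      ok <- !(r %in% c("X", "-"))
      r <- r[ok]; ids <- ing[ok]
      if (length(r) == 0L || all(r == o)) next
      if (length(unique(r)) == 1L && r[1L] != o) next  # 100% frequency: excluded
      tab <- table(r)
      maj <- names(tab)[order(-as.integer(tab), names(tab))][1L]  # ties: alphabetical
      for (k in seq_along(r)) {
        sp <- unname(species_of[ids[k]])
        if (maj != o) {
          if (r[k] == o) {
            changes <- rbind(changes, data.frame(
              gene = gene, position = j, from = maj, to = o,
              direction = "reverse", species = sp, stringsAsFactors = FALSE))
          } else {
            changes <- rbind(changes, data.frame(
              gene = gene, position = j, from = o, to = r[k],
              direction = "forward", species = sp, stringsAsFactors = FALSE))
          }
        } else if (r[k] != o) {
          changes <- rbind(changes, data.frame(
            gene = gene, position = j, from = o, to = r[k],
            direction = "forward", species = sp, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(changes)) {
    return(list(changes = NULL, pair_imbalance = NULL))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(changes))),
                          changes[c("gene", "position", "from", "to",
                                    "direction", "species")], sum)
  pair <- apply(agg[c("from", "to")], 1L, function(p) paste(sort(p), collapse = "<->"))
  fwd <- tapply(agg$count * (agg$direction == "forward"), pair, sum)
  rev_ <- tapply(agg$count * (agg$direction == "reverse"), pair, sum)
  imb <- data.frame(pair = names(fwd),
                    forward = as.numeric(fwd),
                    reverse = as.numeric(rev_),
                    stringsAsFactors = FALSE, row.names = NULL)
  imb$imbalance <- abs(imb$forward - imb$reverse)
  list(changes = agg, pair_imbalance = imb)
}

#' Write a substitution-count table as TSV
#' @param counts data.frame from [count_gene_substitutions()] rows.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_substitutions_tsv <- function(counts, path) {
  counts$omega <- round(counts$omega, 2L)
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
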