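#' Compare pipeline output against simulation ground truth
#'
#' Runs the package's own analyses on a simulated sample set and scores
#' them against the generator's truth table: SNP scope/type confusion
#' matrix and accuracy (on the planted columns, classified over the
#' ingroup samples), planted repeat-locus recall and precision (detector
#' run per sample, restricted to the repeat-bearing compartments: control
#' region, pseudogene and intergenic spacers), per-gene dN/dS rank
#' correlation (Spearman, estimated nonsyn/syn ratio vs the generator's
#' omega), and bipartition recall of the neighbor-joining tree (species
#' clades plus the true species-tree splits).
#'
#' @param sim a \code{mito_sim} from [simulate_mitogenomes()].
#' @param ref_species species whose first sample anchors the substitution
#'   counting (default the sister species analogous to the reference
#'   genome).
#' @return list: \code{snp} (confusion, accuracy, recall), \code{repeats}
#'   (recall, precision, n_truth, n_detected), \code{omega} (rho, table),
#'   \code{tree} (recall, tree).
#' @export
recovery_report <- function(sim, ref_species = "Sarotherodon_galilaeus") {
  truth <- sim$truth
  ingroup <- truth$ingroup
  species_of <- sim$species_of

  ## SNP scope/type recovery
  g_aln <- alignment_set(sim$genome_aln$seqs[ingroup, , drop = FALSE],
                         species_of[ingroup], region = "whole-genome")
  calls <- call_variants(g_aln)
  tab <- classify_variants(calls, species_of)
  snp_tab <- tab[tab$kind == "SNP", , drop = FALSE]
  key <- function(scope, type) paste(scope, type, sep = "/")
  pred <- stats::setNames(key(snp_tab$scope, snp_tab$inter_type), snp_tab$column)
  truth_key <- key(truth$snps$scope, truth$snps$inter_type)
  got <- pred[as.character(truth$snps$column)]
  found <- !is.na(got)
  confusion <- table(truth = truth_key, predicted = ifelse(found, got, "missed"))
  list_snp <- list(confusion = confusion,
                   accuracy = mean(found & got == truth_key),
                   recall = mean(found))

  ## planted repeat recovery
  n_match <- 0L; n_truth <- 0L; n_det <- 0L
  for (sid in ingroup) {
    rec <- sim$records[[sid]]
    hits <- locate_repeats(find_tandem_repeats(rec$sequence), rec)
    keep <- hits$location_kind %in% c("control_region", "pseudogene", "IGS")
    hits <- hits[keep, , drop = FALSE]
    tr <- truth$repeats[truth$repeats$sample_id == sid, , drop = FALSE]
    n_truth <- n_truth + nrow(tr)
    n_det <- n_det + nrow(hits)
    for (i in seq_len(nrow(tr))) {
      m <- hits$unit == tr$unit[i] & hits$copies == tr$copies[i]
      if (any(m)) {
        n_match <- n_match + 1L
        hits <- hits[-which(m)[1L], , drop = FALSE]
      }
    }
  }
  list_rep <- list(recall = if (n_truth) n_match / n_truth else NA_real_,
                   precision = if (n_det) n_match / n_det else NA_real_,
                   n_truth = n_truth, n_detected = n_det)

  ## dN/dS rank recovery
  ref_id <- ingroup[species_of[ingroup] == ref_species][1L]
  qry_sp <- setdiff(unique(species_of[ingroup]), ref_species)
  qry_ids <- vapply(qry_sp, function(sp) {
    ingroup[species_of[ingroup] == sp][1L]
  }, character(1L))
  genes <- names(truth$omega)
  est <- vapply(genes, function(g) {
    aln <- sim$gene_alns[[g]]
    syn <- 0L; nonsyn <- 0L
    for (q in qry_ids) {
      cnt <- count_gene_substitutions(aln, ref_id, q)
      syn <- syn + cnt$syn_count
      nonsyn <- nonsyn + cnt$nonsyn_count
    }
    if (syn > 0L) nonsyn / syn else NA_real_
  }, numeric(1L))
  ok <- !is.na(est)
  rho <- if (sum(ok) >= 3L) {
    stats::cor(est[ok], truth$omega[genes][ok], method = "spearman")
  } else NA_real_
  list_omega <- list(rho = rho,
                     table = data.frame(gene = genes, true_omega = truth$omega[genes],
                                        est_ratio = est, row.names = NULL))

  ## tree bipartition recovery
  est_tree <- neighbor_joining(distance_matrix(sim$genome_aln, "JC69"))
  splits <- species_splits(truth$tree, species_of)
  hit <- vapply(splits, function(tips) has_split(est_tree, tips), logical(1L))
  list_tree <- list(recall = mean(hit), tree = est_tree)

  list(snp = list_snp, repeats = list_rep, omega = list_omega, tree = list_tree)
}

# species-level clades and true-tree internal splits, expanded to sample ids
species_splits <- function(tree, species_of) {
  splits <- list()
  for (sp in unique(species_of)) {
    ids <- names(species_of)[species_of == sp]
    if (length(ids) >= 2L && length(ids) < length(species_of) - 1L) {
      splits[[sp]] <- ids
    }
  }
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    ids <- names(species_of)[species_of %in% side]
    splits[[paste(side, collapse = "+")]] <- ids
  }
  splits
}

#' Rank-recovery experiment for the dN/dS counting chain
#'
#' Simulates one coding gene per omega value (ancestral CDS evolved along a
#' single branch under acceptance-rejection selection), counts synonymous
#' and nonsynonymous substitutions back with [count_gene_substitutions()],
#' and reports the Spearman correlation between the estimated nonsyn/syn
#' ratios and the generating omegas.
#'
#' @param omegas generating dN/dS values, one gene each.
#' @param n_codons coding codons per gene.
#' @param branch branch length (substitutions/site).
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return list: \code{rho} (Spearman), \code{table} (gene, true omega,
#'   syn, nonsyn, estimated ratio).
#' @export
omega_rank_experiment <- function(omegas = c(0.02, 0.05, 0.1, 0.15, 0.25,
                                             0.35, 0.5, 0.7, 0.9, 1.2),
                                  n_codons = 2000L, branch = 0.2,
                                  kappa = 4, seed = 1L) {
  set.seed(seed)
  freq <- default_base_comp()
  tab <- NULL
  for (k in seq_along(omegas)) {
    anc <- random_cds(n_codons, freq)
    anc_v <- seq_chars(anc)
    ev <- evolve_cds(anc_v, branch, rate = 1, omega = omegas[k],
                     freq = freq, kappa = kappa)
    aln <- alignment_set(c(ref = anc, qry = chars_seq(ev$seq)),
                         c(ref = "ref_sp", qry = "qry_sp"),
                         region = sprintf("gene%02d", k))
    cnt <- count_gene_substitutions(aln, "ref", "qry")
    tab <- rbind(tab, data.frame(
      gene = sprintf("gene%02d", k), true_omega = omegas[k],
      syn = cnt$syn_count, nonsyn = cnt$nonsyn_count,
      est_ratio = ifelse(cnt$syn_count > 0,
                         cnt$nonsyn_count / cnt$syn_count, NA_real_),
      stringsAsFactors = FALSE))
  }
  ok <- !is.na(tab$est_ratio)
  list(rho = stats::cor(tab$est_ratio[ok], tab$true_omega[ok],
                        method = "spearman"),
       table = tab)
}
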