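## Synthetic annotated mitogenomes with ground truth.
##
## The generator emulates the data model the comparative analyses assume:
## a ~16.5 kb circular vertebrate mitogenome (13 PCGs, 22 tRNAs, 2 rRNAs,
## control region, standard gene order, ND6 + 8 tRNAs on the light strand),
## AT-rich composition, per-gene rate multipliers and dN/dS, and D-loop /
## spacer / pseudogene tandem-repeat arrays with copy-number polymorphism.
## Everything is reproducible from one seed.

#' Default target base composition (heavy strand)
#' @return named numeric vector A/C/G/T summing to 1.
#' @export
default_base_comp <- function() {
  x <- c(A = 0.2776, C = 0.3082, G = 0.1578, T = 0.2566)
  x / sum(x)  # printed 2-decimal percentages sum to 100.02; renormalise
}

#' Default per-gene relative rate multipliers
#' @return named numeric vector over template features (tRNAs share "tRNA",
#'   rRNAs "rRNA", spacers "IGS").
#' @export
default_gene_rates <- function() {
  c(ND1 = 1.0, ND2 = 1.3, COX1 = 0.6, COX2 = 0.7, ATP8 = 1.3, ATP6 = 0.9,
    COX3 = 0.4, ND3 = 1.1, ND4L = 0.9, ND4 = 1.3, ND5 = 1.4, ND6 = 1.6,
    CYTB = 0.9, tRNA = 0.15, rRNA = 0.4, `D-loop` = 1.8, IGS = 1.2,
    pseudogene = 1.0)
}

#' Default per-gene dN/dS used by the simulator
#' @return named numeric vector over the 13 protein-coding genes.
#' @export
default_omega <- function() {
  c(ND1 = 0.10, ND2 = 0.15, COX1 = 0.04, COX2 = 0.05, ATP8 = 0.30,
    ATP6 = 0.08, COX3 = 0.02, ND3 = 0.25, ND4L = 0.06, ND4 = 0.12,
    ND5 = 0.18, ND6 = 0.45, CYTB = 0.12)
}

#' Default planted tandem-repeat specification
#'
#' D-loop arrays (TA with copy-number polymorphism, TTA, and an
#' AATAC/AATGC unit polymorphism), a CCCG array in the trnN-trnC spacer and
#' a CAA array in the trnS2 pseudogene.
#'
#' @return list of per-locus specs (region, unit, copy range, optional
#'   species-specific alternative unit).
#' @export
default_repeat_spec <- function() {
  list(
    list(region = "D-loop", unit = "TA", copies = c(4L, 6L)),
    list(region = "D-loop", unit = "TTA", copies = c(4L, 5L)),
    list(region = "D-loop", unit = "AATAC", copies = c(5L, 5L),
         alt_unit = "AATGC", alt_species = "Oreochromis_niloticus"),
    list(region = "trnN-trnC", unit = "CCCG", copies = c(4L, 6L)),
    list(region = "trnS2", unit = "CAA", copies = c(3L, 5L)))
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; every random draw in [simulate_mitogenomes()]
#'   descends from it.
#' @param tree newick string with branch lengths in substitutions/site;
#'   leaf names are species names. The default places the two sister
#'   tilapiine analogues at 0.03, their common stem at 0.015, the third
#'   ingroup species at 0.045 and a distant outgroup at 0.30.
#' @param n_samples named integer vector, samples per species.
#' @param base_comp target A/C/G/T fractions (must sum to 1).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param gene_rates named relative rate multipliers (see
#'   [default_gene_rates()]).
#' @param omega named per-gene dN/dS in (0, 1.5].
#' @param repeat_spec planted repeat arrays (see [default_repeat_spec()]).
#' @param intra_branch within-species tip branch length (subs/site).
#' @param scale genome-size scale factor (1 = full ~16.5 kb; 0.1 gives a
#'   fast miniature genome with the same structure).
#' @param snp_plant list: intra_per_species, type_i, type_ii, type_iii —
#'   numbers of SNP columns planted with known scope/type in the rRNAs.
#' @param outgroup species name of the outgroup leaf.
#' @return validated list of class \code{sim_config}.
#' @export
simulation_config <- function(
    seed = 1L,
    tree = paste0("((Oreochromis_niloticus:0.03,Sarotherodon_galilaeus:0.03):",
                  "0.015,Coptodon_zillii:0.045,Oncorhynchus_keta:0.30);"),
    n_samples = c(Coptodon_zillii = 3L, Oreochromis_niloticus = 3L,
                  Sarotherodon_galilaeus = 3L, Oncorhynchus_keta = 1L),
    base_comp = default_base_comp(),
    kappa = 4,
    gene_rates = default_gene_rates(),
    omega = default_omega(),
    repeat_spec = default_repeat_spec(),
    intra_branch = 0.004,
    scale = 1,
    snp_plant = list(intra_per_species = 5L, type_i = 5L, type_ii = 3L,
                     type_iii = 10L),
    outgroup = "Oncorhynchus_keta") {
  stopifnot(abs(sum(base_comp) - 1) < 1e-8, kappa > 0, all(omega > 0),
            all(omega <= 1.5), all(gene_rates > 0), scale > 0)
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) stop("invalid newick tree", call. = FALSE)
  if (!setequal(phy$tip.label, names(n_samples))) {
    stop("tree leaf names must match names(n_samples)", call. = FALSE)
  }
  if (!outgroup %in% phy$tip.label) stop("outgroup not in tree", call. = FALSE)
  structure(list(seed = as.integer(seed), tree = tree, phy = phy,
                 n_samples = n_samples, base_comp = base_comp, kappa = kappa,
                 gene_rates = gene_rates, omega = omega,
                 repeat_spec = repeat_spec, intra_branch = intra_branch,
                 scale = scale, snp_plant = snp_plant, outgroup = outgroup),
            class = "sim_config")
}

# template: standard vertebrate mitochondrial gene order; CDS sizes carry a
# coding codon count and a stop tail ("TAA"/"TAG" complete, "T"/"TA"
# incomplete).  Lengths loosely follow tilapiine annotations.
genome_template <- function(scale = 1) {
  f <- function(name, kind, strand, len = NA, codons = NA, tail = "") {
    data.frame(name = name, kind = kind, strand = strand, len = len,
               codons = codons, tail = tail, stringsAsFactors = FALSE)
  }
  t_len <- function(len) max(24L, round(len * scale))
  cds <- function(name, codons, tail = "TAA", strand = "+") {
    f(name, "CDS", strand, NA, max(12L, round(codons * scale)), tail)
  }
  tpl <- rbind(
    f("trnF", "tRNA", "+", t_len(68)),
    f("rrnS", "rRNA", "+", t_len(950)),
    f("trnV", "tRNA", "+", t_len(72)),
    f("rrnL", "rRNA", "+", t_len(1690)),
    f("trnL1", "tRNA", "+", t_len(74)),
    cds("ND1", 324),
    f("trnI", "tRNA", "+", t_len(70)),
    f("trnQ", "tRNA", "-", t_len(71)),
    f("trnM", "tRNA", "+", t_len(69)),
    cds("ND2", 348),
    f("trnW", "tRNA", "+", t_len(71)),
    f("trnA", "tRNA", "-", t_len(69)),
    f("trnN", "tRNA", "-", t_len(72)),
    f("OL", "IGS", "+", t_len(36)),
    f("trnC", "tRNA", "-", t_len(66)),
    f("trnY", "tRNA", "-", t_len(70)),
    cds("COX1", 516),
    f("trnS1", "tRNA", "-", t_len(71)),
    f("trnD", "tRNA", "+", t_len(68)),
    cds("COX2", 229, tail = "T"),
    f("trnK", "tRNA", "+", t_len(74)),
    cds("ATP8", 55),
    cds("ATP6", 227),
    cds("COX3", 261, tail = "T"),
    f("trnG", "tRNA", "+", t_len(68)),
    cds("ND3", 116, tail = "T"),
    f("trnR", "tRNA", "+", t_len(69)),
    cds("ND4L", 98),
    cds("ND4", 459, tail = "T"),
    f("trnH", "tRNA", "+", t_len(69)),
    f("trnS2", "pseudogene", "+", t_len(68)),
    f("trnL2", "tRNA", "+", t_len(73)),
    cds("ND5", 611),
    cds("ND6", 173, tail = "TAG", strand = "-"),
    f("trnE", "tRNA", "-", t_len(69)),
    cds("CYTB", 380, tail = "T"),
    f("trnT", "tRNA", "+", t_len(72)),
    f("trnP", "tRNA", "-", t_len(70)),
    f("D-loop", "control_region", "+", max(150L, round(890 * scale))))
  tpl$len[tpl$kind == "CDS"] <- tpl$codons[tpl$kind == "CDS"] * 3L +
    ifelse(tpl$tail[tpl$kind == "CDS"] %in% c("TAA", "TAG"), 3L,
           nchar(tpl$tail[tpl$kind == "CDS"]))
  tpl
}

# ---- sequence generation and evolution -------------------------------------

rand_bases <- function(n, freq) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq)
}

# codon sampling weights: product of base frequencies, stops excluded
codon_weights <- function(freq, code) {
  w <- vapply(names(code), function(cdn) {
    b <- seq_chars(cdn)
    freq[[b[1L]]] * freq[[b[2L]]] * freq[[b[3L]]]
  }, numeric(1L))
  w[code == "*"] <- 0
  w
}

#' Draw a random in-frame CDS with no internal stop codons
#'
#' @param n_codon number of coding codons including the start.
#' @param freq base frequencies.
#' @param code codon table.
#' @param start_codon initiation codon (ATG, or GTG as used by COX1).
#' @param tail terminal "TAA"/"TAG" (complete stop) or "T"/"TA"
#'   (incomplete stop completed by polyadenylation).
#' @return DNA string.
#' @export
random_cds <- function(n_codon, freq = default_base_comp(),
                       code = mito_code(), start_codon = "ATG", tail = "TAA") {
  w <- codon_weights(freq, code)
  body <- sample(names(code), n_codon - 1L, replace = TRUE, prob = w)
  paste0(start_codon, paste(body, collapse = ""),
         if (tail %in% c("TAA", "TAG")) tail else tail)
}

# HKY-like replacement kernel: new base j != i with weight freq_j * kappa
# if i<->j is a transition
propose_base <- function(old, freq, kappa) {
  partners <- c(A = "G", G = "A", C = "T", T = "C")
  w <- freq
  w[[partners[[old]]]] <- w[[partners[[old]]]] * kappa
  w[[old]] <- 0
  sample(c("A", "C", "G", "T"), 1L, prob = w)
}

#' Evolve a neutral sequence along a branch
#'
#' Each site mutates independently with probability branch * rate; the
#' replacement base is drawn from an HKY-like kernel (frequency-weighted,
#' transitions favoured by kappa).
#'
#' @param x base character vector (sense strand).
#' @param branch branch length (substitutions/site).
#' @param rate relative rate multiplier.
#' @param freq base frequencies.
#' @param kappa transition/transversion ratio.
#' @return mutated character vector.
#' @export
evolve_neutral <- function(x, branch, rate, freq = default_base_comp(),
                           kappa = 4) {
  p <- min(1, branch * rate)
  hit <- which(stats::runif(length(x)) < p)
  for (i in hit) x[i] <- propose_base(x[i], freq, kappa)
  x
}

#' Evolve a coding sequence along a branch under selection
#'
#' Proposal mutations arise as in [evolve_neutral()]; a proposal is
#' rejected if it creates a stop codon, accepted if synonymous, and
#' accepted with probability \code{omega} if nonsynonymous
#' (acceptance-rejection implementation of dN/dS).
#'
#' @param x base character vector (sense strand, in frame from position 1;
#'   bases beyond the last complete codon are left untouched).
#' @param branch branch length (substitutions/site).
#' @param rate relative rate multiplier.
#' @param omega dN/dS acceptance probability for nonsynonymous proposals.
#' @param freq base frequencies.
#' @param kappa transition/transversion ratio.
#' @param code codon table.
#' @return list: \code{seq} (mutated vector), \code{syn}, \code{nonsyn}
#'   (accepted substitution counts).
#' @export
evolve_cds <- function(x, branch, rate, omega, freq = default_base_comp(),
                       kappa = 4, code = mito_code()) {
  L <- length(x) - (length(x) %% 3L)
  p <- min(1, branch * rate)
  hit <- which(stats::runif(L) < p)
  hit <- hit[hit > 3L]  # the initiation codon is conserved
  syn <- 0L; nonsyn <- 0L
  for (i in hit) {
    ci <- (i - 1L) %/% 3L
    idx <- (ci * 3L + 1L):(ci * 3L + 3L)
    old_codon <- chars_seq(x[idx])
    new <- propose_base(x[i], freq, kappa)
    new_codon <- old_codon
    substr(new_codon, i - ci * 3L, i - ci * 3L) <- new
    aa_old <- translate_codon(old_codon, code)
    aa_new <- translate_codon(new_codon, code)
    if (is.na(aa_new) || aa_new == "*") next
    if (identical(aa_old, aa_new)) {
      x[i] <- new; syn <- syn + 1L
    } else if (stats::runif(1L) < omega) {
      x[i] <- new; nonsyn <- nonsyn + 1L
    }
  }
  list(seq = x, syn = syn, nonsyn = nonsyn)
}

# draw a background sequence free of tandem arrays at the detector's
# default thresholds (so planted arrays are the only ones in their regions)
screened_background <- function(n, freq, min_len = 8L, tries = 50L) {
  for (k in seq_len(tries)) {
    x <- rand_bases(n, freq)
    if (nrow(find_tandem_repeats(chars_seq(x), min_len = min_len)) == 0L) return(x)
  }
  stop("could not draw an array-free background", call. = FALSE)
}

# mutate a screened background without creating chance arrays
evolve_screened <- function(x, branch, rate, freq, kappa, tries = 20L) {
  for (k in seq_len(tries)) {
    y <- evolve_neutral(x, branch, rate, freq, kappa)
    if (nrow(find_tandem_repeats(chars_seq(y))) == 0L) return(y)
  }
  x  # give up on mutating this block rather than plant a spurious array
}

# ---- block plan -------------------------------------------------------------

# Build the ordered block plan from the template and repeat spec. Hosts of
# planted arrays (D-loop, trnS2, trnN-trnC spacer) are split into screened
# flank blocks and array blocks.
build_block_plan <- function(tpl, repeat_spec) {
  blocks <- list()
  igs_names <- character(0)
  # resolve spacer hosts: "X-Y" refers to the IGS between features X and Y
  host_of <- function(i) tpl$name[i]
  for (i in seq_len(nrow(tpl))) {
    nm <- tpl$name[i]
    host_specs <- Filter(function(sp) {
      sp$region == nm ||
        (tpl$kind[i] == "IGS" && i > 1L && i < nrow(tpl) &&
         sp$region == paste0(tpl$name[i - 1L], "-", tpl$name[i + 1L]))
    }, repeat_spec)
    if (length(host_specs) == 0L) {
      blocks[[length(blocks) + 1L]] <- list(
        feature = nm, kind = tpl$kind[i], strand = tpl$strand[i],
        type = "seq", len = tpl$len[i], codons = tpl$codons[i],
        tail = tpl$tail[i], screened = FALSE)
      next
    }
    # split host length into flanks around the arrays (max-copy footprint)
    arr_len <- vapply(host_specs, function(sp) {
      sp$copies[2L] * nchar(sp$unit)
    }, numeric(1L))
    flank_total <- max(length(host_specs) + 1L,
                       tpl$len[i] - sum(arr_len))
    k <- length(host_specs) + 1L
    fl <- diff(round(seq(0, flank_total, length.out = k + 1L)))
    for (j in seq_along(host_specs)) {
      blocks[[length(blocks) + 1L]] <- list(
        feature = nm, kind = tpl$kind[i], strand = "+", type = "seq",
        len = fl[j], codons = NA, tail = "", screened = TRUE)
      blocks[[length(blocks) + 1L]] <- c(
        list(feature = nm, kind = tpl$kind[i], strand = "+", type = "array",
             screened = FALSE), host_specs[[j]])
    }
    blocks[[length(blocks) + 1L]] <- list(
      feature = nm, kind = tpl$kind[i], strand = "+", type = "seq",
      len = fl[k], codons = NA, tail = "", screened = TRUE)
  }
  blocks
}

# ancestral sense-strand sequence for every seq block
ancestral_blocks <- function(blocks, freq, code) {
  lapply(blocks, function(b) {
    if (b$type == "array") return(NULL)
    if (b$kind == "CDS") {
      start <- if (b$feature == "COX1") "GTG" else "ATG"
      seq_chars(random_cds(b$codons, freq, code, start, b$tail))
    } else if (b$screened) {
      guarded_background(b, freq)
    } else {
      rand_bases(b$len, freq)
    }
  })
}

# screened background; the guard bases adjacent to arrays are fixed later,
# at assembly, via enforce_guards()
guarded_background <- function(b, freq) {
  if (b$len <= 0L) return(character(0))
  screened_background(b$len, freq)
}

# stop a planted array from extending into its flanks: the base just left
# of the array must differ from the unit's last base, the base just right
# from the unit's first base
enforce_guards <- function(blocks, seqs) {
  for (i in seq_along(blocks)) {
    if (blocks[[i]]$type != "array") next
    unit <- seq_chars(blocks[[i]]$unit)
    if (i > 1L && length(seqs[[i - 1L]]) > 0L) {
      j <- length(seqs[[i - 1L]])
      if (seqs[[i - 1L]][j] == unit[length(unit)]) {
        seqs[[i - 1L]][j] <- setdiff(c("A", "C", "G", "T"),
                                     unit[length(unit)])[1L]
      }
    }
    if (i < length(seqs) && length(seqs[[i + 1L]]) > 0L) {
      if (seqs[[i + 1L]][1L] == unit[1L]) {
        seqs[[i + 1L]][1L] <- setdiff(c("A", "C", "G", "T"), unit[1L])[1L]
      }
    }
  }
  seqs
}

# evolve all blocks along one branch; returns new seqs + per-gene counts
evolve_blocks <- function(blocks, seqs, branch, cfg, code, counts) {
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b$type == "array") next
    if (length(seqs[[i]]) == 0L) next
    rate <- block_rate(b, cfg)
    if (b$kind == "CDS") {
      res <- evolve_cds(seqs[[i]], branch, rate, cfg$omega[[b$feature]],
                        cfg$base_comp, cfg$kappa, code)
      seqs[[i]] <- res$seq
      counts[[b$feature]] <- counts[[b$feature]] + c(res$syn, res$nonsyn)
    } else if (b$screened) {
      seqs[[i]] <- evolve_screened(seqs[[i]], branch, rate, cfg$base_comp,
                                   cfg$kappa)
    } else {
      seqs[[i]] <- evolve_neutral(seqs[[i]], branch, rate, cfg$base_comp,
                                  cfg$kappa)
    }
  }
  list(seqs = seqs, counts = counts)
}

block_rate <- function(b, cfg) {
  r <- cfg$gene_rates
  if (b$feature %in% names(r)) return(unname(r[b$feature]))
  key <- switch(b$kind, tRNA = "tRNA", rRNA = "rRNA",
                control_region = "D-loop", pseudogene = "pseudogene", "IGS")
  unname(r[key])
}

# ---- the simulator ----------------------------------------------------------

#' Simulate an annotated mitogenome sample set with ground truth
#'
#' Draws an ancestral genome (codon-aware for the protein-coding genes: no
#' internal stops, ATG starts except GTG for COX1, incomplete stop codons
#' where the template specifies them), evolves it along the configured
#' species tree with per-gene rates and dN/dS (acceptance-rejection), adds
#' within-species haplotype divergence, plants tandem-repeat arrays with
#' per-sample copy numbers and SNP columns of known scope/type, and emits
#' annotated records, per-gene and whole-genome alignments, and a truth
#' table. Indels occur only through repeat copy-number variation (never in
#' CDS). Byte-identical output for identical config.
#'
#' @param config a [simulation_config()].
#' @return list of class \code{mito_sim}: \code{records} (named list of
#'   [mitogenome_record()]), \code{gene_alns} (named list of sense-strand
#'   [alignment_set()] per feature), \code{genome_aln} (whole-genome
#'   heavy-strand alignment), \code{species_of}, \code{truth} (tree,
#'   planted SNPs, planted repeats, per-gene substitution counts, omega
#'   and rate maps, gene column map), \code{config}.
#' @export
simulate_mitogenomes <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  code <- mito_code()
  tpl <- genome_template(cfg$scale)
  blocks <- build_block_plan(tpl, cfg$repeat_spec)
  anc <- ancestral_blocks(blocks, cfg$base_comp, code)
  anc <- enforce_guards(blocks, anc)

  phy <- ape::reorder.phylo(cfg$phy, "cladewise")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  counts0 <- stats::setNames(
    rep(list(c(syn = 0L, nonsyn = 0L)), sum(tpl$kind == "CDS")),
    tpl$name[tpl$kind == "CDS"])

  node_seqs <- vector("list", ntip + phy$Nnode)
  node_counts <- vector("list", ntip + phy$Nnode)
  node_seqs[[root]] <- anc
  node_counts[[root]] <- counts0
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    res <- evolve_blocks(blocks, node_seqs[[par]], phy$edge.length[e], cfg,
                         code, node_counts[[par]])
    node_seqs[[child]] <- res$seqs
    node_counts[[child]] <- res$counts
  }

  # per-sample haplotypes
  sample_ids <- character(0); species_of <- character(0)
  sample_seqs <- list()
  gene_counts <- counts0
  for (sp in phy$tip.label) {
    tip <- match(sp, phy$tip.label)
    for (k in seq_len(cfg$n_samples[[sp]])) {
      sid <- sprintf("%s_%02d", abbreviate_species(sp), k)
      res <- evolve_blocks(blocks, node_seqs[[tip]], cfg$intra_branch, cfg,
                           code, node_counts[[tip]])
      sample_ids <- c(sample_ids, sid)
      species_of[sid] <- sp
      sample_seqs[[sid]] <- res$seqs
    }
  }
  for (g in names(gene_counts)) {
    # total accepted substitutions over the species tree (root to tips)
    gene_counts[[g]] <- Reduce(`+`, lapply(seq_len(ntip),
                                           function(t) node_counts[[t]][[g]]))
  }

  ingroup <- sample_ids[species_of[sample_ids] != cfg$outgroup]

  # plant SNP columns with known scope/type into the rRNA blocks
  planted <- plant_snps(blocks, sample_seqs, ingroup, species_of, cfg)
  sample_seqs <- planted$seqs
  snp_truth <- planted$truth

  # re-assert the array junction guards (a flank base adjacent to a planted
  # array may have mutated into an array-extending state)
  for (sid in sample_ids) {
    sample_seqs[[sid]] <- enforce_guards(blocks, sample_seqs[[sid]])
  }

  # per-sample repeat copy numbers
  arrays <- draw_arrays(blocks, sample_ids, species_of, cfg)

  # block-local screening cannot see arrays that straddle block boundaries
  # (e.g. a tRNA end continuing periodically into a screened flank); break
  # any non-planted array overlapping the repeat compartments
  sample_seqs <- repair_spurious_arrays(blocks, sample_seqs, arrays,
                                        sample_ids)

  asm <- assemble_samples(blocks, sample_seqs, arrays, sample_ids,
                          species_of, tpl)

  snp_truth$column <- asm$block_col_offset[snp_truth$block] + snp_truth$pos
  truth <- list(tree = cfg$phy, snps = snp_truth, repeats = arrays$truth,
                gene_counts = gene_counts, omega = cfg$omega,
                rates = cfg$gene_rates, gene_columns = asm$gene_columns,
                ingroup = ingroup)
  structure(list(records = asm$records, gene_alns = asm$gene_alns,
                 genome_aln = asm$genome_aln, species_of = species_of,
                 truth = truth, config = cfg),
            class = "mito_sim")
}

abbreviate_species <- function(sp) {
  parts <- strsplit(sp, "_", fixed = TRUE)[[1L]]
  if (length(parts) >= 2L) {
    paste0(substr(parts[1L], 1L, 1L), substr(parts[2L], 1L, 3L))
  } else substr(sp, 1L, 4L)
}

# choose distinct positions in the rRNA blocks and overwrite ingroup bases
# to realise configured intra / type i / ii / iii columns
plant_snps <- function(blocks, sample_seqs, ingroup, species_of, cfg) {
  rblocks <- which(vapply(blocks, function(b) {
    b$type == "seq" && b$kind == "rRNA"
  }, logical(1L)))
  sp_in <- unique(species_of[ingroup])
  n_per_sp <- table(species_of[ingroup])
  if (any(n_per_sp[sp_in] < 2L)) {
    stop("SNP planting needs >= 2 samples per ingroup species", call. = FALSE)
  }
  n_plant <- with(cfg$snp_plant,
                  intra_per_species * length(sp_in) + type_i + type_ii + type_iii)
  slots <- do.call(rbind, lapply(rblocks, function(bi) {
    data.frame(block = bi, pos = seq_along(sample_seqs[[ingroup[1L]]][[bi]]))
  }))
  pick <- slots[sample.int(nrow(slots), n_plant), ]
  truth <- NULL
  r <- 0L
  assign_col <- function(bi, pos, alleles_by_sample) {
    for (sid in names(alleles_by_sample)) {
      sample_seqs[[sid]][[bi]][pos] <<- alleles_by_sample[[sid]]
    }
  }
  two_alleles <- function() sample(c("A", "C", "G", "T"), 2L)
  for (sp in sp_in) {
    for (k in seq_len(cfg$snp_plant$intra_per_species)) {
      r <- r + 1L
      ab <- two_alleles()
      al <- stats::setNames(rep(ab[1L], length(ingroup)), ingroup)
      own <- ingroup[species_of[ingroup] == sp]
      n_minor <- sample.int(length(own) - 1L, 1L)
      al[sample(own, n_minor)] <- ab[2L]
      assign_col(pick$block[r], pick$pos[r], as.list(al))
      truth <- rbind(truth, data.frame(block = pick$block[r], pos = pick$pos[r],
                                       scope = "intra", inter_type = "none",
                                       species = sp, stringsAsFactors = FALSE))
    }
  }
  plant_type <- function(type, n) {
    for (k in seq_len(n)) {
      r <<- r + 1L
      ab <- two_alleles()
      roles <- sample(sp_in)
      al <- stats::setNames(rep(ab[1L], length(ingroup)), ingroup)
      if (type == "i") {
        # first species segregates, second fixed for one allele, third for
        # the other
        own <- ingroup[species_of[ingroup] == roles[1L]]
        al[sample(own, sample.int(length(own) - 1L, 1L))] <- ab[2L]
        al[species_of[ingroup] == roles[3L]] <- ab[2L]
      } else if (type == "ii") {
        for (sp in roles) {
          own <- ingroup[species_of[ingroup] == sp]
          al[sample(own, sample.int(length(own) - 1L, 1L))] <- ab[2L]
        }
      } else {  # iii: two fixed groups
        al[species_of[ingroup] == roles[1L]] <- ab[2L]
      }
      assign_col(pick$block[r], pick$pos[r], as.list(al))
      truth <<- rbind(truth, data.frame(block = pick$block[r], pos = pick$pos[r],
                                        scope = "inter", inter_type = type,
                                        species = NA_character_,
                                        stringsAsFactors = FALSE))
    }
  }
  plant_type("i", cfg$snp_plant$type_i)
  plant_type("ii", cfg$snp_plant$type_ii)
  plant_type("iii", cfg$snp_plant$type_iii)
  list(seqs = sample_seqs, truth = truth)
}

# per-sample copy numbers (whole-unit steps) and unit variants
draw_arrays <- function(blocks, sample_ids, species_of, cfg) {
  ab <- which(vapply(blocks, function(b) b$type == "array", logical(1L)))
  copies <- list(); units <- list(); truth <- NULL
  for (bi in ab) {
    b <- blocks[[bi]]
    cp_range <- seq.int(b$copies[1L], b$copies[2L])
    cp <- stats::setNames(
      if (length(cp_range) == 1L) rep(cp_range, length(sample_ids))
      else sample(cp_range, length(sample_ids), replace = TRUE),
      sample_ids)
    un <- stats::setNames(rep(b$unit, length(sample_ids)), sample_ids)
    if (!is.null(b$alt_unit)) {
      un[species_of[sample_ids] == b$alt_species] <- b$alt_unit
    }
    copies[[as.character(bi)]] <- cp
    units[[as.character(bi)]] <- un
    truth <- rbind(truth, data.frame(
      block = bi, feature = b$feature, sample_id = sample_ids,
      unit = unname(un), copies = unname(cp), stringsAsFactors = FALSE))
  }
  list(blocks = ab, copies = copies, units = units, truth = truth)
}

# Deterministically mutate single bases so the planted arrays are the only
# tandem arrays overlapping the control region, pseudogene and spacer
# compartments. A spurious array always has a position outside the planted
# array blocks (arrays themselves are never mutated); that base is set to a
# value breaking the periodicity at the array's lag without creating a new
# match, and the genome is re-scanned until clean.
repair_spurious_arrays <- function(blocks, sample_seqs, arrays, sample_ids,
                                   max_pass = 60L) {
  nb <- length(blocks)
  comp <- vapply(blocks, function(b) {
    b$kind %in% c("control_region", "pseudogene", "IGS")
  }, logical(1L))
  is_array <- vapply(blocks, function(b) b$type == "array", logical(1L))
  for (sid in sample_ids) {
    heavy <- character(nb)
    for (i in seq_len(nb)) {
      heavy[i] <- if (is_array[i]) {
        strrep(arrays$units[[as.character(i)]][[sid]],
               arrays$copies[[as.character(i)]][[sid]])
      } else {
        s <- chars_seq(sample_seqs[[sid]][[i]])
        if (identical(blocks[[i]]$strand, "-")) reverse_complement(s) else s
      }
    }
    lens <- nchar(heavy)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    g <- seq_chars(paste(heavy, collapse = ""))
    block_of <- rep(seq_len(nb), lens)
    changed_any <- FALSE
    for (pass in seq_len(max_pass)) {
      hits <- find_tandem_repeats(chars_seq(g))
      fixed <- FALSE
      for (h in seq_len(nrow(hits))) {
        span <- hits$start[h]:hits$end[h]
        bl <- unique(block_of[span])
        if (!any(comp[bl])) next
        # exact planted array?
        if (length(bl) == 1L && is_array[bl] &&
            hits$start[h] == starts[bl] && hits$end[h] == ends[bl]) next
        u <- hits$unit_len[h]
        cand <- span[!is_array[block_of[span]]]
        if (length(cand) == 0L) next
        # prefer positions outside coding sequence
        kinds <- vapply(blocks[block_of[cand]], `[[`, character(1L), "kind")
        if (any(kinds != "CDS")) cand <- cand[kinds != "CDS"]
        p <- cand[1L]
        avoid <- c(g[p],
                   if (p + u <= length(g)) g[p + u],
                   if (p - u >= 1L) g[p - u])
        g[p] <- setdiff(c("A", "C", "G", "T"), avoid)[1L]
        fixed <- TRUE
        changed_any <- TRUE
        break
      }
      if (!fixed) break
    }
    if (changed_any) {
      for (i in seq_len(nb)) {
        if (is_array[i]) next
        s <- chars_seq(g[starts[i]:ends[i]])
        if (identical(blocks[[i]]$strand, "-")) s <- reverse_complement(s)
        sample_seqs[[sid]][[i]] <- seq_chars(s)
      }
    }
  }
  sample_seqs
}

# assemble per-sample genomes, feature tables, per-gene and whole-genome
# alignments
assemble_samples <- function(blocks, sample_seqs, arrays, sample_ids,
                             species_of, tpl) {
  nb <- length(blocks)
  # alignment width per block
  widths <- integer(nb)
  for (i in seq_len(nb)) {
    widths[i] <- if (blocks[[i]]$type == "array") {
      max(arrays$copies[[as.character(i)]]) * nchar(blocks[[i]]$unit)
    } else {
      length(sample_seqs[[sample_ids[1L]]][[i]])
    }
  }
  block_col_offset <- c(0L, cumsum(widths))[seq_len(nb)]

  # per-sample heavy-strand block strings (aligned + ungapped)
  aligned <- list(); ungapped <- list()
  for (sid in sample_ids) {
    al <- character(nb); un <- character(nb)
    for (i in seq_len(nb)) {
      b <- blocks[[i]]
      if (b$type == "array") {
        u <- arrays$units[[as.character(i)]][[sid]]
        cp <- arrays$copies[[as.character(i)]][[sid]]
        s <- strrep(u, cp)
        un[i] <- s
        al[i] <- paste0(s, strrep("-", widths[i] - nchar(s)))
      } else {
        s <- chars_seq(sample_seqs[[sid]][[i]])
        if (identical(b$strand, "-")) s <- reverse_complement(s)
        un[i] <- s
        al[i] <- s
      }
    }
    aligned[[sid]] <- al
    ungapped[[sid]] <- un
  }

  # feature tables and records per sample
  records <- list()
  for (sid in sample_ids) {
    lens <- nchar(ungapped[[sid]])
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    feats <- NULL
    for (fname in unique(vapply(blocks, `[[`, character(1L), "feature"))) {
      bis <- which(vapply(blocks, function(b) b$feature == fname, logical(1L)))
      ki <- blocks[[bis[1L]]]$kind
      if (ki == "IGS") next  # spacers stay unannotated; derive_igs finds them
      feats <- rbind(feats, data.frame(
        name = fname, kind = ki,
        start = starts[min(bis)], end = ends[max(bis)],
        strand = blocks[[bis[1L]]]$strand,
        codon_start = if (ki == "CDS") 1L else NA_integer_,
        pseudo = ki == "pseudogene", stringsAsFactors = FALSE))
    }
    records[[sid]] <- mitogenome_record(
      sid, species_of[[sid]], paste(ungapped[[sid]], collapse = ""),
      circular = TRUE, features = feats)
  }

  # whole-genome alignment (heavy strand)
  gseqs <- vapply(sample_ids, function(sid) paste(aligned[[sid]], collapse = ""),
                  character(1L))
  genome_aln <- alignment_set(gseqs, species_of, region = "whole-genome")

  # per-gene alignments on the sense strand + gene -> column map
  gene_alns <- list(); gene_columns <- list()
  for (fname in tpl$name) {
    bis <- which(vapply(blocks, function(b) b$feature == fname, logical(1L)))
    cols <- unlist(lapply(bis, function(i) {
      block_col_offset[i] + seq_len(widths[i])
    }))
    gene_columns[[fname]] <- cols
    rows <- vapply(sample_ids, function(sid) {
      s <- paste(aligned[[sid]][bis], collapse = "")
      if (identical(blocks[[bis[1L]]]$strand, "-")) reverse_complement(s) else s
    }, character(1L))
    gene_alns[[fname]] <- alignment_set(rows, species_of, region = fname)
  }

  list(records = records, gene_alns = gene_alns, genome_aln = genome_aln,
       gene_columns = gene_columns, block_col_offset = block_col_offset)
}

#' @export
print.mito_sim <- function(x, ...) {
  cat(sprintf("<mito_sim> %d samples, %d species, genome %d bp (aligned %d)\n",
              length(x$records), length(unique(x$species_of)),
              x$records[[1L]]$length, ncol(x$genome_aln$seqs)))
  invisible(x)
}

#' Write simulated outputs to disk
#'
#' GenBank per sample, aligned FASTA per gene and whole genome, a grouping
#' TSV and truth tables (TSV/JSON).
#'
#' @param sim a \code{mito_sim} from [simulate_mitogenomes()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$records)) {
    write_genbank(sim$records[[sid]], file.path(dir, paste0(sid, ".gb")))
  }
  write_fasta(sim$genome_aln, file.path(dir, "whole_genome.aln.fasta"))
  gdir <- file.path(dir, "genes")
  dir.create(gdir, showWarnings = FALSE)
  for (g in names(sim$gene_alns)) {
    write_fasta(sim$gene_alns[[g]], file.path(gdir, paste0(g, ".aln.fasta")))
  }
  utils::write.table(
    data.frame(sample_id = names(sim$species_of),
               species = unname(sim$species_of)),
    file.path(dir, "grouping.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$repeats, file.path(dir, "truth_repeats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(omega = as.list(sim$truth$omega), rates = as.list(sim$truth$rates)),
    file.path(dir, "truth_params.json"), auto_unbox = TRUE, digits = NA)
  write_newick(sim$truth$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
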