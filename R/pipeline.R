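#' Pipeline run configuration
#'
#' Validates inputs for [run_pipeline()]. Inputs are either a directory in
#' the layout written by [write_simulation()] (GenBank per sample, a
#' \code{genes/} directory of per-gene aligned FASTA, a whole-genome
#' aligned FASTA and a grouping TSV) or an in-memory \code{mito_sim}.
#'
#' @param input a \code{mito_sim} object or a directory path.
#' @param reference_id sample id anchoring substitution counting and VCF
#'   coordinates.
#' @param outgroup_id sample id of the outgroup (amino-acid spectrum,
#'   display rooting); NULL disables the spectrum stage.
#' @param out_dir output directory for the report bundle.
#' @param stages subset of
#'   c("compose","codon","repeats","variants","popgen","selection","phylo").
#' @param seed integer seed (bootstrap resampling).
#' @param repeat_min_len minimum tandem-array length (bp).
#' @param bootstrap_reps bootstrap replicates for the trees.
#' @param model distance model for the trees ("p", "JC69", "K2P").
#' @return list of class \code{run_config}.
#' @export
pipeline_config <- function(input, reference_id, outgroup_id = NULL,
                            out_dir = "mitocomp_out",
                            stages = c("compose", "codon", "repeats",
                                       "variants", "popgen", "selection",
                                       "phylo"),
                            seed = 1L, repeat_min_len = 8L,
                            bootstrap_reps = 100L,
                            model = "JC69") {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(input)) {
    if (!dir.exists(input)) stop("input directory does not exist", call. = FALSE)
    need <- c("whole_genome.aln.fasta", "grouping.tsv")
    miss <- need[!file.exists(file.path(input, need))]
    if (length(miss)) {
      stop(sprintf("missing input file(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
  } else if (!inherits(input, "mito_sim")) {
    stop("input must be a mito_sim or a directory path", call. = FALSE)
  }
  structure(list(input = input, reference_id = reference_id,
                 outgroup_id = outgroup_id, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed),
                 repeat_min_len = repeat_min_len,
                 bootstrap_reps = bootstrap_reps, model = model),
            class = "run_config")
}

load_pipeline_inputs <- function(input) {
  if (inherits(input, "mito_sim")) {
    return(list(records = input$records, gene_alns = input$gene_alns,
                genome_aln = input$genome_aln, species_of = input$species_of))
  }
  species_of <- read_grouping(file.path(input, "grouping.tsv"))
  gb <- list.files(input, pattern = "\\.gb$", full.names = TRUE)
  records <- lapply(gb, read_genbank)
  names(records) <- vapply(records, `[[`, character(1L), "sample_id")
  for (sid in names(records)) records[[sid]]$species <- species_of[[sid]]
  genome_aln <- read_aligned_fasta(file.path(input, "whole_genome.aln.fasta"),
                                   species_of, region = "whole-genome")
  gene_alns <- list()
  gdir <- file.path(input, "genes")
  if (dir.exists(gdir)) {
    for (f in list.files(gdir, pattern = "\\.aln\\.fasta$", full.names = TRUE)) {
      g <- sub("\\.aln\\.fasta$", "", basename(f))
      gene_alns[[g]] <- read_aligned_fasta(f, species_of, region = g)
    }
  }
  list(records = records, gene_alns = gene_alns, genome_aln = genome_aln,
       species_of = species_of)
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Orchestrates composition/skew profiling, codon usage, tandem repeats,
#' SNP/indel calling and typing, diversity statistics, substitution
#' counting with amino-acid spectra, and neighbor-joining trees over the
#' whole-genome, CDS, control-region and spacer partitions. Per-stage TSVs
#' plus a consolidated JSON summary are written under
#' \code{config$out_dir}; every run parameter is logged. Deterministic
#' given the seed. A stage failure aborts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with every stage's in-memory result and
#'   \code{summary} (the JSON summary as a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = log_path)
  logf("mitocomp pipeline: stages=%s seed=%d repeat_min_len=%d bootstrap=%d model=%s",
       paste(config$stages, collapse = ","), config$seed,
       config$repeat_min_len, config$bootstrap_reps, config$model)

  inp <- load_pipeline_inputs(config$input)
  records <- inp$records; gene_alns <- inp$gene_alns
  genome_aln <- inp$genome_aln; species_of <- inp$species_of
  ref_rec <- records[[config$reference_id]]
  if (is.null(ref_rec)) stop("reference_id not among records", call. = FALSE)

  res <- list()
  summary <- list(
    parameters = list(seed = config$seed, reference_id = config$reference_id,
                      outgroup_id = config$outgroup_id,
                      repeat_min_len = config$repeat_min_len,
                      bootstrap_reps = config$bootstrap_reps,
                      model = config$model),
    genomes = data.frame(
      sample_id = names(records),
      species = vapply(records, `[[`, character(1L), "species"),
      length_bp = vapply(records, `[[`, numeric(1L), "length"),
      n_features = vapply(records, function(r) nrow(r$features), numeric(1L)),
      row.names = NULL))

  stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    logf("stage %s ...", name)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  stage("compose", function() {
    tab <- do.call(rbind, lapply(names(records), function(sid) {
      t <- per_gene_skew_table(records[[sid]])
      t$sample_id <- sid
      t
    }))
    write_composition_tsv(tab, file.path(config$out_dir, "composition.tsv"))
    wg <- tab[tab$region == "whole-genome", ]
    summary$composition <<- data.frame(
      sample_id = wg$sample_id, at_content = round(wg$at_content, 2L),
      gc_content = round(wg$gc_content, 2L),
      at_skew = round(wg$at_skew, 4L), gc_skew = round(wg$gc_skew, 4L))
    res$composition <<- tab
  })

  stage("codon", function() {
    cds_by_species <- list()
    for (sid in names(records)) {
      sp <- records[[sid]]$species
      ft <- records[[sid]]$features
      cds_idx <- which(ft$kind == "CDS")
      cds_by_species[[sp]] <- c(cds_by_species[[sp]],
        lapply(cds_idx, function(i) {
          s <- extract_gene(records[[sid]], i)
          substr(s, ft$codon_start[i], nchar(s))
        }))
    }
    rep_ <- codon_usage_report(lapply(cds_by_species, unlist))
    write_codon_usage_tsv(rep_, file.path(config$out_dir, "codon_usage.tsv"))
    summary$codon_usage <<- list(
      total_codons = sum(rep_$count[rep_$aa != "*"]),
      biased = sum(rep_$bias == "biased", na.rm = TRUE),
      rare = sum(rep_$bias == "rare", na.rm = TRUE))
    res$codon_usage <<- rep_
  })

  stage("repeats", function() {
    hits_by_sample <- lapply(records, function(rec) {
      locate_repeats(find_tandem_repeats(rec$sequence,
                                         min_len = config$repeat_min_len), rec)
    })
    all_hits <- do.call(rbind, lapply(names(hits_by_sample), function(sid) {
      h <- hits_by_sample[[sid]]
      if (nrow(h)) h$sample_id <- sid
      h
    }))
    write_repeats_tsv(all_hits, file.path(config$out_dir, "repeats.tsv"))
    sm <- repeat_class_summary(hits_by_sample)
    poly <- polymorphic_repeats(hits_by_sample, species_of)
    if (!is.null(poly)) {
      write_repeats_tsv(poly, file.path(config$out_dir, "repeats_polymorphic.tsv"))
    }
    summary$repeats <<- list(
      classes = data.frame(class = sm$classes$class,
                           abundance = sm$classes$abundance,
                           percentage = round(sm$classes$percentage, 2L)),
      location_split = if (is.null(sm$location_split)) NULL else
        data.frame(location = sm$location_split$location,
                   percentage = round(sm$location_split$percentage, 2L)))
    res$repeats <<- list(hits = hits_by_sample, summary = sm, polymorphic = poly)
  })

  stage("variants", function() {
    regions <- column_regions(genome_aln, ref_rec, config$reference_id)
    calls <- call_variants(genome_aln)
    sm <- variant_summary(calls, species_of, regions)
    utils::write.table(sm$table, file.path(config$out_dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf(calls, genome_aln, config$reference_id,
              file.path(config$out_dir, "variants.vcf"))
    summary$variants <<- list(
      totals = sm$totals,
      intra_by_species = as.list(sm$intra_by_species),
      inter_by_type = as.list(sm$inter_by_type),
      pairwise_fixed = as.list(sm$pairwise_fixed))
    res$variants <<- sm
  })

  stage("popgen", function() {
    tab <- diversity_table(gene_alns)
    write_diversity_tsv(tab, file.path(config$out_dir, "diversity.tsv"))
    summary$diversity <<- list(
      regions = length(gene_alns),
      max_pi_region = tab$region[which.max(tab$pi)][1L])
    res$diversity <<- tab
  })

  stage("selection", function() {
    kinds <- feature_kinds(ref_rec)
    cds_genes <- names(gene_alns)[kinds[names(gene_alns)] %in% "CDS"]
    counts <- NULL
    qry <- one_sample_per_species(species_of,
                                  exclude = c(config$reference_id,
                                              config$outgroup_id))
    qry <- setdiff(qry, records[[config$reference_id]]$sample_id)
    for (g in cds_genes) {
      for (q in qry) {
        counts <- rbind(counts,
          count_gene_substitutions(gene_alns[[g]], config$reference_id, q,
                                   gene = g))
      }
    }
    write_substitutions_tsv(counts,
                            file.path(config$out_dir, "substitutions.tsv"))
    avg <- substitution_rate_summary(counts)
    utils::write.table(avg, file.path(config$out_dir, "substitution_averages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$selection <<- list(
      genes = length(cds_genes),
      max_mean_omega_gene = avg$gene[which.max(avg$mean_omega)][1L])
    if (!is.null(config$outgroup_id)) {
      prot <- lapply(gene_alns[cds_genes], translate_alignment)
      spec <- amino_acid_change_spectrum(prot, config$outgroup_id, species_of)
      if (!is.null(spec$changes)) {
        utils::write.table(spec$changes,
                           file.path(config$out_dir, "aa_changes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(spec$pair_imbalance,
                           file.path(config$out_dir, "aa_pair_imbalance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      res$aa_spectrum <<- spec
    }
    res$substitutions <<- list(counts = counts, averages = avg)
  })

  stage("phylo", function() {
    kinds <- feature_kinds(ref_rec)
    parts <- list(genome = genome_aln)
    cds_genes <- names(gene_alns)[kinds[names(gene_alns)] %in% "CDS"]
    if (length(cds_genes)) parts$cds <- concat_alignments(gene_alns[cds_genes], "cds")
    dl <- names(gene_alns)[kinds[names(gene_alns)] %in% "control_region"]
    if (length(dl)) parts$dloop <- gene_alns[[dl[1L]]]
    igs <- names(gene_alns)[is.na(kinds[names(gene_alns)]) |
                            kinds[names(gene_alns)] %in% "IGS"]
    if (length(igs)) parts$igs <- concat_alignments(gene_alns[igs], "igs")
    trees <- list()
    for (p in names(parts)) {
      bs <- bootstrap_support(parts[[p]], model = config$model,
                              n_reps = config$bootstrap_reps,
                              seed = config$seed)
      write_newick(bs$tree, file.path(config$out_dir,
                                      sprintf("tree_%s.nwk", p)))
      trees[[p]] <- bs
    }
    summary$phylo <<- lapply(trees, function(bs) {
      ape::write.tree(bs$tree)
    })
    res$trees <<- trees
  })

  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = 8,
                       dataframe = "rows")
  logf("summary written to %s", summary_path)
  res$summary <- summary
  invisible(res)
}

feature_kinds <- function(record) {
  stats::setNames(record$features$kind, record$features$name)
}

one_sample_per_species <- function(species_of, exclude = NULL) {
  ids <- setdiff(names(species_of), exclude)
  ids[!duplicated(species_of[ids])]
}

# column-bind alignments sharing the same rows
concat_alignments <- function(alns, region) {
  ids <- alns[[1L]]$ids
  m <- do.call(cbind, lapply(alns, function(a) a$seqs[ids, , drop = FALSE]))
  alignment_set(m, alns[[1L]]$species, region = region)
}
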