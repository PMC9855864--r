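test_that("identical config gives byte-identical output", {
  cfg <- simulation_config(seed = 99L, scale = 0.1)
  s1 <- simulate_mitogenomes(cfg)
  s2 <- simulate_mitogenomes(cfg)
  expect_identical(s1$genome_aln$seqs, s2$genome_aln$seqs)
  expect_identical(lapply(s1$records, `[[`, "sequence"),
                   lapply(s2$records, `[[`, "sequence"))
  expect_identical(s1$truth$snps, s2$truth$snps)
  expect_identical(s1$truth$repeats, s2$truth$repeats)
})

test_that("zero branch lengths give identical samples everywhere", {
  tree0 <- paste0("((Oreochromis_niloticus:0,Sarotherodon_galilaeus:0):0,",
                  "Coptodon_zillii:0,Oncorhynchus_keta:0);")
  spec0 <- lapply(default_repeat_spec(), function(sp) {
    sp$copies <- c(sp$copies[2L], sp$copies[2L])  # fixed copy numbers
    sp$alt_unit <- NULL                           # no species-specific units
    sp$alt_species <- NULL
    sp
  })
  cfg <- simulation_config(seed = 5L, tree = tree0, intra_branch = 0,
                           scale = 0.1, repeat_spec = spec0,
                           snp_plant = list(intra_per_species = 0L,
                                            type_i = 0L, type_ii = 0L,
                                            type_iii = 0L))
  sim <- simulate_mitogenomes(cfg)
  seqs <- vapply(sim$records, `[[`, character(1L), "sequence")
  expect_identical(length(unique(seqs)), 1L)
  ing <- sim$truth$ingroup
  aln <- alignment_set(sim$genome_aln$seqs[ing, , drop = FALSE],
                       sim$species_of[ing], "wg")
  expect_length(call_variants(aln), 0L)
  expect_equal(nucleotide_diversity(aln), 0)
})

test_that("genome structure matches the vertebrate template", {
  sim <- mini_sim()
  rec <- sim$records[[1L]]
  ft <- rec$features
  expect_identical(sum(ft$kind == "CDS"), 13L)
  # 22 tRNA genes, one of which (trnS2) is annotated as a pseudogene
  expect_identical(sum(ft$kind == "tRNA"), 21L)
  expect_identical(ft$name[ft$kind == "pseudogene"], "trnS2")
  expect_identical(sum(ft$kind == "rRNA"), 2L)
  expect_identical(sum(ft$kind == "control_region"), 1L)
  expect_true(rec$circular)
  # light strand: ND6 + 8 tRNAs
  light <- ft$name[ft$strand == "-"]
  expect_identical(sum(light == "ND6"), 1L)
  expect_identical(length(light), 9L)
  # CDS starts and stops: ATG (GTG for COX1), no internal stops
  code <- mito_code()
  for (g in ft$name[ft$kind == "CDS"]) {
    s <- extract_gene(rec, g)
    expect_identical(substr(s, 1L, 3L), if (g == "COX1") "GTG" else "ATG")
    aa <- translate_dna(s)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    expect_false(grepl("*", body, fixed = TRUE),
                 label = sprintf("internal stop in %s", g))
  }
})

test_that("full-scale genome size and composition are in the real range", {
  sim <- simulate_mitogenomes(simulation_config(seed = 11L))
  L <- sim$records[[1L]]$length
  expect_gt(L, 16000L)
  expect_lt(L, 17000L)
  comp <- base_composition(sim$records[[1L]]$sequence)
  expect_gt(comp$at_content, 50)
  expect_lt(comp$at_content, 58)
})

test_that("control-region composition tracks the target within 3 SE", {
  sim <- mini_sim()
  rec <- sim$records[[1L]]
  dl <- extract_gene(rec, "D-loop")
  comp <- base_composition(dl)
  n <- nchar(dl)
  target <- default_base_comp()
  for (b in c("A", "C", "G", "T")) {
    p <- target[[b]]
    se <- sqrt(p * (1 - p) / n)
    # planted repeat arrays sit inside the region, so allow their footprint
    # on top of the multinomial band
    expect_lt(abs(comp[[paste0(b, "_pct")]] / 100 - p), 3 * se + 0.05)
  }
})

test_that("substitution counts scale linearly with branch x rate", {
  set.seed(13)
  L <- 3000L
  x <- rand_bases_for_test(L)
  bls <- c(0.02, 0.05, 0.1, 0.2)
  mean_subs <- vapply(bls, function(b) {
    mean(replicate(12L, {
      y <- evolve_neutral(x, b, rate = 1)
      sum(y != x)
    }))
  }, numeric(1L))
  fit <- stats::lm(mean_subs ~ 0 + bls)
  # per-site mutation probability b gives an expected slope of L
  expect_lt(abs(unname(stats::coef(fit)) - L) / L, 0.1)
})

test_that("high-omega genes accumulate relatively more nonsynonymous changes", {
  set.seed(14)
  wins <- replicate(20L, {
    anc <- seq_chars(random_cds(300L))
    hi <- evolve_cds(anc, 0.15, 1, omega = 1.0)
    lo <- evolve_cds(anc, 0.15, 1, omega = 0.1)
    r_hi <- hi$nonsyn / max(1L, hi$syn)
    r_lo <- lo$nonsyn / max(1L, lo$syn)
    r_hi > r_lo
  })
  expect_gte(mean(wins), 0.95)
})

test_that("whole-genome alignment columns reproduce the per-gene alignments", {
  sim <- mini_sim()
  cols <- sim$truth$gene_columns
  # heavy-strand gene: identical slice
  nd2 <- sim$genome_aln$seqs[, cols[["ND2"]], drop = FALSE]
  expect_identical(unname(nd2), unname(sim$gene_alns[["ND2"]]$seqs))
  # light-strand gene: slice is the reverse complement of the sense alignment
  nd6_slice <- sim$genome_aln$seqs[, cols[["ND6"]], drop = FALSE]
  sense <- sim$gene_alns[["ND6"]]$seqs
  rc <- t(apply(sense, 1L, function(r) rev(chartr("ACGT", "TGCA", r))))
  expect_identical(unname(nd6_slice), unname(rc))
})

test_that("recovery on a noiseless simulation is perfect", {
  tree_tiny <- paste0("((Oreochromis_niloticus:0.001,",
                      "Sarotherodon_galilaeus:0.001):0.001,",
                      "Coptodon_zillii:0.002,Oncorhynchus_keta:0.01);")
  cfg <- simulation_config(seed = 21L, tree = tree_tiny,
                           intra_branch = 0.0005, scale = 0.1)
  sim <- simulate_mitogenomes(cfg)
  rr <- recovery_report(sim)
  expect_identical(rr$snp$recall, 1)
  expect_identical(rr$snp$accuracy, 1)
  expect_identical(rr$repeats$recall, 1)
  expect_identical(rr$repeats$precision, 1)
  # confusion-matrix row sums equal the planted counts
  expect_equal(sum(rr$snp$confusion), nrow(sim$truth$snps))
  n_iii <- sum(sim$truth$snps$inter_type == "iii")
  expect_equal(unname(rowSums(rr$snp$confusion)["inter/iii"]), n_iii)
})

test_that("written simulation round-trips through the file interfaces", {
  sim <- mini_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "whole_genome.aln.fasta")))
  back <- read_aligned_fasta(file.path(dir, "whole_genome.aln.fasta"),
                             file.path(dir, "grouping.tsv"))
  expect_identical(back$seqs, sim$genome_aln$seqs)
  rec <- read_genbank(file.path(dir, paste0(names(sim$records)[1L], ".gb")))
  expect_identical(rec$sequence, sim$records[[1L]]$sequence)
  tr <- read_newick(file.path(dir, "true_tree.nwk"))
  expect_setequal(tr$tip.label, sim$truth$tree$tip.label)
})
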