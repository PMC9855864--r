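test_that("single-site classification under the mitochondrial code", {
  expect_identical(classify_site_substitution("CTT", 3L, "C"), "synonymous")
  expect_identical(classify_site_substitution("ATG", 1L, "G"), "nonsynonymous")
  # TGA is Trp in the mito code, so TGA -> TGG is synonymous
  expect_identical(classify_site_substitution("TGA", 3L, "G"), "synonymous")
  expect_warning(out <- classify_site_substitution("ANG", 2L, "C"), "skipped")
  expect_true(is.na(out))
})

test_that("omega convention matches the printed-count rules", {
  expect_equal(omega_from_counts(76, 24), 24 / 76)
  expect_equal(omega_from_counts(0, 0), 0)   # "0 0 0" rows
  expect_equal(omega_from_counts(2, 0), 0)   # "2 0 0" rows
  expect_true(is.na(omega_from_counts(0, 3)))
})

test_that("gene-level counting sums per-site classifications", {
  # identical rows
  sp <- c(r = "ref_sp", q = "qry_sp")
  aln <- make_aln(c(r = "ATGAAACCC", q = "ATGAAACCC"), sp, region = "g")
  cnt <- count_gene_substitutions(aln, "r", "q")
  expect_identical(c(cnt$syn_count, cnt$nonsyn_count), c(0L, 0L))
  expect_equal(cnt$omega, 0)
  # hand-built 4-codon pair: CTT->CTC (syn), GGA->GGG (syn), ATG->GTG (nonsyn)
  aln <- make_aln(c(r = "CTTGGAATGAAA", q = "CTCGGGGTGAAA"), sp, region = "g")
  cnt <- count_gene_substitutions(aln, "r", "q")
  expect_identical(c(cnt$syn_count, cnt$nonsyn_count), c(2L, 1L))
  expect_equal(cnt$omega, 0.5)
  # codons with N are skipped; trailing partial codon trimmed
  aln <- make_aln(c(r = "CTTNGAATGAA", q = "CTCNGGGTGAA"), sp, region = "g")
  expect_warning(cnt <- count_gene_substitutions(aln, "r", "q"), NA)
  expect_identical(c(cnt$syn_count, cnt$nonsyn_count), c(1L, 1L))
  expect_error(count_gene_substitutions(aln, "r", "missing"), "missing")
})

test_that("each mismatching classifiable site is counted exactly once", {
  set.seed(61)
  sp <- c(r = "ref_sp", q = "qry_sp")
  for (k in 1:20) {
    r <- random_cds(30L)
    qv <- seq_chars(r)
    idx <- sample(3:(length(qv) - 3L), 6L)
    for (i in idx) qv[i] <- sample(setdiff(c("A", "C", "G", "T"), qv[i]), 1L)
    q <- chars_seq(qv)
    aln <- make_aln(c(r = r, q = q), sp, region = "g")
    cnt <- count_gene_substitutions(aln, "r", "q")
    rv <- seq_chars(r)
    Luse <- length(rv) - length(rv) %% 3L
    mism <- sum(rv[1:Luse] != qv[1:Luse])
    expect_identical(cnt$syn_count + cnt$nonsyn_count, mism)
  }
})

test_that("cross-species averages are plain arithmetic means", {
  counts <- data.frame(
    gene = rep(c("ND5", "ATP8"), each = 3L),
    species = rep(c("a", "b", "c"), 2L),
    syn_count = c(224L, 118L, 7L, 11L, 9L, 0L),
    nonsyn_count = c(30L, 24L, 1L, 2L, 3L, 0L),
    omega = c(0.13, 0.20, 0.14, 0.18, 0.33, 0))
  avg <- substitution_rate_summary(counts)
  expect_equal(avg$mean_syn[avg$gene == "ND5"], 116.33, tolerance = 5e-3)
  expect_equal(avg$mean_syn[avg$gene == "ATP8"], 6.67, tolerance = 5e-3)
  expect_equal(avg$mean_nonsyn[avg$gene == "ND5"], 18.33, tolerance = 5e-3)
  # single species: averages equal that species' counts
  one <- substitution_rate_summary(counts[counts$species == "a", ])
  expect_equal(one$mean_syn, c(224, 11))
})

test_that("amino-acid spectrum applies the outgroup anchor and exclusions", {
  sp <- c(o = "outg", a1 = "spA", a2 = "spA", b1 = "spB", c1 = "spC")
  # column 1: outgroup V, every ingroup sample I at 100% -> excluded
  # column 2: outgroup V, three I and one retained V -> 3 forward V->I and
  #           1 reverse I->V
  m <- rbind(o  = c("V", "V", "L"),
             a1 = c("I", "I", "L"),
             a2 = c("I", "I", "L"),
             b1 = c("I", "I", "L"),
             c1 = c("I", "V", "L"))
  spec <- amino_acid_change_spectrum(list(g = m), "o", sp)
  ch <- spec$changes
  expect_true(all(ch$position == 2L))
  expect_identical(sum(ch$count[ch$direction == "forward"]), 3L)
  expect_identical(sum(ch$count[ch$direction == "reverse"]), 1L)
  imb <- spec$pair_imbalance
  expect_identical(imb$pair, "I<->V")
  expect_equal(c(imb$forward, imb$reverse, imb$imbalance), c(3, 1, 2))
  expect_error(amino_acid_change_spectrum(list(g = m), "zz", sp), "outgroup")
  # no varying residues -> empty result
  flat <- rbind(o = c("L", "M"), a1 = c("L", "M"), b1 = c("L", "M"))
  expect_null(amino_acid_change_spectrum(list(g = flat), "o", sp)$changes)
})

test_that("translated alignments feed the spectrum end to end", {
  sim <- mini_sim()
  kinds <- stats::setNames(sim$records[[1L]]$features$kind,
                           sim$records[[1L]]$features$name)
  cds <- names(sim$gene_alns)[kinds[names(sim$gene_alns)] %in% "CDS"]
  prot <- lapply(sim$gene_alns[cds[1:3]], translate_alignment)
  og <- names(sim$species_of)[sim$species_of == "Oncorhynchus_keta"][1L]
  spec <- amino_acid_change_spectrum(prot, og, sim$species_of)
  expect_true(is.null(spec$changes) || all(spec$changes$from != spec$changes$to))
})
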