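test_that("column classification emits SNPs, indels and mixed calls", {
  sp <- c(s1 = "sp1", s2 = "sp1", s3 = "sp2")
  aln <- make_aln(c(s1 = "AAAAA", s2 = "AAGA-", s3 = "AAGTA"), sp)
  calls <- call_variants(aln)
  kinds <- vapply(calls, `[[`, character(1L), "kind")
  cols <- vapply(calls, `[[`, integer(1L), "column")
  expect_identical(cols[kinds == "SNP"], c(3L, 4L))
  expect_identical(cols[kinds == "indel"], 5L)
  # no call on monomorphic or N-masked columns
  aln2 <- make_aln(c(s1 = "AN", s2 = "AN", s3 = "AA"), sp)
  expect_length(call_variants(aln2), 0L)
  # a column with gaps AND base variation yields one indel and one SNP call
  aln3 <- make_aln(c(s1 = "A", s2 = "-", s3 = "G"), sp)
  expect_identical(sort(vapply(call_variants(aln3), `[[`, character(1L), "kind")),
                   c("SNP", "indel"))
  expect_error(call_variants(make_aln(c(s1 = "ACGT"), sp[1L])), ">= 2 rows")
})

test_that("scope classification handles the canonical three-species cases", {
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  cl <- function(al) {
    unlist(classify_scope(list(alleles = stats::setNames(al, names(sp))),
                          sp)[c("scope", "inter_type")])
  }
  # fixed difference between two groups -> type iii
  expect_identical(unname(cl(c("A", "A", "A", "A", "G", "G"))),
                   c("inter", "iii"))
  # segregating in two species, fixed in the third -> type i
  expect_identical(unname(cl(c("A", "G", "A", "G", "A", "A"))),
                   c("inter", "i"))
  # variation confined to one species -> intra
  expect_identical(unname(cl(c("A", "G", "A", "A", "A", "A"))),
                   c("intra", "none"))
  # same polymorphism in every species -> type ii
  expect_identical(unname(cl(c("A", "G", "A", "G", "A", "G"))),
                   c("inter", "ii"))
  # one species segregates, the others fixed for different alleles -> i
  expect_identical(unname(cl(c("A", "G", "A", "A", "G", "G"))),
                   c("inter", "i"))
})

test_that("classification is invariant to row order and label swaps", {
  set.seed(41)
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  for (k in 1:50) {
    al <- stats::setNames(sample(c("A", "G"), 6L, replace = TRUE), names(sp))
    base <- classify_scope(list(alleles = al), sp)
    perm <- sample(names(sp))
    again <- classify_scope(list(alleles = al[perm]), sp[perm])
    expect_identical(base$scope, again$scope)
    expect_identical(base$inter_type, again$inter_type)
    # relabeling species permutes nothing structural
    relab <- stats::setNames(c(A = "X", B = "Y", C = "Z")[sp], names(sp))
    swapped <- classify_scope(list(alleles = al), relab)
    expect_identical(base$inter_type, swapped$inter_type)
  }
})

test_that("summaries count planted columns and partition totals", {
  sp <- c(a1 = "spA", a2 = "spA", b1 = "spB", b2 = "spB", c1 = "spC", c2 = "spC")
  base <- strrep("A", 40L)
  rows <- stats::setNames(rep(base, 6L), names(sp))
  poke <- function(rows, col, alleles) {
    for (i in seq_along(rows)) substr(rows[i], col, col) <- alleles[i]
    rows
  }
  # 5 intra columns in spA, 2 type-iii columns
  for (col in 1:5) rows <- poke(rows, col, c("G", "A", "A", "A", "A", "A"))
  for (col in 6:7) rows <- poke(rows, col, c("A", "A", "G", "G", "A", "A"))
  aln <- make_aln(rows, sp)
  sm <- variant_summary(call_variants(aln), sp)
  expect_identical(unname(sm$intra_by_species["spA"]), 5)
  expect_identical(unname(sm$intra_by_species["spB"]), 0)
  expect_identical(unname(sm$inter_by_type[["iii"]]), 2)
  expect_identical(sm$totals$snps, 7L)
  expect_equal(sm$totals$intra + sm$totals$inter, sm$totals$calls)
  # pairwise fixed differences: spB differs from both others at cols 6-7
  expect_equal(unname(sm$pairwise_fixed[["spA|spB"]]), 2)
  expect_equal(unname(sm$pairwise_fixed[["spA|spC"]]), 0)
  # empty call list -> zeros
  sm0 <- variant_summary(list(), sp)
  expect_identical(sm0$totals$calls, 0L)
  expect_true(all(sm0$intra_by_species == 0))
})

test_that("region projection and VCF export use reference coordinates", {
  sp <- c(r = "spR", q = "spQ", u = "spU")
  rec <- mitogenome_record("r", "spR", "AAACCCGGG", circular = FALSE,
    features = data.frame(name = c("g1", "g2"), kind = "CDS",
                          start = c(1L, 7L), end = c(3L, 9L), strand = "+",
                          codon_start = 1L, pseudo = FALSE))
  aln <- make_aln(c(r = "AAA-CCCGGG", q = "AAATCCCGGG", u = "AGA-CCCGGA"), sp)
  regions <- column_regions(aln, rec, "r")
  expect_identical(regions[1:3], rep("g1", 3L))
  expect_true(is.na(regions[4L]))   # reference gap column
  expect_identical(regions[5:7], rep("IGS", 3L))
  calls <- call_variants(aln)
  tab <- classify_variants(calls, sp, regions)
  expect_identical(tab$region[tab$column == 2L], "g1")
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, aln, "r", p)
  lines <- readLines(p)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 2L)  # columns 2 and 10; gap col 4 skipped
  expect_identical(strsplit(body[1L], "\t")[[1L]][c(2L, 4L, 5L)],
                   c("2", "A", "G"))
})

test_that("simulated CDS alignments carry no indels", {
  sim <- mini_sim()
  kinds <- stats::setNames(sim$records[[1L]]$features$kind,
                           sim$records[[1L]]$features$name)
  for (g in names(sim$gene_alns)) {
    if (identical(unname(kinds[g]), "CDS")) {
      expect_false(any(sim$gene_alns[[g]]$seqs == "-"),
                   label = sprintf("gaps in CDS alignment %s", g))
    }
  }
})
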