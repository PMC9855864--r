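test_that("distance models: identity, p, JC69 correction and saturation", {
  expect_equal(pairwise_distance("ACGT", "ACGT", "p"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", "JC69"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", "K2P"), 0)
  expect_equal(pairwise_distance("ACGTACGTAC", "GCGTACGTAC", "p"), 0.1)
  # p = 0.3 -> JC69 = 0.383119...
  s1 <- strrep("A", 10L)
  s2 <- paste0(strrep("C", 3L), strrep("A", 7L))
  expect_equal(pairwise_distance(s1, s2, "JC69"), -0.75 * log(1 - 0.4),
               tolerance = 1e-9)
  # saturation: p >= 0.75 undefined
  expect_true(is.na(pairwise_distance("AAAA", "CCCC", "JC69")))
  # gap/N sites dropped in either sequence
  expect_equal(pairwise_distance("AC-TN", "ACGTA", "p"), 0)
  # JC69 >= p on (0, 0.75)
  for (p in seq(0.05, 0.7, by = 0.05)) {
    n1 <- strrep("A", 100L)
    n2 <- paste0(strrep("G", round(100 * p)), strrep("A", 100L - round(100 * p)))
    expect_gte(pairwise_distance(n1, n2, "JC69"),
               pairwise_distance(n1, n2, "p"))
  }
})

test_that("distance matrices agree with ape::dist.dna", {
  set.seed(71)
  base <- rand_bases_for_test(300L)
  seqs <- vapply(1:5, function(i) {
    x <- base
    idx <- sample(300L, 25L)
    x[idx] <- sample(c("A", "C", "G", "T"), 25L, replace = TRUE)
    paste(x, collapse = "")
  }, character(1L))
  aln <- make_aln(seqs)
  bin <- ape::as.DNAbin(aln$seqs)
  for (mod in c("p", "JC69", "K2P")) {
    D <- distance_matrix(aln, mod)
    ape_mod <- c(p = "raw", JC69 = "JC69", K2P = "K80")[[mod]]
    ref <- as.matrix(ape::dist.dna(bin, model = ape_mod))
    expect_equal(D, ref[rownames(D), colnames(D)],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3 taxa")
  D[1, 2] <- D[2, 1] <- NA
  expect_error(neighbor_joining(D), "missing")
})

test_that("an additive four-taxon matrix is recovered exactly", {
  # hand-drawn tree: ((a:1,b:2):1,(c:3,d:1):2)
  true <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  D <- ape::cophenetic.phylo(true)
  est <- neighbor_joining(D[c("a", "b", "c", "d"), c("a", "b", "c", "d")])
  expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # tie on an ultrametric star: deterministic across runs
  S <- matrix(1, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(S) <- 0
  expect_identical(ape::write.tree(neighbor_joining(S)),
                   ape::write.tree(neighbor_joining(S)))
})

test_that("negative NJ branches are clamped to zero", {
  # near-degenerate matrix known to produce a negative internal branch
  D <- matrix(c(0, 2, 2.1, 2.1,
                2, 0, 2.1, 2.1,
                2.1, 2.1, 0, 0.2,
                2.1, 2.1, 0.2, 0), 4L,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is seeded, bounded and high for clean splits", {
  # 4 taxa, every column a clean synapomorphy for (a,b)|(c,d)
  block <- function(x, n) strrep(x, n)
  seqs <- c(a = paste0(block("A", 100L)),
            b = paste0(block("A", 100L)),
            c = paste0(block("G", 100L)),
            d = paste0(block("G", 100L)))
  aln <- make_aln(seqs)
  bs <- bootstrap_support(aln, model = "p", n_reps = 100L, seed = 9L)
  support <- mean(vapply(bs$trees, has_split, logical(1L), c("a", "b"))) * 100
  expect_gte(support, 99)
  bs2 <- bootstrap_support(aln, model = "p", n_reps = 100L, seed = 9L)
  expect_identical(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))
  # identical sequences: no resolved split gets support
  flat <- make_aln(stats::setNames(rep(strrep("ACGT", 25L), 4L),
                                   letters[1:4]))
  bsf <- bootstrap_support(flat, model = "p", n_reps = 20L, seed = 1L)
  expect_true(all(bsf$tree$edge.length < 1e-9))
})

test_that("newick round-trips and rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,(C:1,D:1):0.5);", p)
  tr <- read_newick(p)
  write_newick(tr, p)
  tr2 <- read_newick(p)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_true(has_split(tr, c("C", "D")))
  expect_true(has_split(tr, c("A", "B")))  # complement of the same split
  writeLines("(A:1,B:1,(C:1,D:1:0.5);", p)
  expect_error(suppressWarnings(read_newick(p)))
  # PHYLIP export is readable square format
  D <- matrix(c(0, 1, 1, 0), 2L, dimnames = list(c("x", "y"), c("x", "y")))
  pd <- withr::local_tempfile()
  write_phylip_dist(D, pd)
  expect_match(readLines(pd)[1L], "^\\s+2$")
})
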