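test_that("basic arrays, primitivity and canonical units", {
  h <- find_tandem_repeats("TATATATA")
  expect_identical(nrow(h), 1L)
  expect_identical(h$unit, "TA")
  expect_equal(h$copies, 4)
  expect_identical(h$array_len, 8L)

  h <- find_tandem_repeats("CCCGCCCGCCCG")
  expect_identical(h$unit, "CCCG")   # primitive unit, not CC
  expect_equal(h$copies, 3)
  expect_identical(h$array_len, 12L)
  expect_identical(h$canonical, "CCCG")  # smallest rotation
  expect_identical(find_tandem_repeats("TATATATA")$canonical, "AT")

  # homopolymers have a 1-bp primitive unit and are never reported
  expect_identical(nrow(find_tandem_repeats("AAAAAAAAAA")), 0L)
  # arrays split at N
  expect_identical(nrow(find_tandem_repeats("TATANTATA")), 0L)
  expect_error(find_tandem_repeats("ACGT", unit_min = 1L), "unit range")
})

test_that("a planted array is recovered exactly at its coordinates", {
  set.seed(21)
  bg <- screened <- NULL
  repeat {
    bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
    if (nrow(find_tandem_repeats(bg)) == 0L) break
  }
  planted <- strrep("AATAC", 5L)
  seq <- paste0(substr(bg, 1, 400), planted, substr(bg, 401, 1000))
  hits <- find_tandem_repeats(seq)
  oracle <- brute_force_repeats(seq)
  expect_identical(hits$start, oracle$start)
  expect_identical(hits$unit, oracle$unit)
  any_planted <- hits$unit == "AATAC" & hits$start == 401L & hits$copies == 5
  expect_true(any(any_planted))
})

test_that("reverse-complementing maps hits to mirrored coordinates", {
  set.seed(22)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    h <- find_tandem_repeats(s, min_len = 6L)
    hr <- find_tandem_repeats(reverse_complement(s), min_len = 6L)
    expect_identical(nrow(h), nrow(hr))
    if (nrow(h)) {
      L <- nchar(s)
      mirrored <- data.frame(start = L - h$end + 1L, end = L - h$start + 1L)
      mirrored <- mirrored[order(mirrored$start), ]
      expect_identical(hr$start, mirrored$start)
      expect_identical(hr$end, mirrored$end)
    }
  }
})

test_that("location labels follow the majority rule and derived spacers", {
  seq <- paste0(strrep("AC", 20L),            # 1..40   trnN
                "CATCATCATCAT",               # 41..52  IGS with planted array
                strrep("GACT", 10L),          # 53..92  trnC
                "TATATATATA", strrep("GGAC", 5L))  # 93..102 in D-loop
  rec <- mitogenome_record("s", "sp", seq, circular = FALSE,
    features = data.frame(
      name = c("trnN", "trnC", "D-loop"),
      kind = c("tRNA", "tRNA", "control_region"),
      start = c(1L, 53L, 93L), end = c(40L, 92L, 122L),
      strand = c("-", "-", "+"), codon_start = NA_integer_, pseudo = FALSE))
  hits <- locate_repeats(find_tandem_repeats(rec$sequence), rec)
  expect_identical(hits$location[hits$unit == "CAT"], "trnN-trnC")
  expect_identical(hits$location_kind[hits$unit == "CAT"], "IGS")
  expect_identical(hits$location[hits$unit == "TA"], "D-loop")
  # 60/40 straddle goes to the feature
  seq2 <- paste0(strrep("AC", 20L), "GATTGATTGATTGATT", strrep("TG", 20L))
  rec2 <- mitogenome_record("s", "sp", seq2, circular = FALSE,
    features = data.frame(name = "g", kind = "CDS", start = 1L, end = 50L,
                          strand = "+", codon_start = 1L, pseudo = FALSE))
  h2 <- locate_repeats(find_tandem_repeats(rec2$sequence), rec2)
  expect_identical(h2$location[h2$unit == "GATT"], "g")
})

test_that("class summary percentages total 100 and split by pseudogene", {
  hits <- data.frame(
    unit = c("TA", "CAA", "CCCG"), unit_len = c(2L, 3L, 4L),
    copies = c(6, 5, 5), location = c("D-loop", "trnS2", "trnN-trnC"),
    location_kind = c("control_region", "pseudogene", "IGS"))
  sm <- repeat_class_summary(list(a = hits, b = hits))
  expect_equal(sum(sm$classes$percentage), 100, tolerance = 0.02)
  expect_equal(sm$classes$abundance[sm$classes$unit_len == 2L], 12)
  expect_equal(sm$location_split$percentage[1L], 100 * 10 / 32)
  # single class = 100%
  one <- repeat_class_summary(hits[1L, ])
  expect_equal(one$classes$percentage, 100)
})

test_that("cross-sample polymorphism flags unit and copy variation", {
  h <- function(unit, copies, loc = "D-loop",
                kind = "control_region") {
    data.frame(unit = unit, canonical = vapply(unit, function(u) {
      r <- vapply(seq_len(nchar(u)), function(i) {
        paste0(substr(u, i, nchar(u)), substr(u, 1L, i - 1L))
      }, character(1L))
      min(r)
    }, character(1L), USE.NAMES = FALSE),
    unit_len = nchar(unit), copies = copies,
    start = 10L, end = 10L + nchar(unit) * copies - 1L,
    array_len = nchar(unit) * copies,
    location = loc, location_kind = kind, stringsAsFactors = FALSE)
  }
  species <- c(a1 = "sp1", a2 = "sp1", b1 = "sp2", c1 = "sp3")
  # unit polymorphism between species (AATAC vs AATGC)
  hs <- list(a1 = h("AATAC", 5), a2 = h("AATAC", 5),
             b1 = h("AATGC", 5), c1 = h("AATAC", 5))
  out <- polymorphic_repeats(hs, species)
  expect_identical(out$scope, "inter-specific")
  expect_true(out$unit_polymorphic)
  # copy-number polymorphism within one species
  hs2 <- list(a1 = h("TA", 4), a2 = h("TA", 6),
              b1 = h("TA", 5), c1 = h("TA", 5))
  out2 <- polymorphic_repeats(hs2, species)
  expect_true(out2$copy_polymorphic)
  expect_identical(out2$scope, "shared")  # varies within sp1 and between
  hs3 <- list(a1 = h("TA", 4), a2 = h("TA", 6),
              b1 = h("TA", 4), c1 = h("TA", 6))
  # identical arrays everywhere: no rows
  hs4 <- list(a1 = h("TA", 5), a2 = h("TA", 5),
              b1 = h("TA", 5), c1 = h("TA", 5))
  expect_null(polymorphic_repeats(hs4, species))
})
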