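# Independent oracles used to validate the package implementations.

# Brute-force tandem-repeat enumerator: walks every (start, unit length)
# pair, extends the periodic run base by base, then applies the documented
# shortest-unit collapse. Independent of the rle/shift detector.
brute_force_repeats <- function(seq, unit_min = 2L, unit_max = 15L,
                                min_len = 8L, min_copies = 2) {
  x <- strsplit(seq, "")[[1L]]
  L <- length(x)
  cand <- NULL
  for (u in unit_min:unit_max) {
    if (2L * u > L) break
    for (s in seq_len(L - 2L * u + 1L)) {
      # left-maximal: no periodic extension into s-1
      if (s > 1L && x[s - 1L] != "N" && x[s - 1L] == x[s - 1L + u]) next
      unit <- paste(x[s:(s + u - 1L)], collapse = "")
      if (grepl("N", unit, fixed = TRUE)) next
      e <- s + u - 1L
      while (e + 1L <= L && x[e + 1L] != "N" && x[e + 1L] == x[e + 1L - u]) {
        e <- e + 1L
      }
      alen <- e - s + 1L
      if (alen < min_len || alen / u < min_copies) next
      prim <- TRUE
      for (d in seq_len(u %/% 2L)) {
        if (u %% d == 0L &&
            unit == strrep(substr(unit, 1L, d), u %/% d)) { prim <- FALSE; break }
      }
      if (!prim) next
      cand <- rbind(cand, data.frame(unit = unit, unit_len = u,
                                     copies = alen / u, start = s, end = e,
                                     array_len = alen,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) {
    return(data.frame(unit = character(), unit_len = integer(),
                      copies = numeric(), start = integer(), end = integer(),
                      array_len = integer(), stringsAsFactors = FALSE))
  }
  cand <- unique(cand)
  cand <- cand[order(cand$unit_len, -cand$array_len, cand$start), ]
  kept <- NULL
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    if (!is.null(kept)) {
      for (j in seq_len(nrow(kept))) {
        if (cand$start[i] <= kept$end[j] && cand$end[i] >= kept$start[j]) {
          clash <- TRUE; break
        }
      }
    }
    if (!clash) kept <- rbind(kept, cand[i, ])
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}

# Step-by-step Tajima's D evaluation (gap/N-free alignments).
tajima_oracle <- function(mat) {
  n <- nrow(mat)
  S <- sum(apply(mat, 2L, function(cl) length(unique(cl)) >= 2L))
  if (S == 0L || n < 4L) return(NA_real_)
  pairs <- utils::combn(n, 2L)
  kbar <- mean(apply(pairs, 2L, function(p) sum(mat[p[1L], ] != mat[p[2L], ])))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Direct decision rules for the SNP scope/type classification applied to
# per-species states "AA" (fixed A), "GG" (fixed G), "AG" (segregating).
scope_oracle <- function(states) {
  poly <- states == "AG"
  fixedA <- states == "AA"
  fixedG <- states == "GG"
  if (all(fixedA) || all(fixedG)) return(c(NA_character_, "none"))
  if (sum(poly) == 1L && (sum(fixedA) == 0L || sum(fixedG) == 0L)) {
    return(c("intra", "none"))
  }
  if (sum(poly) == 0L) return(c("inter", "iii"))
  if (all(poly)) return(c("inter", "ii"))
  c("inter", "i")
}

# quick alignment builder: unnamed sequences become s1..sn, one species per
# sample unless a species map is given
make_aln <- function(seqs, species = NULL, region = "test") {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (is.null(species)) {
    species <- stats::setNames(paste0("sp", seq_along(seqs)), names(seqs))
  }
  alignment_set(seqs, species, region = region)
}

# random gap/N-free alignment for oracle sweeps
random_aln <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  make_aln(stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m)))
}

# shared mini simulation, built once per test run
.fixtures <- new.env()
mini_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_mitogenomes(simulation_config(seed = 42L, scale = 0.1))
  }
  .fixtures$sim
}

rand_bases_for_test <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}
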