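#' Construct an annotated mitogenome record
#'
#' The central container for one circular (or linear) mitochondrial genome:
#' its sequence, topology and feature table. Coordinates are 1-based
#' inclusive; a feature whose \code{end} is smaller than its \code{start}
#' wraps the origin of a circular molecule.
#'
#' @param sample_id sample identifier.
#' @param species species label.
#' @param sequence DNA string over \{A,C,G,T,N\}.
#' @param circular logical; molecule topology.
#' @param features data.frame with columns \code{name}, \code{kind}
#'   (CDS, tRNA, rRNA, control_region, pseudogene, IGS), \code{start},
#'   \code{end}, \code{strand} ("+" heavy, "-" light), \code{codon_start}
#'   (1/2/3, NA outside CDS) and \code{pseudo} (logical).
#' @return An object of class \code{mitogenome}.
#' @export
mitogenome_record <- function(sample_id, species, sequence,
                              circular = TRUE, features = empty_features()) {
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence", call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "kind", "start", "end", "strand", "codon_start", "pseudo")
  miss <- setdiff(need, names(features))
  for (m in miss) {
    features[[m]] <- if (m == "pseudo") logical(nrow(features))
                     else if (m %in% c("start", "end", "codon_start")) NA_integer_
                     else NA_character_
  }
  features <- features[, need]
  if (nrow(features) > 0L) {
    bad <- features$start < 1L | features$start > L |
           features$end < 1L | features$end > L
    if (any(bad)) {
      stop(sprintf("feature(s) outside [1, %d]: %s", L,
                   paste(features$name[bad], collapse = ", ")), call. = FALSE)
    }
    if (!circular && any(features$end < features$start)) {
      stop("wrapped feature on a linear molecule", call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, species = species,
                 sequence = sequence, length = L, circular = circular,
                 features = features),
            class = "mitogenome")
}

empty_features <- function() {
  data.frame(name = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             codon_start = integer(), pseudo = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s): %d bp, %s, %d features\n",
              x$sample_id, x$species, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

# length of a feature, wrap-aware
feature_length <- function(feature, genome_length) {
  ifelse(feature$end >= feature$start,
         feature$end - feature$start + 1L,
         genome_length - feature$start + 1L + feature$end)
}

#' Extract a gene sequence from a mitogenome
#'
#' Returns the feature's sequence on its sense strand: light-strand ("-")
#' features are reverse-complemented, origin-wrapping features are spliced
#' (tail + head), so downstream code never handles circularity.
#'
#' @param record a [mitogenome_record()].
#' @param feature a feature name, a row index into \code{record$features},
#'   or a single-row feature data.frame.
#' @return DNA string.
#' @export
extract_gene <- function(record, feature) {
  f <- resolve_feature(record, feature)
  s <- if (f$end >= f$start) {
    substr(record$sequence, f$start, f$end)
  } else {
    if (!record$circular) stop("wrapped feature on linear record", call. = FALSE)
    paste0(substr(record$sequence, f$start, record$length),
           substr(record$sequence, 1L, f$end))
  }
  if (identical(f$strand, "-")) reverse_complement(s) else s
}

resolve_feature <- function(record, feature) {
  ft <- record$features
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    return(as.list(feature))
  }
  if (is.character(feature)) {
    i <- match(feature, ft$name)
    if (is.na(i)) stop(sprintf("no feature named '%s'", feature), call. = FALSE)
    return(as.list(ft[i, ]))
  }
  if (feature < 1L || feature > nrow(ft)) stop("feature index out of range", call. = FALSE)
  as.list(ft[feature, ])
}

#' Derive intergenic spacers between annotated features
#'
#' Finds the maximal unannotated spans between adjacent features of a
#' circular record and labels each "X-Y" after its flanking features.
#' Existing IGS rows are ignored when computing coverage.
#'
#' @param record a [mitogenome_record()].
#' @return Feature data.frame of the derived IGS intervals (strand "+").
#' @export
derive_igs <- function(record) {
  ft <- record$features[record$features$kind != "IGS", , drop = FALSE]
  L <- record$length
  out <- empty_features()
  if (nrow(ft) == 0L) return(out)
  covered <- logical(L)
  for (i in seq_len(nrow(ft))) {
    covered[feature_positions(ft$start[i], ft$end[i], L)] <- TRUE
  }
  if (all(covered)) return(out)
  # runs of uncovered positions on the circle
  runs <- uncovered_runs(covered, circular = record$circular)
  for (r in runs) {
    prev_pos <- if (r$start == 1L) L else r$start - 1L
    next_pos <- if (r$end == L) 1L else r$end + 1L
    left <- feature_at(ft, prev_pos, L)
    right <- feature_at(ft, next_pos, L)
    out <- rbind(out, data.frame(
      name = paste0(left, "-", right), kind = "IGS",
      start = r$start, end = r$end, strand = "+",
      codon_start = NA_integer_, pseudo = FALSE, stringsAsFactors = FALSE))
  }
  out
}

feature_positions <- function(start, end, L) {
  if (end >= start) start:end else c(start:L, 1:end)
}

feature_at <- function(ft, pos, L) {
  for (i in seq_len(nrow(ft))) {
    if (pos %in% feature_positions(ft$start[i], ft$end[i], L)) return(ft$name[i])
  }
  "origin"
}

uncovered_runs <- function(covered, circular) {
  L <- length(covered)
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(function(s, e) list(start = s, end = e),
              starts[r$values], ends[r$values])
  # merge a run touching position L with one starting at 1 on a circle
  if (circular && length(runs) >= 2L &&
      runs[[1L]]$start == 1L && runs[[length(runs)]]$end == L) {
    runs[[1L]]$start <- runs[[length(runs)]]$start  # wrapped run (end < start)
    runs[[length(runs)]] <- NULL
  }
  runs
}

## ---- GenBank flat-file I/O -------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses LOCUS (length, topology), the FEATURES table (CDS, tRNA, rRNA,
#' D-loop, gene, misc_feature) and ORIGIN into a [mitogenome_record()].
#' \code{complement()} and \code{join()} locations are supported;
#' an origin-spanning join on a circular molecule is stored as a single
#' wrapped feature. A CDS whose in-frame length has a trailing remainder
#' that cannot be an incomplete stop codon is retained with a warning.
#'
#' @param path file path.
#' @param sample_id,species optional labels; default to the LOCUS name.
#' @return A [mitogenome_record()].
#' @export
read_genbank <- function(path, sample_id = NULL, species = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed record: no LOCUS line", call. = FALSE)
  locus <- lines[[locus_i[1L]]]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]

  org_i <- grep("^\\s+ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^\\s+ORGANISM", "", lines[[org_i[1L]]])) else NA_character_

  seq <- parse_origin(lines)
  feats <- parse_feature_table(lines, seq, circular)

  mitogenome_record(
    sample_id = if (is.null(sample_id)) name else sample_id,
    species = if (is.null(species)) organism else species,
    sequence = seq, circular = circular, features = feats)
}

parse_origin <- function(lines) {
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("malformed record: no ORIGIN section", call. = FALSE)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > oi[1L]][1L] else length(lines) + 1L
  body <- lines[seq.int(oi[1L] + 1L, end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  if (nchar(seq) == 0L) stop("malformed record: empty sequence", call. = FALSE)
  seq
}

parse_feature_table <- function(lines, seq, circular) {
  L <- nchar(seq)
  fi <- grep("^FEATURES", lines)
  out <- empty_features()
  if (length(fi) == 0L) return(out)
  oi <- grep("^ORIGIN", lines)[1L]
  body <- lines[seq.int(fi[1L] + 1L, oi - 1L)]
  # group into features: a new feature starts with 5 spaces then a key
  starts <- grep("^ {5}\\S", body)
  if (length(starts) == 0L) return(out)
  bounds <- c(starts, length(body) + 1L)
  idx <- 0L
  for (k in seq_along(starts)) {
    chunk <- body[seq.int(bounds[k], bounds[k + 1L] - 1L)]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
    if (key == "source") next
    idx <- idx + 1L
    loc <- sub("^ {5}\\S+\\s*", "", chunk[1L])
    quali <- grep("^\\s{10,}/", chunk)
    # location may continue over lines before the first qualifier
    cont <- setdiff(seq_along(chunk)[-1L],
                    if (length(quali)) seq.int(min(quali), length(chunk)) else integer())
    if (length(cont)) loc <- paste0(loc, trimws(chunk[cont]))
    pl <- parse_location(loc, L, circular, line = chunk[1L])
    q <- parse_qualifiers(chunk[quali])
    nm <- q$gene %||% q$product %||% q$note %||% paste0(key, idx)
    kind <- switch(key,
      CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
      "D-loop" = "control_region", gene = "CDS",
      misc_feature = if (isTRUE(q$pseudo)) "pseudogene" else "IGS",
      "IGS")
    if (isTRUE(q$pseudo) && kind == "IGS") kind <- "pseudogene"
    cs <- if (kind == "CDS") as.integer(q$codon_start %||% 1L) else NA_integer_
    if (kind == "CDS") {
      flen <- feature_length(list(start = pl$start, end = pl$end), L)
      r <- (flen - (cs - 1L)) %% 3L
      if (r != 0L) {
        # a 1-2 base remainder is fine when it can be an incomplete stop
        # codon (T.., TA. completed by polyadenylation; mito stops TAA/TAG/
        # AGA/AGG); anything else is flagged but the feature is kept
        tail_seq <- cds_tail(seq, pl, r)
        if (!tail_seq %in% c("T", "TA", "A", "AG")) {
          warning(sprintf(
            "CDS '%s': in-frame length not divisible by 3 (trailing '%s')",
            nm, tail_seq), call. = FALSE)
        }
      }
    }
    out <- rbind(out, data.frame(
      name = nm, kind = kind, start = pl$start, end = pl$end,
      strand = pl$strand, codon_start = cs,
      pseudo = isTRUE(q$pseudo), stringsAsFactors = FALSE))
  }
  out
}

parse_location <- function(loc, L, circular, line) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    iv <- lapply(parts, parse_interval, line = line)
    if (length(iv) == 2L && circular && iv[[1L]]$end == L && iv[[2L]]$start == 1L) {
      return(list(start = iv[[1L]]$start, end = iv[[2L]]$end, strand = strand))
    }
    # contiguous join segments collapse to one interval
    for (k in seq_len(length(iv) - 1L)) {
      if (iv[[k + 1L]]$start != iv[[k]]$end + 1L) {
        stop(sprintf("unsupported discontiguous join in line: %s", line), call. = FALSE)
      }
    }
    return(list(start = iv[[1L]]$start, end = iv[[length(iv)]]$end, strand = strand))
  }
  iv <- parse_interval(loc, line = line)
  list(start = iv$start, end = iv$end, strand = strand)
}

# last r sense-strand bases of a (possibly wrapped/complemented) feature
cds_tail <- function(seq, pl, r) {
  L <- nchar(seq)
  s <- if (pl$end >= pl$start) {
    substr(seq, pl$start, pl$end)
  } else {
    paste0(substr(seq, pl$start, L), substr(seq, 1L, pl$end))
  }
  if (identical(pl$strand, "-")) {
    s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  substr(s, nchar(s) - r + 1L, nchar(s))
}

parse_interval <- function(x, line) {
  if (grepl("^\\d+\\.\\.\\d+$", x)) {
    p <- as.integer(strsplit(x, "..", fixed = TRUE)[[1L]])
    return(list(start = p[1L], end = p[2L]))
  }
  if (grepl("^\\d+$", x)) {
    p <- as.integer(x)
    return(list(start = p, end = p))
  }
  stop(sprintf("parse error in feature location '%s' (line: %s)", x, line),
       call. = FALSE)
}

parse_qualifiers <- function(qlines) {
  q <- list()
  for (ln in qlines) {
    ln <- trimws(ln)
    if (grepl("^/pseudo\\b", ln)) { q$pseudo <- TRUE; next }
    m <- regmatches(ln, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', ln))[[1L]]
    if (length(m) == 3L) q[[gsub("-", "_", m[2L])]] <- m[3L]
  }
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits LOCUS (with topology), a FEATURES table and ORIGIN. Kinds map to
#' GenBank keys (control_region to D-loop, IGS/pseudogene to misc_feature
#' with \code{/pseudo} for pseudogenes); wrapped features are written as
#' origin-spanning \code{join()} locations. Reading the file back with
#' [read_genbank()] reproduces sequence, topology and feature intervals.
#'
#' @param record a [mitogenome_record()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(record, path) {
  L <- record$length
  topo <- if (record$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s VRT",
                   gsub("\\s", "_", record$sample_id), L, topo),
           sprintf("DEFINITION  %s mitochondrion.", record$species),
           "  ORGANISM  " , "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  out[3L] <- sprintf("  ORGANISM  %s", record$species)
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    key <- switch(ft$kind[i],
      CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
      control_region = "D-loop", "misc_feature")
    loc <- if (ft$end[i] >= ft$start[i]) {
      sprintf("%d..%d", ft$start[i], ft$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", ft$start[i], L, ft$end[i])
    }
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf('                     /gene="%s"', ft$name[i]))
    if (!is.na(ft$codon_start[i])) {
      out <- c(out, sprintf("                     /codon_start=%d", ft$codon_start[i]))
    }
    if (isTRUE(ft$pseudo[i])) out <- c(out, "                     /pseudo")
  }
  out <- c(out, "ORIGIN")
  pos <- seq.int(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, L))
    blocks <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---- alignments ------------------------------------------------------------

#' Construct an alignment set
#'
#' Aligned sequences of equal length over \{A,C,G,T,N,-\} with a
#' sample-to-species map.
#'
#' @param seqs named character vector of aligned sequences, or a character
#'   matrix (rows = samples) of single bases.
#' @param species_of named character vector mapping sample id to species.
#' @param region region label (e.g. "whole-genome", a gene name, "D-loop").
#' @return Object of class \code{aln_set} with elements \code{seqs}
#'   (character matrix, one base per cell), \code{ids}, \code{species},
#'   \code{region}.
#' @export
alignment_set <- function(seqs, species_of, region = "region") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
    if (anyDuplicated(names(seqs))) {
      stop(sprintf("duplicate sequence id(s): %s",
                   paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")),
           call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("aligned sequences have unequal lengths", call. = FALSE)
    }
    m <- do.call(rbind, lapply(toupper(seqs), seq_chars))
  }
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop(sprintf("invalid alignment character(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  ids <- rownames(m)
  missing <- setdiff(ids, names(species_of))
  if (length(missing)) {
    stop(sprintf("sample id(s) missing from grouping: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(seqs = m, ids = ids,
                 species = species_of[ids], region = region),
            class = "aln_set")
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("<aln_set> %s: %d sequences x %d columns, %d species\n",
              x$region, nrow(x$seqs), ncol(x$seqs),
              length(unique(x$species))))
  invisible(x)
}

#' Read an aligned FASTA with a species grouping table
#'
#' @param path aligned FASTA file; all rows must be equal length.
#' @param grouping_tsv TSV with header \code{sample_id<TAB>species}, or a
#'   named character vector mapping sample id to species.
#' @param region region label for the alignment.
#' @return An [alignment_set()].
#' @export
read_aligned_fasta <- function(path, grouping_tsv, region = "whole-genome") {
  xs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(xs))) {
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(names(xs)[duplicated(names(xs))]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- as.character(xs)
  names(seqs) <- sub("\\s.*$", "", names(xs))
  species_of <- if (is.character(grouping_tsv) && length(grouping_tsv) == 1L &&
                    file.exists(grouping_tsv)) {
    read_grouping(grouping_tsv)
  } else grouping_tsv
  alignment_set(seqs, species_of, region = region)
}

#' Read a sample-to-species grouping TSV
#'
#' @param path TSV with header columns \code{sample_id} and \code{species}.
#' @return Named character vector (names = sample ids).
#' @export
read_grouping <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "species") %in% names(g))) {
    stop("grouping TSV must have columns sample_id and species", call. = FALSE)
  }
  stats::setNames(g$species, g$sample_id)
}

#' Write an alignment set (or named sequences) as FASTA
#'
#' @param x an [alignment_set()] or a named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "aln_set")) {
    stats::setNames(apply(x$seqs, 1L, paste, collapse = ""), x$ids)
  } else x
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

# subset an alignment to a column range or column index vector
aln_slice <- function(aln, cols, region = aln$region) {
  alignment_set(aln$seqs[, cols, drop = FALSE], aln$species, region = region)
}
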