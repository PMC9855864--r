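#' Find perfect tandem repeats
#'
#' Detects maximal perfect tandem arrays with primitive units of length
#' \code{unit_min}..\code{unit_max}. An array must reach \code{min_len}
#' bases and \code{min_copies} copies (the final copy may be partial, so
#' copy counts can be fractional). Overlapping detections are collapsed to
#' the representation with the shortest primitive unit (ties: longer array,
#' then leftmost start). Arrays never cross an N: the sequence is split at
#' N bases and segments scanned separately.
#'
#' The reported \code{unit} is the repeat unit as anchored at the array
#' start; \code{canonical} is its lexicographically smallest rotation
#' (useful for cross-sample comparison).
#'
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @param unit_min,unit_max unit length bounds (bp), defaults 2 and 15.
#' @param min_len minimum array length (bp), default 8.
#' @param min_copies minimum copy number, default 2.
#' @return data.frame of class \code{repeat_hits}: unit, canonical,
#'   unit_len, copies, start, end, array_len (1-based inclusive span).
#' @examples
#' find_tandem_repeats("CCCGCCCGCCCG")  # unit CCCG, 3 copies
#' @export
find_tandem_repeats <- function(seq, unit_min = 2L, unit_max = 15L,
                                min_len = 8L, min_copies = 2) {
  if (unit_min < 2L || unit_max < unit_min) {
    stop("invalid unit range: need 2 <= unit_min <= unit_max", call. = FALSE)
  }
  seq <- check_dna(seq)
  x <- seq_chars(seq)
  hits <- empty_hits()
  # split at N bases; scan each clean segment with its genomic offset
  segs <- clean_segments(x)
  for (sg in segs) {
    hits <- rbind(hits, scan_segment(x[sg$start:sg$end], sg$start - 1L,
                                     unit_min, unit_max, min_len, min_copies))
  }
  collapse_hits(hits)
}

empty_hits <- function() {
  structure(data.frame(unit = character(), canonical = character(),
                       unit_len = integer(), copies = numeric(),
                       start = integer(), end = integer(),
                       array_len = integer(), stringsAsFactors = FALSE),
            class = c("repeat_hits", "data.frame"))
}

clean_segments <- function(x) {
  ok <- x != "N"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) list(start = s, end = e),
      starts[r$values], ends[r$values])
}

scan_segment <- function(x, offset, unit_min, unit_max, min_len, min_copies) {
  L <- length(x)
  out <- empty_hits()
  u_max <- min(unit_max, L %/% 2L)
  if (u_max < unit_min) return(out)
  for (u in unit_min:u_max) {
    eq <- x[seq_len(L - u)] == x[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      alen <- r$lengths[k] + u               # run of matches at lag u
      if (alen < min_len || alen / u < min_copies) next
      s <- starts[k]
      unit <- chars_seq(x[s:(s + u - 1L)])
      if (!is_primitive(unit)) next
      out <- rbind(out, data.frame(
        unit = unit, canonical = canonical_rotation(unit),
        unit_len = u, copies = alen / u,
        start = s + offset, end = s + alen - 1L + offset,
        array_len = alen, stringsAsFactors = FALSE))
    }
  }
  out
}

# a unit is primitive if it is not a whole-number repetition of a shorter unit
is_primitive <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u %/% 2L)) {
    if (u %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

canonical_rotation <- function(unit) {
  u <- nchar(unit)
  rot <- vapply(seq_len(u), function(i) {
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L))
  }, character(1L))
  min(rot)
}

# shortest-unit precedence collapse of overlapping arrays
collapse_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(hits$unit_len, -hits$array_len, hits$start), ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- keep & hits$start <= hits$end[i] & hits$end >= hits$start[i]
    if (!any(ov)) keep[i] <- TRUE
  }
  out <- hits[keep, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  structure(out, class = c("repeat_hits", "data.frame"))
}

#' Assign a genomic location label to repeat hits
#'
#' A hit takes the name of the feature covering at least half of its array
#' (majority rule); otherwise, if it lies in an intergenic spacer, the label
#' is "X-Y" after the flanking features (spacers are derived with
#' [derive_igs()] when not annotated). Control-region and pseudogene
#' features contribute their own names (e.g. "D-loop").
#'
#' @param hits \code{repeat_hits} data.frame (coordinates on
#'   \code{record}'s sequence).
#' @param record a [mitogenome_record()].
#' @return \code{hits} with added columns \code{location} and
#'   \code{location_kind} (feature kind, or "IGS").
#' @export
locate_repeats <- function(hits, record) {
  ft <- record$features
  igs <- rbind(ft[ft$kind == "IGS", , drop = FALSE], derive_igs(record))
  L <- record$length
  hits$location <- "unassigned"
  hits$location_kind <- NA_character_
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] < 1L || hits$end[i] > L) {
      stop("repeat span outside record bounds", call. = FALSE)
    }
    span <- hits$start[i]:hits$end[i]
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nrow(ft))) {
      if (ft$kind[j] == "IGS") next
      ov <- length(intersect(span, feature_positions(ft$start[j], ft$end[j], L)))
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (!is.na(best_j) && best >= length(span) / 2) {
      hits$location[i] <- ft$name[best_j]
      hits$location_kind[i] <- ft$kind[best_j]
      next
    }
    for (j in seq_len(nrow(igs))) {
      ov <- length(intersect(span, feature_positions(igs$start[j], igs$end[j], L)))
      if (ov >= length(span) / 2) {
        hits$location[i] <- igs$name[j]
        hits$location_kind[i] <- "IGS"
        break
      }
    }
  }
  hits
}

#' Repeat-class abundance summary
#'
#' Aggregates hits from all samples into unit-length classes (dinucleotide
#' .. 15-nucleotide). Abundance is the total copy count over samples;
#' percentages are shares of the grand total. Also reports the coarse
#' location split pseudogene vs other when hits carry location kinds.
#'
#' @param hits_by_sample named list of located \code{repeat_hits}
#'   data.frames (one per sample), or a single data.frame.
#' @return list with \code{classes} (data.frame: class, unit_len,
#'   abundance, percentage) and \code{location_split} (data.frame:
#'   location, abundance, percentage; NULL without location kinds).
#' @export
repeat_class_summary <- function(hits_by_sample) {
  if (is.data.frame(hits_by_sample)) hits_by_sample <- list(hits_by_sample)
  all_hits <- do.call(rbind, lapply(hits_by_sample, function(h) {
    h[, intersect(names(h), c("unit", "unit_len", "copies", "location",
                              "location_kind")), drop = FALSE]
  }))
  if (is.null(all_hits) || nrow(all_hits) == 0L) stop("no repeat hits", call. = FALSE)
  grand <- sum(all_hits$copies)
  ab <- tapply(all_hits$copies, all_hits$unit_len, sum)
  classes <- data.frame(
    class = class_name(as.integer(names(ab))),
    unit_len = as.integer(names(ab)),
    abundance = as.numeric(ab),
    percentage = 100 * as.numeric(ab) / grand,
    stringsAsFactors = FALSE)
  loc <- NULL
  if ("location_kind" %in% names(all_hits) && !all(is.na(all_hits$location_kind))) {
    in_pseudo <- all_hits$location_kind %in% "pseudogene"
    loc <- data.frame(
      location = c("pseudogene", "other"),
      abundance = c(sum(all_hits$copies[in_pseudo]),
                    sum(all_hits$copies[!in_pseudo])),
      stringsAsFactors = FALSE)
    loc$percentage <- 100 * loc$abundance / grand
  }
  list(classes = classes, location_split = loc)
}

class_name <- function(unit_len) {
  nm <- c("2" = "dinucleotide", "3" = "trinucleotide", "4" = "tetranucleotide",
          "5" = "pentanucleotide", "6" = "hexanucleotide")
  out <- nm[as.character(unit_len)]
  out[is.na(out)] <- paste0(unit_len[is.na(out)], "-nucleotide")
  unname(out)
}

#' Cross-sample repeat polymorphism
#'
#' Matches repeat arrays at homologous loci across samples and flags
#' unit-sequence and copy-number polymorphism. Loci are matched by
#' projecting spans onto alignment columns when a whole-genome alignment
#' (and the per-sample records) are supplied; otherwise by location label
#' and unit length, with repeated loci within a label matched by rank.
#' Scope is intra-specific (variation within at least one species only),
#' inter-specific (species internally uniform but differing between), or
#' shared (both).
#'
#' @param hits_by_sample named list of located \code{repeat_hits}.
#' @param species_of named character vector sample id -> species.
#' @param aln optional whole-genome [alignment_set()] for column projection.
#' @param records optional named list of [mitogenome_record()] (needed with
#'   \code{aln}) to map sample coordinates to alignment columns.
#' @return data.frame: locus, location, unit_len, units (comma-joined
#'   variants), copy_min, copy_max, unit_polymorphic, copy_polymorphic,
#'   scope. Only polymorphic loci present in >= 2 samples are returned.
#' @export
polymorphic_repeats <- function(hits_by_sample, species_of,
                                aln = NULL, records = NULL) {
  samples <- names(hits_by_sample)
  if (length(samples) < 2L) stop("need hits from >= 2 samples", call. = FALSE)
  rows <- do.call(rbind, lapply(samples, function(sid) {
    h <- hits_by_sample[[sid]]
    if (nrow(h) == 0L) return(NULL)
    h$sample_id <- sid
    h
  }))
  if (is.null(rows)) return(NULL)
  if (!is.null(aln)) {
    stopifnot(!is.null(records))
    rows$col_start <- NA_integer_
    rows$col_end <- NA_integer_
    for (i in seq_len(nrow(rows))) {
      sid <- rows$sample_id[i]
      cols <- ungapped_to_column(aln, sid)
      rows$col_start[i] <- cols[rows$start[i]]
      rows$col_end[i] <- cols[rows$end[i]]
    }
    rows <- rows[order(rows$col_start), ]
    # chain-merge overlapping projected spans into loci
    locus <- integer(nrow(rows))
    cur <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(rows))) {
      if (rows$col_start[i] > cur_end) { cur <- cur + 1L; cur_end <- rows$col_end[i] }
      else cur_end <- max(cur_end, rows$col_end[i])
      locus[i] <- cur
    }
    rows$locus <- paste0("locus", locus)
  } else {
    rows <- rows[order(rows$sample_id, rows$location, rows$unit_len, rows$start), ]
    rank_in <- stats::ave(seq_len(nrow(rows)), rows$sample_id, rows$location,
                          rows$unit_len, FUN = seq_along)
    rows$locus <- paste0(rows$location, "/", rows$unit_len, "mer/", rank_in)
  }
  out <- NULL
  for (lc in unique(rows$locus)) {
    g <- rows[rows$locus == lc, ]
    if (length(unique(g$sample_id)) < 2L) next
    units <- sort(unique(g$canonical))
    unit_poly <- length(units) > 1L
    copy_poly <- length(unique(g$copies)) > 1L
    if (!unit_poly && !copy_poly) next
    sp <- species_of[g$sample_id]
    within <- any(vapply(split(g, sp), function(gg) {
      length(unique(gg$canonical)) > 1L || length(unique(gg$copies)) > 1L
    }, logical(1L)))
    rep_by_sp <- lapply(split(g, sp), function(gg) {
      paste(sort(unique(paste(gg$canonical, gg$copies))), collapse = ";")
    })
    between <- length(unique(unlist(rep_by_sp))) > 1L
    scope <- if (within && between) "shared"
             else if (within) "intra-specific" else "inter-specific"
    out <- rbind(out, data.frame(
      locus = lc, location = g$location[1L], unit_len = g$unit_len[1L],
      units = paste(sort(unique(g$unit)), collapse = ","),
      copy_min = min(g$copies), copy_max = max(g$copies),
      unit_polymorphic = unit_poly, copy_polymorphic = copy_poly,
      scope = scope, stringsAsFactors = FALSE))
  }
  out
}

# for sample sid, vector mapping ungapped position -> alignment column
ungapped_to_column <- function(aln, sid) {
  row <- aln$seqs[sid, ]
  which(row != "-")
}

#' Write a repeat table as TSV
#' @param hits located \code{repeat_hits} (optionally with sample column).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_repeats_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
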