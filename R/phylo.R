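#' Pairwise distance between two aligned sequences
#'
#' Sites with a gap or N in either sequence are dropped. Models: "p"
#' (mismatch proportion), "JC69" (-3/4 log(1 - 4p/3); undefined at
#' saturation p >= 3/4) and "K2P" (Kimura two-parameter from transition and
#' transversion proportions).
#'
#' @param s1,s2 equal-length aligned DNA strings (or base vectors).
#' @param model "p", "JC69" or "K2P".
#' @return numeric distance; NA when the correction is undefined.
#' @export
pairwise_distance <- function(s1, s2, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  x <- if (length(s1) == 1L) seq_chars(toupper(s1)) else toupper(s1)
  y <- if (length(s2) == 1L) seq_chars(toupper(s2)) else toupper(s2)
  stopifnot(length(x) == length(y))
  ok <- !(x %in% c("N", "-")) & !(y %in% c("N", "-"))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (model == "p") return(sum(x != y) / n)
  if (model == "JC69") {
    p <- sum(x != y) / n
    if (p >= 0.75) return(NA_real_)
    return(-0.75 * log(1 - 4 * p / 3))
  }
  # K2P: transitions A<->G, C<->T
  dif <- x != y
  pur <- c("A", "G")
  ts <- sum(dif & ((x %in% pur) == (y %in% pur)))
  P <- ts / n
  Q <- (sum(dif) - ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln an [alignment_set()].
#' @param model distance model, see [pairwise_distance()].
#' @return symmetric numeric matrix with taxon dimnames and attribute
#'   \code{"model"}.
#' @export
distance_matrix <- function(aln, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  n <- nrow(aln$seqs)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- pairwise_distance(aln$seqs[i, ], aln$seqs[j, ], model)
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \code{ape::nj}); negative branch lengths
#' are clamped to zero with the deficit moved to an adjacent branch of the
#' same node, preserving path lengths as far as possible.
#'
#' @param D symmetric distance matrix (>= 3 taxa, finite, NA-free).
#' @return an unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (any(is.na(D)) || any(!is.finite(D))) {
    stop("distance matrix contains missing or non-finite entries", call. = FALSE)
  }
  if (nrow(D) < 3L) stop("need >= 3 taxa", call. = FALSE)
  tree <- ape::nj(as.dist(D))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sib <- setdiff(which(tree$edge[, 1L] == tree$edge[e, 1L]), e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- max(0, tree$edge.length[sib[1L]] + deficit)
    }
  }
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the tree for each
#' replicate and reports, for every internal edge of the full-data tree,
#' the percentage of replicates containing the same bipartition. Fully
#' reproducible given \code{seed}.
#'
#' @param aln an [alignment_set()].
#' @param model distance model.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return list: \code{tree} (ape::phylo with node labels = support 0-100),
#'   \code{trees} (replicate trees), \code{n_reps} (replicates that
#'   produced a usable tree).
#' @export
bootstrap_support <- function(aln, model = "JC69", n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  base <- neighbor_joining(distance_matrix(aln, model))
  set.seed(seed)
  trees <- vector("list", n_reps)
  ok <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln$seqs), replace = TRUE)
    rep_aln <- aln_slice(aln, cols)
    tr <- tryCatch(neighbor_joining(distance_matrix(rep_aln, model)),
                   error = function(e) NULL)
    if (!is.null(tr)) { trees[[r]] <- tr; ok[r] <- TRUE }
  }
  trees <- trees[ok]
  cnt <- ape::prop.clades(base, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  base$node.label <- round(100 * cnt / length(trees), 1L)
  list(tree = base, trees = trees, n_reps = length(trees))
}

#' Does an unrooted tree contain a given bipartition?
#'
#' @param tree an \code{ape::phylo}.
#' @param tips character vector of tip labels on one side of the split.
#' @return logical.
#' @export
has_split <- function(tree, tips) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  if (anyNA(target)) stop("tip label(s) not in tree", call. = FALSE)
  comp <- sort(setdiff(seq_along(labs), target))
  any(vapply(parts, function(p) {
    identical(sort(p), target) || identical(sort(p), comp)
  }, logical(1L)))
}

#' Read / write newick trees
#'
#' Thin wrappers over \code{ape::read.tree} and \code{ape::write.tree};
#' bootstrap supports are serialised as internal node labels.
#'
#' @param path file path.
#' @return [read_newick()]: an \code{ape::phylo}.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick file", call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a PHYLIP square distance matrix
#'
#' @param D distance matrix from [distance_matrix()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste0(formatC(rownames(D)[i], width = -10L),
                      paste(sprintf("%.6f", D[i, ]), collapse = " "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
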