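# Dual phylogenies: single-copy supermatrix (distance + NJ with bootstrap)
# and presence/absence Manhattan tree, plus Robinson-Foulds comparison.
# Alignments are character matrices (rows = taxa, columns = positions).

#' Convert sequences to an alignment matrix
#'
#' @param seqs Named character vector or \code{XStringSet} of equal-length
#'   aligned sequences.
#' @return Character matrix, rows = taxa.
#' @export
alignmentMatrix <- function(seqs) {
  s <- as.character(seqs)
  if (length(unique(nchar(s))) != 1L) stop("aligned rows must share one length")
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(s)
  m
}

#' Concatenate single-copy family alignments into a supermatrix
#'
#' Every family must be single-copy over the same taxon set; rows are
#' matched by taxon name and columns appended.  Per-family column provenance
#' is kept in the \code{partition} attribute.
#'
#' @param alignments Named list of character matrices (rows named by taxon).
#' @param taxa Character vector of taxa expected in every family.
#' @return Character matrix supermatrix with a \code{partition} attribute
#'   (named integer vector of family lengths).
#' @export
concatenateSingleCopy <- function(alignments, taxa) {
  if (!length(alignments)) stop("no alignments to concatenate")
  mats <- lapply(seq_along(alignments), function(i) {
    m <- alignments[[i]]
    if (!all(taxa %in% rownames(m)))
      stop("family ", names(alignments)[i] %||% i, " is missing taxa: ",
           paste(setdiff(taxa, rownames(m)), collapse = ", "))
    m[taxa, , drop = FALSE]
  })
  out <- do.call(cbind, mats)
  rownames(out) <- taxa
  attr(out, "partition") <- setNames(vapply(mats, ncol, 0L),
                                     names(alignments))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter poorly supported alignment columns
#'
#' Removes columns whose gap fraction exceeds \code{max_gap_fraction} or
#' whose most frequent non-gap character falls below \code{min_conservation}
#' of the non-gap rows.
#'
#' @param alignment Character matrix.
#' @param max_gap_fraction Maximum tolerated fraction of gaps per column.
#' @param min_conservation Minimum majority-character fraction per column.
#' @return Filtered character matrix with attribute \code{removed} (count).
#' @export
filterColumns <- function(alignment, max_gap_fraction = 0.5,
                          min_conservation = 0.5) {
  nr <- nrow(alignment)
  keep <- vapply(seq_len(ncol(alignment)), function(j) {
    col <- alignment[, j]
    gaps <- col == "-"
    if (mean(gaps) > max_gap_fraction) return(FALSE)
    res <- col[!gaps]
    if (!length(res)) return(FALSE)
    max(table(res)) / length(res) >= min_conservation
  }, TRUE)
  if (!any(keep)) stop("all columns removed by filtering")
  out <- alignment[, keep, drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Pairwise distances from an alignment
#'
#' p-distance is the mismatch fraction over columns where neither sequence
#' is gapped; the Poisson correction is \code{-log(1 - p)}.
#'
#' @param alignment Character matrix (>= 2 taxa).
#' @param model Either \code{"p_distance"} or \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
alignmentDistance <- function(alignment, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  n <- nrow(alignment)
  if (n < 2) stop("need at least 2 taxa")
  taxa <- rownames(alignment)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- alignment[i, ]; b <- alignment[j, ]
    ok <- a != "-" & b != "-"
    p <- if (any(ok)) mean(a[ok] != b[ok]) else 0
    if (model == "poisson") {
      if (p >= 1) stop("saturated pair (p >= 1) under poisson correction")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbor joining (via \code{ape::nj}); negative
#' branch lengths arising from noisy distances are clamped to zero.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return Unrooted \code{phylo} tree.
#' @export
njTree <- function(dm) {
  if (nrow(dm) < 3) stop("need at least 3 taxa for neighbor joining")
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbor-joining alignment tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing its bipartition (stored in
#' \code{node.label}).
#'
#' @param alignment Character matrix.
#' @param model Distance model passed to [alignmentDistance()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return \code{phylo} tree with percentage supports in \code{node.label}.
#' @export
bootstrapSupport <- function(alignment, model = "poisson", n_reps = 100,
                             seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  base_tree <- njTree(alignmentDistance(alignment, model))
  reps <- .withSeed(seed, lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(alignment), replace = TRUE)
    njTree(alignmentDistance(alignment[, cols, drop = FALSE], model))
  }))
  counts <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base_tree$node.label <- round(100 * counts / n_reps, 1)
  base_tree
}

#' Gene-content tree from a presence/absence matrix
#'
#' Pairwise genome distance is the Manhattan distance between 0/1 family
#' profiles (the number of families present in one genome but not the
#' other); the tree is built by neighbor joining.
#'
#' @param matrix 0/1 matrix from [buildPresenceAbsence()].
#' @return Unrooted \code{phylo} tree over the genomes.
#' @export
manhattanTree <- function(matrix) {
  if (ncol(matrix) < 3) stop("need at least 3 genomes")
  d <- as.matrix(dist(t(matrix), method = "manhattan"))
  njTree(d)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the unrooted bipartition sets (via
#' \code{phangorn::RF.dist}); 0 means identical topologies.
#'
#' @param t1,t2 \code{phylo} trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
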