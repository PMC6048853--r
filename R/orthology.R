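# Orthologous family construction: m8 hit filtering, similarity graph with
# -log10(E) weights, Markov clustering, and core/accessory/specific calls.

.m8cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Load and filter a 12-column m8 similarity table
#'
#' Reads a tab-separated BLAST-style tabular file, keeps rows with E-value at
#' or below the cutoff, and drops self-hits (query equal to subject).
#'
#' @param path Path to the m8 TSV (no header).
#' @param evalue_cutoff Maximum E-value retained (default 1e-5).
#' @return data.frame with the 12 standard m8 columns.
#' @export
loadHits <- function(path, evalue_cutoff = 1e-5) {
  hits <- tryCatch(
    read.delim(path, header = FALSE, col.names = .m8cols,
               colClasses = c("character", "character", rep("numeric", 10)),
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse m8 table '", path, "': ",
                             conditionMessage(e)))
  if (!nrow(hits)) {
    warning("empty hit table: ", path)
    return(hits)
  }
  if (anyNA(hits$evalue) || anyNA(hits$bitscore)) {
    bad <- which(is.na(hits$evalue) | is.na(hits$bitscore))[1L]
    stop("malformed m8 row at line ", bad, " of ", path)
  }
  hits <- hits[hits$evalue <= evalue_cutoff & hits$query != hits$subject, ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build an undirected similarity graph from filtered hits
#'
#' Edge weight is \code{-log10(E)} capped at 200 (the cap stands in for
#' E = 0), averaged over the two reciprocal directions when both are present;
#' a pair seen in only one direction keeps that direction's weight.
#'
#' @param hits Filtered hit data.frame (from [loadHits()]).
#' @return list with \code{nodes} (character) and \code{edges} (data.frame
#'   from, to, weight).
#' @export
buildSimilarityGraph <- function(hits) {
  if (!nrow(hits)) return(list(nodes = character(), edges = data.frame(
    from = character(), to = character(), weight = numeric())))
  w <- ifelse(hits$evalue <= 0, 200, pmin(-log10(hits$evalue), 200))
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  key <- paste(a, b, sep = "\r")
  wm <- tapply(w, key, mean)
  ab <- strsplit(names(wm), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(ab, `[`, "", 1L),
                      to = vapply(ab, `[`, "", 2L),
                      weight = unname(wm), stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges)
}

#' Markov clustering of a weighted similarity graph
#'
#' Sparse implementation of the MCL iteration: self-loops (weight = the
#' node's maximum incident edge weight) are added, columns are normalized to
#' a stochastic matrix, then expansion (matrix power), inflation
#' (elementwise power and renormalization) and pruning alternate until the
#' largest column change drops below \code{convergence_tol}.  Clusters are
#' the connected components of the converged matrix.
#'
#' @param graph list(nodes, edges) from [buildSimilarityGraph()].
#' @param inflation Inflation exponent (> 1, default 1.5).
#' @param expansion Matrix-power expansion order (integer >= 2).
#' @param prune_threshold Entries below this are dropped each iteration.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param convergence_tol Largest permitted column change at convergence.
#' @return list of character vectors, each a cluster of gene ids; clusters
#'   partition the node set.
#' @export
mclCluster <- function(graph, inflation = 1.5, expansion = 2L,
                       prune_threshold = 1e-5, max_iter = 200L,
                       convergence_tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2L) stop("expansion must be >= 2")
  nodes <- graph$nodes
  if (!length(nodes)) stop("empty graph")
  n <- length(nodes)
  e <- graph$edges
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(e$weight, e$weight), dims = c(n, n))
  colMax <- function(m) {
    m <- methods::as(m, "CsparseMatrix")
    out <- numeric(n)
    if (length(m@x)) {
      grp <- rep.int(seq_len(n), diff(m@p))
      mx <- tapply(m@x, grp, max)
      out[as.integer(names(mx))] <- mx
    }
    out
  }
  loop <- colMax(M)
  loop[loop <= 0] <- 1
  M <- M + Matrix::Diagonal(n, loop)
  normalize <- function(m) {
    cs <- Matrix::colSums(m)
    cs[cs == 0] <- 1
    m %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Mexp <- methods::as(Mexp, "CsparseMatrix")
    Mexp@x <- Mexp@x^inflation
    Mexp@x[Mexp@x < prune_threshold] <- 0
    Mexp <- Matrix::drop0(Mexp)
    Mexp <- normalize(Mexp)
    delta <- max(abs(Mexp - M))
    M <- Mexp
    if (delta < convergence_tol) {
      sym <- (M + Matrix::t(M)) > 0
      g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                               diag = FALSE)
      comp <- igraph::components(g)$membership
      return(unname(split(nodes, comp)))
    }
  }
  stop("MCL did not converge within ", max_iter, " iterations")
}

#' Classify clusters into core, accessory and specific families
#'
#' A family present in every genome is core, in exactly one genome specific
#' (singleton), otherwise accessory.  Genes absent from every cluster become
#' their own specific singleton families.  A family is single-copy when it
#' spans all genomes with exactly one gene each.
#'
#' @param clusters list of gene-id vectors (from [mclCluster()]).
#' @param gene_genomes Named character: genome label per gene id, covering
#'   the full gene universe (unclustered genes included).
#' @param genomes Character vector of all genome ids; defaults to the
#'   distinct values of \code{gene_genomes}.
#' @return A \linkS4class{FamilySet}.
#' @export
classifyFamilies <- function(clusters, gene_genomes,
                             genomes = sort(unique(gene_genomes))) {
  clustered <- unlist(clusters, use.names = FALSE)
  if (anyNA(match(clustered, names(gene_genomes))))
    stop("cluster contains gene(s) with unknown genome")
  orphan <- setdiff(names(gene_genomes), clustered)
  all_clusters <- c(clusters, as.list(orphan))
  nfam <- length(all_clusters)
  fam_ids <- sprintf("FAM%05d", seq_len(nfam))
  sizes <- lengths(all_clusters)
  membership <- data.frame(
    family = rep(fam_ids, sizes),
    gene = unlist(all_clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  membership$genome <- unname(gene_genomes[membership$gene])
  membership <- membership[, c("family", "genome", "gene")]
  ngen <- length(genomes)
  n_genomes_fam <- vapply(split(membership$genome, membership$family),
                          function(g) length(unique(g)), 0L)[fam_ids]
  category <- ifelse(n_genomes_fam == ngen, "core",
                     ifelse(n_genomes_fam == 1L, "specific", "accessory"))
  single <- sizes == ngen & n_genomes_fam == ngen
  new("FamilySet", membership = membership,
      category = setNames(category, fam_ids),
      singleCopy = setNames(unname(single), fam_ids),
      genomes = genomes)
}

#' Construct a FamilySet directly from ground truth
#'
#' Convenience constructor turning a \linkS4class{PanTruth} membership table
#' into a classified \linkS4class{FamilySet} (used for truth-vs-pipeline
#' comparisons and to feed downstream stages without clustering).
#'
#' @param truth A \linkS4class{PanTruth}.
#' @param genomes All genome labels (defaults to those seen in the truth).
#' @return A \linkS4class{FamilySet}.
#' @export
familySetFromTruth <- function(truth,
                               genomes = sort(unique(familyMembership(truth)$genome))) {
  mem <- familyMembership(truth)
  clusters <- split(mem$gene, mem$family)
  classifyFamilies(unname(clusters), setNames(mem$genome, mem$gene), genomes)
}
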