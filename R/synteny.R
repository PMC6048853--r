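# Metal-reduction (mtr-omc) cluster profiling: locate homologs of the
# reference locus in each genome, read order/strand along the densest run,
# count copies, and compare profiles across genomes.

#' Reference metal-reduction cluster definition
#'
#' The seven-gene outer-membrane electron-conduit locus in its reference
#' order, with the adjacent ferrous-iron transport operon as flank labels.
#'
#' @param labels Ordered cluster gene labels.
#' @param flank Flanking operon labels.
#' @return list of class \code{referenceCluster}.
#' @export
referenceCluster <- function(labels = c("mtrD", "mtrE", "mtrF", "omcA",
                                        "mtrC", "mtrA", "mtrB"),
                             flank = c("feoA", "feoB")) {
  if (anyDuplicated(labels)) stop("cluster labels must be unique")
  structure(list(labels = labels, flank = flank), class = "referenceCluster")
}

#' Map reference cluster genes to orthologous families
#'
#' Each labelled gene of the reference genome is looked up in the family
#' set; the label inherits that family.  A reference gene in no family, or
#' two labels landing in one family (homology collision), is an error.
#'
#' @param families A \linkS4class{FamilySet}.
#' @param reference_members Named character: label -> gene id in the
#'   reference genome.
#' @return Named character: label -> family id.
#' @export
assignClusterHomologs <- function(families, reference_members) {
  mem <- familyMembership(families)
  fam <- mem$family[match(reference_members, mem$gene)]
  if (anyNA(fam))
    stop("reference gene(s) not in any family: ",
         paste(reference_members[is.na(fam)], collapse = ", "))
  if (anyDuplicated(fam)) {
    dup <- fam[duplicated(fam)][1L]
    stop("homology collision: labels ",
         paste(names(reference_members)[fam == dup], collapse = " and "),
         " map to family ", dup)
  }
  setNames(fam, names(reference_members))
}

#' Profile the cluster in one genome
#'
#' Cluster members are located by family membership, copy numbers counted
#' genome-wide, and the locus read along the contig run containing the most
#' cluster genes, tolerating up to \code{max_gap_genes} intervening
#' non-cluster genes between consecutive members.  A genome is
#' \code{complete} when all labels have at least one copy and all appear
#' within that single run.
#'
#' @param gene_table Coordinate data.frame for one genome (columns genome,
#'   gene, contig, start, end, strand).
#' @param label_families Named character label -> family (from
#'   [assignClusterHomologs()]).
#' @param gene_families Named character: family per gene id (covering at
#'   least the cluster genes present).
#' @param reference A [referenceCluster()].
#' @param max_gap_genes Tolerated intervening genes between members.
#' @return list of class \code{clusterProfile}: genome, copy_number (named
#'   integer per label), observed_order (data.frame label, strand), gaps,
#'   complete.
#' @export
profileGenome <- function(gene_table, label_families, gene_families,
                          reference = referenceCluster(),
                          max_gap_genes = 5L) {
  labels <- reference$labels
  fam2label <- setNames(names(label_families), label_families)
  gt <- gene_table[order(gene_table$contig, gene_table$start), , drop = FALSE]
  fam <- unname(gene_families[gt$gene])
  lab <- fam2label[fam]
  copy <- table(factor(lab[!is.na(lab)], levels = labels))
  copy <- setNames(as.integer(copy), labels)
  genome <- if (nrow(gt)) gt$genome[1L] else NA_character_
  hit_idx <- which(!is.na(lab))
  if (!length(hit_idx)) {
    return(structure(list(genome = genome, copy_number = copy,
                          observed_order = data.frame(label = character(),
                                                      strand = character()),
                          gaps = 0L, complete = FALSE),
                     class = "clusterProfile"))
  }
  # densest run: greedy chains of cluster genes on one contig with at most
  # max_gap_genes intervening non-cluster genes between consecutive members
  runs <- list(); cur <- hit_idx[1L]
  if (length(hit_idx) > 1L) for (k in 2L:length(hit_idx)) {
    i <- hit_idx[k]; prev <- cur[length(cur)]
    same_contig <- gt$contig[i] == gt$contig[prev]
    if (same_contig && (i - prev - 1L) <= max_gap_genes) cur <- c(cur, i)
    else { runs[[length(runs) + 1L]] <- cur; cur <- i }
  }
  runs[[length(runs) + 1L]] <- cur
  best <- runs[[which.max(lengths(runs))]]
  observed <- data.frame(label = unname(lab[best]),
                         strand = gt$strand[best],
                         stringsAsFactors = FALSE)
  gaps <- if (length(best) > 1L)
    sum(diff(best) - 1L) else 0L
  complete <- all(copy >= 1L) &&
    all(labels %in% observed$label) &&
    length(best) >= length(labels)
  structure(list(genome = genome, copy_number = copy,
                 observed_order = observed, gaps = as.integer(gaps),
                 complete = complete),
            class = "clusterProfile")
}

#' @export
print.clusterProfile <- function(x, ...) {
  cat("clusterProfile [", x$genome, "]: ",
      paste(x$observed_order$label, collapse = "-"),
      if (x$complete) " (complete)" else " (incomplete)", "\n", sep = "")
  invisible(x)
}

#' Compare cluster profiles across genomes
#'
#' Assembles the genomes x labels copy-number matrix and counts genomes
#' with a complete cluster, genomes retaining the mtrA-mtrB-mtrC
#' sub-operon (all three present), and genomes lacking the whole
#' mtrD-mtrE-mtrF sub-operon (all three absent).
#'
#' @param profiles list of [profileGenome()] results.
#' @param reference A [referenceCluster()].
#' @return list: copy_matrix, n_complete, n_with_mtrABC, n_lacking_mtrDEF,
#'   complete_genomes.
#' @export
compareProfiles <- function(profiles, reference = referenceCluster()) {
  if (!length(profiles)) stop("need at least one profile")
  labels <- reference$labels
  cm <- do.call(rbind, lapply(profiles, function(p) p$copy_number[labels]))
  rownames(cm) <- vapply(profiles, function(p) p$genome, "")
  complete <- vapply(profiles, function(p) isTRUE(p$complete), TRUE)
  abc <- c("mtrA", "mtrB", "mtrC")
  def <- c("mtrD", "mtrE", "mtrF")
  has_abc <- rowSums(cm[, abc, drop = FALSE] >= 1L) == 3L
  no_def <- rowSums(cm[, def, drop = FALSE]) == 0L
  list(copy_matrix = cm,
       n_complete = sum(complete),
       n_with_mtrABC = sum(has_abc),
       n_lacking_mtrDEF = sum(no_def),
       complete_genomes = unname(rownames(cm)[complete]))
}

#' Build a four-genome synteny benchmark with known truth
#'
#' Constructs coordinate tables and a family map for four synthetic genomes
#' exercising the canonical cluster fates: a complete cluster in reference
#' order, a genome lacking the mtrD-mtrE-mtrF sub-operon, a genome with a
#' duplicated omcA copy outside the locus, and a genome lacking the cluster
#' entirely.  Background genes pad each contig.
#'
#' @param n_background Background genes per genome.
#' @param seed RNG seed (strand assignment and padding).
#' @return list: \code{gene_tables} (per genome), \code{gene_families},
#'   \code{label_families}, \code{truth} (data.frame genome, complete,
#'   omcA_copies, lacks_mtrDEF).
#' @export
simulateClusterFixture <- function(n_background = 20L, seed = 1) {
  ref <- referenceCluster()
  labels <- ref$labels
  label_families <- setNames(paste0("FAM_", labels), labels)
  .withSeed(seed, {
    # layout: character vector of slots, cluster labels or "." (background)
    mk_genome <- function(genome, layout) {
      n_bg <- sum(layout == ".")
      bg_genes <- sprintf("%s|bg%03d", genome, seq_len(n_bg))
      bg_fams <- sprintf("BGF_%s_%03d", genome, seq_len(n_bg))
      genes <- character(length(layout)); fams <- character(length(layout))
      is_bg <- layout == "."
      genes[is_bg] <- bg_genes; fams[is_bg] <- bg_fams
      cl <- layout[!is_bg]
      dupn <- ave(cl, cl, FUN = seq_along)
      genes[!is_bg] <- sprintf("%s|%s_%s", genome, cl, dupn)
      fams[!is_bg] <- unname(label_families[cl])
      n <- length(genes)
      start <- (seq_len(n) - 1L) * 1100L
      tab <- data.frame(genome = genome, gene = genes,
                        contig = paste0(genome, "_c1"), start = start,
                        end = start + 900L,
                        strand = sample(c("+", "-"), n, TRUE),
                        stringsAsFactors = FALSE)
      list(table = tab, fams = setNames(fams, genes))
    }
    pad <- function(k) rep(".", k)
    # SYN1: complete cluster in reference order
    g1 <- mk_genome("SYN1", c(pad(6), labels, pad(n_background - 6L)))
    # SYN2: mtrDEF sub-operon lost
    g2 <- mk_genome("SYN2", c(pad(6), setdiff(labels, c("mtrD", "mtrE", "mtrF")),
                              pad(n_background - 6L)))
    # SYN3: omcA duplicated; the locus is split by an over-gap insertion so
    # the densest run (omcA-mtrC-mtrA-mtrB) lacks mtrDEF -> incomplete, and
    # the second omcA copy sits outside that run
    g3 <- mk_genome("SYN3", c(pad(2), "omcA", pad(7),
                              c("mtrD", "mtrE", "mtrF"), pad(7),
                              c("omcA", "mtrC", "mtrA", "mtrB"),
                              pad(n_background - 16L)))
    # SYN4: cluster absent
    g4 <- mk_genome("SYN4", pad(n_background))
    gl <- list(SYN1 = g1, SYN2 = g2, SYN3 = g3, SYN4 = g4)
    list(gene_tables = lapply(gl, `[[`, "table"),
         gene_families = do.call(c, unname(lapply(gl, `[[`, "fams"))),
         label_families = label_families,
         truth = data.frame(
           genome = names(gl),
           complete = c(TRUE, FALSE, FALSE, FALSE),
           omcA_copies = c(1L, 1L, 2L, 0L),
           lacks_mtrDEF = c(FALSE, TRUE, FALSE, TRUE)))
  })
}
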