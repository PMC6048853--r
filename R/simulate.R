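# Synthetic pan-genome generator: species tree, gene-content history,
# codon sequences under known dN/dS, and transfer implants, all seeded.

# Run expr under a temporary RNG state so generators never disturb the
# caller's stream and identical seeds give identical output.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

.genomeLabels <- function(n) sprintf("G%02d", seq_len(n))

#' Simulate an ultrametric species tree
#'
#' Draws a pure-birth (Yule) tree with the requested number of extant leaves,
#' relabelled \code{G01..Gnn}.  The tree is binary and ultrametric, so every
#' root-to-leaf path has the same length.
#'
#' @param n_genomes Number of leaves (>= 2).
#' @param birth_rate Speciation rate per unit time (> 0).
#' @param seed RNG seed.
#' @return An \code{ape::phylo} object with \code{n_genomes} leaves.
#' @examples
#' tr <- simulateSpeciesTree(6, 1, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulateSpeciesTree <- function(n_genomes, birth_rate = 1, seed = 1) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  tree <- .withSeed(seed, ape::rphylo(n_genomes, birth = birth_rate, death = 0))
  tree$tip.label <- .genomeLabels(n_genomes)
  tree
}

# Preorder edge indices (parent before child) for a phylo object.
.preorderEdges <- function(tree) {
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  ord
}

.nodeLabel <- function(tree, node) {
  n <- length(tree$tip.label)
  ifelse(node <= n, tree$tip.label[node], paste0("N", node))
}

#' Simulate gene-content history along a species tree
#'
#' Places a planted core set (present in every genome, exempt from loss),
#' root accessory families, and family gain events drawn from a Poisson
#' process with intensity \code{gain_rate} per unit branch length.  A family
#' present at a node survives each descending branch with probability
#' \code{exp(-loss_rate * t)}; gains on terminal branches create
#' strain-specific families.  Transfer implants (rate \code{hgt_rate} per
#' genome) appear as singleton families with a recorded donor taxon drawn
#' from Vibrio-dominated outgroups.
#'
#' @param tree Species tree from [simulateSpeciesTree()].
#' @param config A [PanSimConfig()].
#' @return A \linkS4class{PanTruth} with family membership, the per-branch
#'   event log, transfer donors and the true dN/dS per family.
#' @examples
#' cfg <- PanSimConfig(n_genomes = 6, n_core_families = 10,
#'                     n_root_accessory = 5, seed = 3)
#' tr <- simulateSpeciesTree(6, 1, seed = 3)
#' truth <- simulateGeneContent(tr, cfg)
#' truth
#' @export
simulateGeneContent <- function(tree, config) {
  stopifnot(is(config, "PanSimConfig"))
  validObject(config)
  ntip <- length(tree$tip.label)
  if (ntip != config@n_genomes)
    stop("tree leaf count does not match config n_genomes")
  .withSeed(config@seed + 1L, {
    edges <- tree$edge
    elen <- tree$edge.length
    ord <- .preorderEdges(tree)
    root <- ntip + 1L
    n_core <- config@n_core_families
    core_ids <- sprintf("F%05d", seq_len(n_core))
    acc_ids <- sprintf("F%05d", n_core + seq_len(config@n_root_accessory))
    fam_counter <- n_core + config@n_root_accessory

    # presence[[node]] = character vector of loss-prone families present
    presence <- vector("list", max(edges))
    presence[[root]] <- acc_ids
    ev_branch <- character(); ev_family <- character(); ev_event <- character()

    for (i in ord) {
      par <- edges[i, 1L]; chi <- edges[i, 2L]; t <- elen[i]
      lab <- .nodeLabel(tree, chi)
      fams <- presence[[par]]
      surv <- fams
      if (config@loss_rate > 0 && length(fams)) {
        keep <- runif(length(fams)) < exp(-config@loss_rate * t)
        lost <- fams[!keep]
        surv <- fams[keep]
        if (length(lost)) {
          ev_branch <- c(ev_branch, rep(lab, length(lost)))
          ev_family <- c(ev_family, lost)
          ev_event <- c(ev_event, rep("loss", length(lost)))
        }
      }
      n_gain <- if (config@gain_rate > 0) rpois(1L, config@gain_rate * t) else 0L
      if (n_gain > 0L) {
        new_ids <- sprintf("F%05d", fam_counter + seq_len(n_gain))
        fam_counter <- fam_counter + n_gain
        surv <- c(surv, new_ids)
        ev_branch <- c(ev_branch, rep(lab, n_gain))
        ev_family <- c(ev_family, new_ids)
        ev_event <- c(ev_event, rep("gain", n_gain))
      }
      presence[[chi]] <- surv
    }

    leaves <- tree$tip.label
    mem_fam <- character(); mem_gen <- character()
    for (k in seq_len(ntip)) {
      fams <- c(core_ids, presence[[k]])
      mem_fam <- c(mem_fam, fams)
      mem_gen <- c(mem_gen, rep(leaves[k], length(fams)))
    }

    # transfer implants: singleton families on terminal branches
    donors_pool <- c(Vibrio = 0.5, Photobacterium = 0.2, Enterobacter = 0.2,
                     Serratia = 0.1)
    hgt_gene <- character(); hgt_donor <- character()
    hgt_fam <- character(); hgt_gen <- character()
    h_counter <- 0L
    if (config@hgt_rate > 0) {
      for (k in seq_len(ntip)) {
        nh <- rpois(1L, config@hgt_rate)
        if (nh == 0L) next
        ids <- sprintf("H%04d", h_counter + seq_len(nh))
        h_counter <- h_counter + nh
        hgt_fam <- c(hgt_fam, ids)
        hgt_gen <- c(hgt_gen, rep(leaves[k], nh))
        dn <- sample(names(donors_pool), nh, replace = TRUE, prob = donors_pool)
        gene_ids <- paste0(leaves[k], "|", ids, "_1")
        hgt_gene <- c(hgt_gene, gene_ids)
        hgt_donor <- c(hgt_donor, dn)
        ev_branch <- c(ev_branch, rep(leaves[k], nh))
        ev_family <- c(ev_family, ids)
        ev_event <- c(ev_event, rep("hgt", nh))
      }
    }

    fam <- c(mem_fam, hgt_fam)
    gen <- c(mem_gen, hgt_gen)
    membership <- data.frame(
      family = fam, genome = gen,
      gene = paste0(gen, "|", fam, "_1"),
      stringsAsFactors = FALSE)

    om <- config@omega_by_class
    all_fams <- unique(membership$family)
    omega <- ifelse(all_fams %in% core_ids, om[["core"]], om[["accessory"]])
    names(omega) <- all_fams

    new("PanTruth",
        familyMembership = membership,
        eventLog = data.frame(branch = ev_branch, family = ev_family,
                              event = ev_event, stringsAsFactors = FALSE),
        hgtDonors = setNames(hgt_donor, hgt_gene),
        omegaTruth = omega)
  })
}

#' Evolve codon sequences for every simulated family
#'
#' Each family receives a random root CDS (ATG first codon, sense codons
#' only) evolved along the species tree under a GY94-style codon model with
#' the family's true dN/dS and the configured transition/transversion ratio,
#' uniform codon frequencies and no indels.  Branch lengths are multiplied by
#' \code{divergence_scale} before evolution.  Genes are laid on one contig
#' per genome with 0-based half-open coordinates and random strands.
#'
#' @param truth A \linkS4class{PanTruth} from [simulateGeneContent()].
#' @param tree The same species tree.
#' @param config The same [PanSimConfig()].
#' @return A \linkS4class{GeneSet}.
#' @export
simulateSequences <- function(truth, tree, config) {
  stopifnot(is(truth, "PanTruth"), is(config, "PanSimConfig"))
  omega <- truth@omegaTruth
  if (any(omega < 0)) stop("omega must be >= 0")
  L <- config@gene_length_codons
  ntip <- length(tree$tip.label)
  .withSeed(config@seed + 2L, {
    tab <- .codonTable()
    atg <- match("ATG", tab$codons)
    edges <- tree$edge
    elen <- tree$edge.length * config@divergence_scale
    ord <- .preorderEdges(tree)
    root <- ntip + 1L
    fams <- names(omega)
    leaf_states <- vector("list", ntip)

    for (w in unique(omega)) {
      fw <- fams[omega == w]
      k <- length(fw)
      eig <- .codonEigen(w, config@kappa_tstv)
      states <- vector("list", max(edges))
      rootm <- matrix(sample.int(tab$n, k * L, replace = TRUE), nrow = k)
      rootm[, 1L] <- atg
      states[[root]] <- rootm
      for (i in ord) {
        P <- .codonProb(eig, elen[i])
        child <- .evolveStates(states[[edges[i, 1L]]], P)
        child[, 1L] <- atg                    # start codon held fixed
        states[[edges[i, 2L]]] <- child
      }
      for (leaf in seq_len(ntip)) {
        m <- states[[leaf]]
        rownames(m) <- fw
        leaf_states[[leaf]] <- rbind(leaf_states[[leaf]], m)
      }
    }

    mem <- truth@familyMembership
    mem_by_genome <- split(mem, mem$genome)
    gi <- list(); cds <- character(); prot <- character(); gids <- character()
    for (leaf in seq_len(ntip)) {
      gname <- tree$tip.label[leaf]
      sub <- mem_by_genome[[gname]]
      if (is.null(sub) || !nrow(sub)) next
      sub <- sub[order(sub$gene), , drop = FALSE]
      st <- leaf_states[[leaf]][sub$family, , drop = FALSE]
      n <- nrow(sub)
      glen <- 3L * L
      ordg <- sample.int(n)                     # shuffle gene order on contig
      starts <- integer(n)
      starts[ordg] <- (seq_len(n) - 1L) * (glen + 100L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      gi[[gname]] <- data.frame(
        genome = gname, gene = sub$gene, contig = paste0(gname, "_c1"),
        start = starts, end = starts + glen, strand = strand,
        stringsAsFactors = FALSE)
      cds <- c(cds, apply(st, 1L, .codonStatesToDna))
      prot <- c(prot, apply(st, 1L, .translateStates))
      gids <- c(gids, sub$gene)
    }
    info <- do.call(rbind, gi)
    rownames(info) <- NULL
    new("GeneSet",
        geneInfo = info,
        cds = Biostrings::DNAStringSet(setNames(cds, gids)),
        protein = Biostrings::AAStringSet(setNames(prot, gids)))
  })
}

#' Simulate a pairwise protein similarity table from sequences
#'
#' Emulates an all-vs-all protein search restricted to informative rows:
#' within-family pairs receive reciprocal hits whose percent identity is
#' computed from the actual simulated proteins (bit score about two per
#' identical residue, E-value from a Karlin-Altschul-style size correction),
#' and a configurable rate of spurious weak cross-family hits exercises the
#' E-value filter and clustering robustness.
#'
#' @param genes A \linkS4class{GeneSet}.
#' @param truth The matching \linkS4class{PanTruth}.
#' @param noise_rate Expected spurious cross-family hit pairs per gene.
#' @param seed RNG seed.
#' @return data.frame in 12-column m8 layout (query, subject, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' @export
simulateOrthologHits <- function(genes, truth, noise_rate = 0.02, seed = 1) {
  stopifnot(is(genes, "GeneSet"), is(truth, "PanTruth"))
  .withSeed(seed + 3L, {
    prot <- as.character(proteinSeqs(genes))
    len <- unname(nchar(prot[1L]))
    n_total <- length(prot)
    mem <- truth@familyMembership
    fam_genes <- split(mem$gene, mem$family)
    qs <- list(); idx <- 0L
    aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
             "T","W","Y","V","*","X")
    for (fg in fam_genes) {
      m <- length(fg)
      if (m < 2L) next
      cm <- do.call(rbind, strsplit(prot[fg], ""))
      matches <- matrix(0L, m, m)
      for (a in unique(as.vector(cm))) {
        Ma <- cm == a
        matches <- matches + tcrossprod(Ma)
      }
      pr <- which(upper.tri(matches), arr.ind = TRUE)
      nm <- matches[pr]
      idx <- idx + 1L
      qs[[idx]] <- data.frame(query = fg[pr[, 1L]], subject = fg[pr[, 2L]],
                              nmatch = nm, stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, qs)
    bits <- 2 * hits$nmatch
    pid <- round(100 * hits$nmatch / len, 1)
    log10e <- log10(len) * 2 + 2 * log10(n_total) - bits * log10(2)
    ev <- 10^pmax(log10e, -180)
    half <- data.frame(query = hits$query, subject = hits$subject,
                       pident = pid, length = len, mismatch = len - hits$nmatch,
                       gapopen = 0L, qstart = 1L, qend = len, sstart = 1L,
                       send = len, evalue = ev, bitscore = bits,
                       stringsAsFactors = FALSE)
    out <- rbind(half,
                 transform(half, query = half$subject, subject = half$query))
    n_noise <- rpois(1L, noise_rate * n_total)
    # spurious hits are drawn among genes that also carry genuine homology
    # signal; an isolated singleton pair joined only by a spurious hit is
    # unresolvable by construction and is not simulated
    multi <- unlist(fam_genes[lengths(fam_genes) >= 2L], use.names = FALSE)
    if (n_noise > 0L && length(multi) >= 2L) {
      q <- sample(multi, n_noise, replace = TRUE)
      s <- sample(multi, n_noise, replace = TRUE)
      fam_of <- setNames(mem$family, mem$gene)
      keep <- q != s & fam_of[q] != fam_of[s]
      if (any(keep)) {
        q <- q[keep]; s <- s[keep]
        b <- runif(length(q), 57, 70)
        nz <- data.frame(query = q, subject = s,
                         pident = round(runif(length(q), 25, 40), 1),
                         length = len, mismatch = round(len * 0.7), gapopen = 0L,
                         qstart = 1L, qend = len, sstart = 1L, send = len,
                         evalue = 10^(log10(len) * 2 + 2 * log10(n_total) -
                                        b * log10(2)),
                         bitscore = round(b, 1), stringsAsFactors = FALSE)
        out <- rbind(out, nz)
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate a taxon-labelled best-hit profile table for transfer detection
#'
#' Every gene receives self-group hits (best hit defines the normalization),
#' vertical genes receive many strong close-group hits and sparse weak distal
#' hits, and implanted transfer genes receive distal-dominated profiles whose
#' top distal hit carries the recorded donor taxon.  A few sub-50%-identity
#' junk hits per gene exercise the identity floor.
#'
#' @param genes A \linkS4class{GeneSet}.
#' @param truth The matching \linkS4class{PanTruth} (donors taken from
#'   [hgtDonors()]).
#' @param seed RNG seed.
#' @return list with \code{hits} (12-column m8 data.frame) and
#'   \code{taxon_map} (data.frame subject, taxon, group).
#' @export
simulateHitTable <- function(genes, truth, seed = 1) {
  stopifnot(is(genes, "GeneSet"), is(truth, "PanTruth"))
  .withSeed(seed + 4L, {
    info <- geneInfo(genes)
    donors <- hgtDonors(truth)
    close_taxa <- c("Shewanellaceae_A", "Shewanellaceae_B")
    distal_taxa <- c("Vibrio", "Photobacterium", "Enterobacter", "Serratia",
                     "Pseudomonas")
    len <- unname(nchar(as.character(proteinSeqs(genes)[1L])))
    rows <- vector("list", nrow(info))
    subj_taxon <- character()
    mk <- function(gene, taxa, frac, ident, best) {
      k <- length(frac)
      subj <- sprintf("%s_p%07d", taxa, sample.int(9999999L, k))
      subj_taxon[subj] <<- taxa
      data.frame(query = gene, subject = subj, pident = round(ident, 1),
                 length = len, mismatch = round(len * (1 - ident / 100)),
                 gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = 10^runif(k, -80, -20),
                 bitscore = round(best * frac, 1), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(info))) {
      gene <- info$gene[i]
      is_hgt <- gene %in% names(donors)
      best <- round(runif(1, 180, 260))
      k_self <- 4L + rpois(1L, 4)
      self_fr <- c(1, runif(k_self - 1L, 0.85, 0.99))
      r <- list(mk(gene, "Shewanella", self_fr, runif(k_self, 92, 100), best))
      if (is_hgt) {
        k_close <- rbinom(1L, 1L, 0.3)
        if (k_close > 0L)
          r <- c(r, list(mk(gene, sample(close_taxa, k_close, TRUE),
                            runif(k_close, 0.05, 0.15),
                            runif(k_close, 55, 65), best)))
        k_dist <- 8L + rpois(1L, 4)
        fr <- sort(runif(k_dist, 0.6, 0.9), decreasing = TRUE)
        taxa <- sample(distal_taxa, k_dist, replace = TRUE)
        taxa[1L] <- donors[[gene]]
        r <- c(r, list(mk(gene, taxa, fr, runif(k_dist, 70, 90), best)))
      } else {
        k_close <- 12L + rpois(1L, 5)
        r <- c(r, list(mk(gene, sample(close_taxa, k_close, TRUE),
                          runif(k_close, 0.55, 0.95),
                          runif(k_close, 75, 95), best)))
        k_dist <- rpois(1L, 2)
        if (k_dist > 0L)
          r <- c(r, list(mk(gene, sample(distal_taxa, k_dist, TRUE),
                            runif(k_dist, 0.05, 0.25),
                            runif(k_dist, 55, 70), best)))
      }
      k_junk <- rpois(1L, 1)
      if (k_junk > 0L)
        r <- c(r, list(mk(gene, sample(distal_taxa, k_junk, TRUE),
                          runif(k_junk, 0.3, 0.6),
                          runif(k_junk, 30, 45), best)))
      rows[[i]] <- do.call(rbind, r)
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    tmap <- data.frame(subject = names(subj_taxon),
                       taxon = unname(subj_taxon), stringsAsFactors = FALSE)
    tmap$group <- ifelse(tmap$taxon == "Shewanella", "self",
                         ifelse(tmap$taxon %in% close_taxa, "close", "distal"))
    list(hits = hits, taxon_map = tmap)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes protein and CDS FASTA, the gene coordinate table, the ground-truth
#' tables, and (optionally) hit tables, as plain text.  Re-running with the
#' same objects reproduces the files byte for byte.
#'
#' @param genes A \linkS4class{GeneSet}.
#' @param truth A \linkS4class{PanTruth}.
#' @param out_dir Output directory (created if missing).
#' @param hits Optional hit table data.frame (written as \code{hits.tsv}).
#' @return Invisibly, the vector of paths written.
#' @export
writeDataset <- function(genes, truth, out_dir, hits = NULL) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  paths <- c(protein = file.path(out_dir, "protein.faa"),
             cds = file.path(out_dir, "cds.fna"),
             genes = file.path(out_dir, "genes.tsv"),
             families = file.path(out_dir, "truth_families.tsv"),
             events = file.path(out_dir, "truth_events.tsv"),
             hgt = file.path(out_dir, "truth_hgt.tsv"),
             omega = file.path(out_dir, "truth_omega.tsv"))
  Biostrings::writeXStringSet(proteinSeqs(genes), paths[["protein"]])
  Biostrings::writeXStringSet(cdsSeqs(genes), paths[["cds"]])
  wtsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  wtsv(geneInfo(genes), paths[["genes"]])
  wtsv(familyMembership(truth), paths[["families"]])
  wtsv(eventLog(truth), paths[["events"]])
  wtsv(data.frame(gene = names(hgtDonors(truth)),
                  donor = unname(hgtDonors(truth))), paths[["hgt"]])
  wtsv(data.frame(family = names(omegaTruth(truth)),
                  omega = unname(omegaTruth(truth))), paths[["omega"]])
  if (!is.null(hits)) {
    paths <- c(paths, hits = file.path(out_dir, "hits.tsv"))
    write.table(hits, paths[["hits"]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
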