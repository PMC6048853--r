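# Independent oracles used by the test suite.  Deliberately written as
# direct, dense, brute-force implementations that share no code path with
# the package internals they check.

# Dense MCL iteration run to convergence on a full adjacency matrix.
dense_mcl <- function(adj, inflation = 1.5, expansion = 2, max_iter = 200,
                      tol = 1e-6, prune = 1e-5) {
  n <- nrow(adj)
  loops <- apply(adj, 2, max)
  loops[loops <= 0] <- 1
  M <- adj + diag(loops)
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    Me <- M
    for (k in seq_len(expansion - 1)) Me <- Me %*% M
    Me <- Me^inflation
    Me[Me < prune] <- 0
    Me <- sweep(Me, 2, pmax(colSums(Me), .Machine$double.eps), "/")
    if (max(abs(Me - M)) < tol) {
      M <- Me
      break
    }
    M <- Me
  }
  conn <- (M + t(M)) > 0
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cid
      stack <- c(stack, which(conn[v, ] & comp == 0))
    }
  }
  split(seq_len(n), comp)
}

# Canonical form of a partition (for comparing clusterings).
canon_partition <- function(parts) {
  unname(sort(vapply(parts,
                     function(p) paste(sort(as.character(p)), collapse = ","),
                     "")))
}

# Least-squares evaluation of the three unrooted quartet topologies; returns
# the sister pair of the best-fitting one (lowest residual sum of squares).
ls_quartet <- function(dm) {
  taxa <- rownames(dm)
  stopifnot(length(taxa) == 4)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- vapply(pairs, function(pr) {
    sisters <- taxa[pr]
    others <- setdiff(taxa, sisters)
    # edges: e1..e4 terminal (order: sis1, sis2, oth1, oth2), e5 internal
    combs <- t(combn(taxa, 2))
    A <- matrix(0, nrow(combs), 5)
    d <- numeric(nrow(combs))
    term <- setNames(1:4, c(sisters, others))
    for (r in seq_len(nrow(combs))) {
      u <- combs[r, 1]; v <- combs[r, 2]
      A[r, term[u]] <- 1; A[r, term[v]] <- 1
      same_side <- (u %in% sisters) == (v %in% sisters)
      if (!same_side) A[r, 5] <- 1
      d[r] <- dm[u, v]
    }
    fit <- lm.fit(A, d)
    sum(fit$residuals^2)
  }, 0)
  sort(taxa[pairs[[which.min(rss)]]])
}

# Brute-force birth-death pruning likelihood: sum over every assignment of
# internal-node sizes, uniform root prior on 1..cap.
brute_bd_loglik <- function(tree, tip_sizes, lambda, cap) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):max(tree$edge)
  states <- 0:cap
  grid <- expand.grid(rep(list(states), length(nodes)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_ <- unlist(grid[g, ])
    names(assign_) <- as.character(nodes)
    root_size <- assign_[[as.character(ntip + 1)]]
    if (root_size == 0) next
    p <- 1 / cap
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      s <- assign_[[as.character(par)]]
      cval <- if (chi <= ntip) tip_sizes[[tree$tip.label[chi]]]
      else assign_[[as.character(chi)]]
      # renormalized transition over 0..cap, matching the model's truncation
      pr <- vapply(states, function(cc)
        bdTransition(s, cc, lambda, tree$edge.length[e]), 0)
      p <- p * pr[cval + 1] / sum(pr)
      if (p == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + p
  }
  log(total)
}

# Gillespie simulation of the linear birth-death size process (rate lambda
# per copy for both birth and death), used as a Monte-Carlo oracle for the
# closed-form transition probability.
gillespie_bd <- function(s, lambda, t_total, n_sims) {
  vapply(seq_len(n_sims), function(i) {
    n <- s; t <- 0
    repeat {
      if (n == 0) return(0L)
      rate <- 2 * lambda * n
      t <- t + rexp(1, rate)
      if (t > t_total) return(as.integer(n))
      n <- n + sample(c(1L, -1L), 1)
    }
  }, 0L)
}

# Small ultrametric tree with unit-scaled depth for reuse across tests.
fixture_tree <- function(n, seed = 11) {
  tr <- simulateSpeciesTree(n, 1, seed = seed)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# Simulated single-copy dataset: one family per omega, n_taxa genomes.
sim_family_dataset <- function(omega, n_taxa = 4, n_families = 1,
                               codons = 500, scale = 0.15, seed = 1) {
  cfg <- PanSimConfig(n_genomes = n_taxa, n_core_families = n_families,
                      n_root_accessory = 0, gain_rate = 0, loss_rate = 0,
                      omega_by_class = c(core = omega, accessory = 0.5),
                      gene_length_codons = codons, divergence_scale = scale,
                      seed = seed)
  tr <- simulateSpeciesTree(n_taxa, 1, seed = seed)
  truth <- simulateGeneContent(tr, cfg)
  genes <- simulateSequences(truth, tr, cfg)
  list(tree = tr, truth = truth, genes = genes, config = cfg)
}

# CDS of one family keyed by genome label.
family_cds <- function(genes, family, truth) {
  mem <- familyMembership(truth)
  sel <- mem[mem$family == family, ]
  cds <- as.character(cdsSeqs(genes)[sel$gene])
  names(cds) <- sel$genome
  cds
}
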