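# Gene-family expansion/contraction along the species tree: birth-death
# size-transition model, pruning likelihood, global rate ML, joint
# max-probability ancestral sizes, per-branch deltas and Monte-Carlo
# family significance.

#' Birth-death family-size transition probability
#'
#' Probability that a family of size \code{s} at the top of a branch of
#' length \code{t} has size \code{c} at the bottom, under the symmetric
#' birth-death size model with rate \code{lambda_bd}.  With
#' \code{alpha = lambda*t / (1 + lambda*t)}:
#' \deqn{P(s \to c) = \sum_j \binom{s}{j} \binom{s+c-j-1}{s-1}
#'   \alpha^{s+c-2j} (1-2\alpha)^j}
#' Size 0 is absorbing.  The closed form requires \code{alpha < 1/2}
#' (i.e. \code{lambda * t < 1}); larger values are an error.
#'
#' @param s,c Parent and child sizes (>= 0).
#' @param lambda_bd Birth/death rate per unit branch length (> 0).
#' @param t Branch length (>= 0).
#' @return Probability in [0, 1].
#' @examples
#' bdTransition(1, 0, 1, 1/3)   # alpha = 0.25 -> 0.25
#' bdTransition(1, 1, 1, 1/3)   # (1 - alpha)^2 = 0.5625
#' @export
bdTransition <- function(s, c, lambda_bd, t) {
  if (s < 0 || c < 0) stop("sizes must be >= 0")
  if (lambda_bd <= 0) stop("lambda_bd must be > 0")
  if (t < 0) stop("branch length must be >= 0")
  if (t == 0) return(as.numeric(c == s))
  alpha <- lambda_bd * t / (1 + lambda_bd * t)
  if (alpha >= 0.5)
    stop("alpha = lambda*t/(1+lambda*t) >= 1/2; model validity bound exceeded")
  if (s == 0) return(as.numeric(c == 0))
  j <- 0:min(s, c)
  sum(choose(s, j) * choose(s + c - j - 1, s - 1) *
        alpha^(s + c - 2 * j) * (1 - 2 * alpha)^j)
}

# Row-renormalized transition matrix over sizes 0..size_cap.
.bdMatrix <- function(size_cap, lambda_bd, t) {
  states <- 0:size_cap
  P <- outer(states, states,
             Vectorize(function(s, c) bdTransition(s, c, lambda_bd, t)))
  P / rowSums(P)
}

# Per-edge transition matrices for a tree at a given rate.
.bdEdgeMatrices <- function(tree, lambda_bd, size_cap) {
  lapply(tree$edge.length, function(t) .bdMatrix(size_cap, lambda_bd, t))
}

# Vectorized pruning over many families at once.
# tip_sizes: families x leaves integer matrix (columns named by leaf label).
# Returns per-family log-likelihood with a uniform root prior on 1..size_cap.
.bdLoglikMatrix <- function(tree, tip_sizes, lambda_bd, size_cap,
                            Pm = NULL) {
  ntip <- length(tree$tip.label)
  nfam <- nrow(tip_sizes)
  nstate <- size_cap + 1L
  if (is.null(Pm)) Pm <- .bdEdgeMatrices(tree, lambda_bd, size_cap)
  post <- rev(.preorderEdges(tree))
  L <- vector("list", max(tree$edge))
  scale <- matrix(0, nfam, 1L)
  logscale <- numeric(nfam)
  tipM <- function(sizes) {
    m <- matrix(0, nfam, nstate)
    m[cbind(seq_len(nfam), sizes + 1L)] <- 1
    m
  }
  for (i in post) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    Lc <- if (chi <= ntip) tipM(tip_sizes[, tree$tip.label[chi]]) else L[[chi]]
    contrib <- Lc %*% t(Pm[[i]])           # (fam x state) parent-conditional
    if (is.null(L[[par]])) L[[par]] <- contrib
    else {
      L[[par]] <- L[[par]] * contrib
      mx <- apply(L[[par]], 1L, max)
      mx[mx <= 0] <- 1
      L[[par]] <- L[[par]] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- rowSums(L[[root]][, -1L, drop = FALSE]) / size_cap
  log(lik) + logscale
}

#' Pruning log-likelihood of one family's tip sizes
#'
#' Felsenstein pruning over size states 0..\code{size_cap} with a uniform
#' root prior on 1..\code{size_cap} (a family observed today is assumed to
#' have existed at the root).
#'
#' @param tree \code{phylo} with branch lengths.
#' @param tip_sizes Named integer vector (one size per leaf).
#' @param lambda_bd Birth/death rate.
#' @param size_cap Largest modeled size; defaults to
#'   \code{2 * max(tip_sizes) + 10}.
#' @return Log-likelihood (scalar).
#' @export
familyLoglik <- function(tree, tip_sizes, lambda_bd,
                         size_cap = 2L * max(tip_sizes) + 10L) {
  if (!all(tree$tip.label %in% names(tip_sizes)))
    stop("tip_sizes must name every leaf")
  if (max(tip_sizes) > size_cap) stop("tip size exceeds size_cap")
  m <- matrix(as.integer(tip_sizes[tree$tip.label]), nrow = 1L,
              dimnames = list(NULL, tree$tip.label))
  as.numeric(.bdLoglikMatrix(tree, m, lambda_bd, size_cap))
}

#' Estimate the global birth-death rate from all families
#'
#' Maximizes the summed per-family pruning log-likelihood over a bounded
#' rate interval (the closed-form transition requires
#' \code{lambda * t < 1} on every branch).
#'
#' @param tree \code{phylo} with branch lengths.
#' @param sizes Families x genomes integer matrix (columns named by leaf).
#' @param size_cap Largest modeled size; default 2 * max observed + 10.
#' @return list: lambda (MLE), loglik, size_cap.
#' @export
estimateLambda <- function(tree, sizes,
                           size_cap = 2L * max(sizes) + 10L) {
  sizes <- as.matrix(sizes)
  if (all(apply(sizes, 1L, function(x) all(x == x[1L]))))
    stop("no signal: all families are invariant across genomes")
  upper <- 0.99 / max(tree$edge.length)
  fn <- function(lam) -sum(.bdLoglikMatrix(tree, sizes, lam, size_cap))
  opt <- optimize(fn, c(1e-6, upper))
  list(lambda = opt$minimum, loglik = -opt$objective, size_cap = size_cap)
}

# Joint max-probability ancestral assignment (Viterbi over the pruning
# lattice); ties broken toward the smaller |child - parent| delta.
.bdViterbi <- function(tree, tip_sizes_row, Pm, size_cap) {
  ntip <- length(tree$tip.label)
  nstate <- size_cap + 1L
  post <- rev(.preorderEdges(tree))
  logP <- lapply(Pm, function(p) log(pmax(p, 1e-300)))
  Lmax <- vector("list", max(tree$edge))     # per node: best log-prob per state
  back <- vector("list", nrow(tree$edge))    # per edge: argmax child state
  states <- 0:size_cap
  for (i in post) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    child_vec <- if (chi <= ntip) {
      v <- rep(-Inf, nstate); v[tip_sizes_row[tree$tip.label[chi]] + 1L] <- 0; v
    } else Lmax[[chi]]
    cand <- sweep(logP[[i]], 2L, child_vec, "+")   # parent x child
    # tie-break toward smaller |delta|: subtract epsilon * |delta|
    eps <- 1e-9
    pen <- outer(states, states, function(s, c) abs(c - s)) * eps
    cand <- cand - pen
    bw <- max.col(cand, ties.method = "first")
    bv <- cand[cbind(seq_len(nstate), bw)]
    back[[i]] <- bw - 1L
    if (is.null(Lmax[[par]])) Lmax[[par]] <- bv else Lmax[[par]] <- Lmax[[par]] + bv
  }
  root <- ntip + 1L
  rootscore <- Lmax[[root]]
  rootscore[1L] <- -Inf                      # root prior excludes size 0
  anc <- integer(max(tree$edge))
  anc[root] <- which.max(rootscore) - 1L
  for (i in .preorderEdges(tree)) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    anc[chi] <- if (chi <= ntip) tip_sizes_row[tree$tip.label[chi]]
    else back[[i]][anc[par] + 1L]
  }
  anc
}

#' Reconstruct ancestral family sizes and count per-branch changes
#'
#' For every family: joint max-probability ancestral sizes (Viterbi over the
#' pruning lattice, ties broken toward the smaller size change), per-branch
#' deltas (child minus parent), per-strain expansion/contraction totals, and
#' a Monte-Carlo p-value — the fraction of null families (root size drawn
#' from the uniform 1..size_cap prior and evolved under \code{lambda_bd})
#' whose likelihood is at most the observed one.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param sizes Families x genomes integer matrix (columns named by leaf).
#' @param lambda_bd Fitted rate (e.g. from [estimateLambda()]).
#' @param size_cap Largest modeled size.
#' @param n_null Null simulations for the p-value (default 1000).
#' @param seed RNG seed for the null simulations.
#' @return list of class \code{familyDynamics}: \code{ancestral} (families x
#'   nodes matrix), \code{deltas} (families x branches, branches labelled by
#'   child node), \code{p_values}, \code{branch_expansions},
#'   \code{branch_contractions}, and \code{strain_changes} (per-leaf
#'   expansion/contraction counts).
#' @export
reconstructAndCount <- function(tree, sizes, lambda_bd,
                                size_cap = 2L * max(sizes) + 10L,
                                n_null = 1000, seed = 1) {
  sizes <- as.matrix(sizes)
  nfam <- nrow(sizes)
  ntip <- length(tree$tip.label)
  Pm <- .bdEdgeMatrices(tree, lambda_bd, size_cap)
  anc <- t(vapply(seq_len(nfam),
                  function(f) .bdViterbi(tree, sizes[f, ], Pm, size_cap),
                  integer(max(tree$edge))))
  branch_labels <- .nodeLabel(tree, tree$edge[, 2L])
  deltas <- anc[, tree$edge[, 2L], drop = FALSE] -
    anc[, tree$edge[, 1L], drop = FALSE]
  colnames(deltas) <- branch_labels
  rownames(deltas) <- rownames(sizes)
  obs_ll <- .bdLoglikMatrix(tree, sizes, lambda_bd, size_cap, Pm = Pm)
  null_ll <- .withSeed(seed, {
    null_sizes <- .simulateBdMatrix(tree, lambda_bd, n_null, size_cap)$tips
    .bdLoglikMatrix(tree, null_sizes, lambda_bd, size_cap, Pm = Pm)
  })
  pvals <- vapply(obs_ll, function(x) mean(null_ll <= x), 0)
  exp_counts <- colSums(deltas > 0)
  con_counts <- colSums(deltas < 0)
  strain <- data.frame(
    strain = tree$tip.label,
    expansions = exp_counts[tree$tip.label],
    contractions = con_counts[tree$tip.label],
    row.names = NULL)
  structure(list(ancestral = anc, deltas = deltas,
                 p_values = setNames(pvals, rownames(sizes)),
                 branch_expansions = exp_counts,
                 branch_contractions = con_counts,
                 strain_changes = strain,
                 lambda = lambda_bd, size_cap = size_cap),
            class = "familyDynamics")
}

#' @export
print.familyDynamics <- function(x, ...) {
  cat("familyDynamics:", nrow(x$deltas), "families,",
      ncol(x$deltas), "branches; lambda =", signif(x$lambda, 4), "\n")
  cat("  mean per-strain expansions:",
      round(mean(x$strain_changes$expansions), 1),
      " contractions:", round(mean(x$strain_changes$contractions), 1), "\n")
  invisible(x)
}

# Evolve family sizes down the tree under the birth-death model; root sizes
# uniform on 1..size_cap.  Returns tip-size matrix and true per-branch deltas.
.simulateBdMatrix <- function(tree, lambda_bd, n_families, size_cap,
                              root_sizes = NULL) {
  ntip <- length(tree$tip.label)
  Pm <- .bdEdgeMatrices(tree, lambda_bd, size_cap)
  node_sizes <- matrix(0L, n_families, max(tree$edge))
  if (is.null(root_sizes))
    root_sizes <- sample.int(size_cap, n_families, replace = TRUE)
  node_sizes[, ntip + 1L] <- root_sizes
  for (i in .preorderEdges(tree)) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    pv <- node_sizes[, par]
    cv <- integer(n_families)
    for (s in unique(pv)) {
      idx <- which(pv == s)
      cv[idx] <- sample.int(size_cap + 1L, length(idx), replace = TRUE,
                            prob = Pm[[i]][s + 1L, ]) - 1L
    }
    node_sizes[, chi] <- cv
  }
  tips <- node_sizes[, seq_len(ntip), drop = FALSE]
  colnames(tips) <- tree$tip.label
  deltas <- node_sizes[, tree$edge[, 2L], drop = FALSE] -
    node_sizes[, tree$edge[, 1L], drop = FALSE]
  colnames(deltas) <- .nodeLabel(tree, tree$edge[, 2L])
  list(tips = tips, deltas = deltas, root = root_sizes)
}

#' Simulate family sizes under the birth-death size model
#'
#' Ground-truth generator for the expansion/contraction stage: root sizes
#' are drawn uniformly from 1..\code{root_max}, then evolved down the tree
#' under rate \code{lambda_bd}; the true per-branch size changes are
#' recorded.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param lambda_bd True rate.
#' @param n_families Number of families.
#' @param size_cap State cap used while simulating.
#' @param root_max Largest root size drawn.
#' @param seed RNG seed.
#' @return list: \code{tips} (families x leaves), \code{deltas} (families x
#'   branches, true changes), \code{root} (root sizes).
#' @export
simulateFamilySizes <- function(tree, lambda_bd, n_families, size_cap = 30L,
                                root_max = 5L, seed = 1) {
  .withSeed(seed, {
    roots <- sample.int(root_max, n_families, replace = TRUE)
    .simulateBdMatrix(tree, lambda_bd, n_families, size_cap,
                      root_sizes = roots)
  })
}

#' Family-size matrix from a FamilySet
#'
#' @param families A \linkS4class{FamilySet}.
#' @return Families x genomes integer copy-number matrix.
#' @export
familySizeMatrix <- function(families) {
  mem <- familyMembership(families)
  fams <- names(familyCategories(families))
  gens <- genomeNames(families)
  m <- matrix(0L, length(fams), length(gens), dimnames = list(fams, gens))
  tb <- table(mem$family, mem$genome)
  m[rownames(tb), colnames(tb)] <- as.integer(tb)
  m
}
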