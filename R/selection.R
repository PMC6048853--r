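# dN/dS estimation: Nei-Gojobori (1986) counting with Jukes-Cantor
# correction, and maximum likelihood under a single-ratio (M0) codon model.

# Per-codon synonymous site fraction: for each position, the fraction of the
# three alternative nucleotides giving a synonymous change; changes creating
# stop codons count as nonsynonymous opportunities (classic NG86 convention,
# fixed by the worked 6-codon example in the test suite).
.ng86Sites <- function() {
  if (!is.null(.codonCache$ng86_sites)) return(.codonCache$ng86_sites)
  tab <- .codonTable()
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  s <- numeric(tab$n)
  for (i in seq_len(tab$n)) {
    cod <- tab$codon_mat[i, ]
    syn <- 0
    for (p in 1:3) for (x in setdiff(nts, cod[p])) {
      alt <- cod; alt[p] <- x
      aa <- gc[[paste(alt, collapse = "")]]
      if (aa == tab$aa[i]) syn <- syn + 1
    }
    s[i] <- syn / 3
  }
  names(s) <- tab$codons
  .codonCache$ng86_sites <- s
  s
}

# Pairwise (Sd, Nd) for every codon pair, averaging substitution pathways
# with equal weight over orders; pathways through stop codons are excluded
# (all-blocked pairs fall back to counting stop steps as nonsynonymous).
.ng86PairCounts <- function() {
  if (!is.null(.codonCache$ng86_pairs)) return(.codonCache$ng86_pairs)
  tab <- .codonTable()
  gc <- Biostrings::GENETIC_CODE
  n <- tab$n
  sd_m <- matrix(0, n, n); nd_m <- matrix(0, n, n)
  perms <- list(`1` = matrix(1, 1), `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- tab$codon_mat[i, ]; b <- tab$codon_mat[j, ]
    pos <- which(a != b)
    k <- length(pos)
    if (k == 0L) next
    ords <- perms[[as.character(k)]]
    paths_s <- numeric(); paths_n <- numeric()
    all_s <- numeric(); all_n <- numeric()
    for (r in seq_len(nrow(ords))) {
      cur <- a; sdd <- 0; ndd <- 0; blocked <- FALSE
      for (step in pos[ords[r, seq_len(k)]]) {
        nxt <- cur; nxt[step] <- b[step]
        aa1 <- gc[[paste(cur, collapse = "")]]
        aa2 <- gc[[paste(nxt, collapse = "")]]
        if (aa2 == "*" || aa1 == "*") { blocked <- TRUE; ndd <- ndd + 1 }
        else if (aa1 == aa2) sdd <- sdd + 1
        else ndd <- ndd + 1
        cur <- nxt
      }
      all_s <- c(all_s, sdd); all_n <- c(all_n, ndd)
      if (!blocked) { paths_s <- c(paths_s, sdd); paths_n <- c(paths_n, ndd) }
    }
    if (length(paths_s)) { sd_ <- mean(paths_s); nd_ <- mean(paths_n) }
    else { sd_ <- mean(all_s); nd_ <- mean(all_n) }
    sd_m[i, j] <- sd_m[j, i] <- sd_
    nd_m[i, j] <- nd_m[j, i] <- nd_
  }
  .codonCache$ng86_pairs <- list(sd = sd_m, nd = nd_m)
  .codonCache$ng86_pairs
}

.jc <- function(p) {
  if (p >= 0.75) stop("saturated proportion (p >= 3/4); Jukes-Cantor ",
                      "correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (NG86) pairwise dN and dS
#'
#' Counts synonymous and nonsynonymous sites per sequence (averaged over the
#' pair), counts synonymous/nonsynonymous differences with multi-hit
#' pathways averaged with equal weight over substitution orders (pathways
#' through stop codons excluded), and applies the Jukes-Cantor multiple-hit
#' correction \code{d = -3/4 log(1 - 4p/3)} to both proportions.
#'
#' @param cds_a,cds_b Equal-length CDS strings (length a multiple of 3, no
#'   internal stop codons).
#' @return list of class \code{dnds}: dN, dS, omega (NA when dS = 0),
#'   S_sites, N_sites, Sd, Nd, method = "ng86".
#' @examples
#' ng86Pairwise("ATGGCTAAATTTGGGCAT", "ATGGCCAAATTCGGGCAT")
#' @export
ng86Pairwise <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must have equal length")
  sa <- .dnaToCodonStates(as.character(cds_a))
  sb <- .dnaToCodonStates(as.character(cds_b))
  sites <- .ng86Sites()
  S <- (sum(sites[sa]) + sum(sites[sb])) / 2
  N <- 3 * length(sa) - S
  pc <- .ng86PairCounts()
  Sd <- sum(pc$sd[cbind(sa, sb)])
  Nd <- sum(pc$nd[cbind(sa, sb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- .jc(pS)
  dN <- .jc(pN)
  omega <- if (dS > 0) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, S_sites = S, N_sites = N,
                 Sd = Sd, Nd = Nd, method = "ng86"), class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("dN/dS (%s): dN = %.4f, dS = %.4f, omega = %s", x$method,
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined (dS = 0)"
              else sprintf("%.4f", x$omega)))
  if (!is.null(x$kappa_tstv))
    cat(sprintf(", kappa = %.3f, logL = %.2f", x$kappa_tstv,
                x$log_likelihood))
  cat("\n")
  invisible(x)
}

# Pattern-compressed pruning log-likelihood under a GY94-style model.
# states: taxa x codon-site integer matrix; tree: rooted phylo whose tips
# match rownames(states); edge_len: per tree edge, expected subs/codon.
.m0Loglik <- function(states, tree, edge_len, omega, kappa) {
  tab <- .codonTable()
  eig <- .codonEigen(omega, kappa)
  ntip <- length(tree$tip.label)
  key <- apply(states, 2L, paste, collapse = ",")
  uniq <- !duplicated(key)
  counts <- as.vector(table(key)[key[uniq]])
  pat <- states[, uniq, drop = FALSE]
  npat <- ncol(pat)
  post <- rev(.preorderEdges(tree))
  L <- vector("list", max(tree$edge))
  tipL <- function(tipstates) {
    m <- matrix(0, tab$n, npat)
    m[cbind(tipstates, seq_len(npat))] <- 1
    m
  }
  ord_tips <- match(tree$tip.label, rownames(states))
  for (i in post) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    Lc <- if (chi <= ntip) tipL(pat[ord_tips[chi], ]) else L[[chi]]
    P <- .codonProb(eig, edge_len[i])
    contrib <- P %*% Lc
    if (is.null(L[[par]])) L[[par]] <- contrib else L[[par]] <- L[[par]] * contrib
  }
  root <- ntip + 1L
  sc <- apply(L[[root]], 2L, max)
  sc[sc <= 0] <- 1
  lik <- colSums(L[[root]] / rep(sc, each = tab$n)) / tab$n
  sum(counts * (log(lik) + log(sc)))
}

#' Fit the single-ratio (M0) codon model by maximum likelihood
#'
#' GY94-style 61x61 substitution model with one dN/dS ratio for the whole
#' alignment, a transition/transversion ratio and uniform codon frequencies;
#' the likelihood is computed by pruning over alignment columns and
#' maximized over omega, kappa and all branch lengths.  The fit is repeated
#' from several initial omega values and the highest-likelihood solution is
#' returned.
#'
#' @param cds Named character vector, \code{DNAStringSet}, or list of CDS
#'   (equal length, multiple of 3, no internal stops); names = taxa.
#' @param tree \code{phylo} whose tip labels equal the taxa.
#' @param n_starts Number of initial omega values used (from 0.1, 1.0, 2.0).
#' @param omega_starts Initial omega values.
#' @return list of class \code{dnds}: dN, dS, omega, kappa_tstv,
#'   log_likelihood, tree_length, method = "m0".  All-identical alignments
#'   return zero branch lengths and an undefined omega.
#' @export
m0Fit <- function(cds, tree, n_starts = 3, omega_starts = c(0.1, 1.0, 2.0)) {
  cds <- vapply(as.list(cds), as.character, "")
  if (!setequal(names(cds), tree$tip.label))
    stop("tree leaves must match alignment taxa")
  states <- do.call(rbind, lapply(cds, .dnaToCodonStates))
  if (all(apply(states, 2L, function(x) length(unique(x)) == 1L))) {
    return(structure(list(dN = 0, dS = 0, omega = NA_real_,
                          kappa_tstv = NA_real_, log_likelihood = NA_real_,
                          tree_length = 0, method = "m0"), class = "dnds"))
  }
  nedge <- nrow(tree$edge)
  t0 <- tree$edge.length
  if (is.null(t0) || any(!is.finite(t0)) ) t0 <- rep(0.1, nedge)
  t0 <- pmin(pmax(t0, 0.01), 5)
  starts <- omega_starts[seq_len(min(n_starts, length(omega_starts)))]
  best <- NULL
  for (w0 in starts) {
    par0 <- c(log(t0), log(2), log(w0))
    fn <- function(par) {
      el <- exp(par[seq_len(nedge)])
      kap <- exp(par[nedge + 1L])
      om <- exp(par[nedge + 2L])
      -tryCatch(.m0Loglik(states, tree, el, om, kap),
                error = function(e) Inf)
    }
    fit <- tryCatch(
      optim(par0, fn, method = "L-BFGS-B",
            lower = c(rep(log(1e-6), nedge), log(0.05), log(1e-4)),
            upper = c(rep(log(20), nedge), log(50), log(20)),
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("M0 optimizer failed to converge from all starts")
  el <- exp(best$par[seq_len(nedge)])
  kap <- exp(best$par[nedge + 1L])
  om <- exp(best$par[nedge + 2L])
  # Convert tree length (expected subs/codon) into dN and dS per site class.
  rho <- function(omega_) {
    Q <- .codonRateMatrix(omega_, kap)
    tab <- .codonTable()
    syn_off <- tab$synonymous & tab$neighbor
    non_off <- (!tab$synonymous) & tab$neighbor
    c(s = sum(Q[syn_off]) / tab$n, n = sum(Q[non_off]) / tab$n)
  }
  r_hat <- rho(om)
  r_mut <- rho(1)
  fS <- r_mut[["s"]] / (r_mut[["s"]] + r_mut[["n"]])
  Ttot <- sum(el)
  dS <- Ttot * r_hat[["s"]] / (3 * fS)
  dN <- Ttot * r_hat[["n"]] / (3 * (1 - fS))
  structure(list(dN = dN, dS = dS, omega = om, kappa_tstv = kap,
                 log_likelihood = -best$value, tree_length = Ttot,
                 method = "m0"), class = "dnds")
}

#' Mean pairwise NG86 estimate for a family alignment
#'
#' Averages dN and dS over all sequence pairs of a family and reports their
#' ratio; a quick counting-based family-level omega.
#'
#' @param cds Named character vector or \code{DNAStringSet} of family CDS.
#' @return list of class \code{dnds} (method \code{"ng86"}).
#' @export
ng86Family <- function(cds) {
  cds <- vapply(as.list(cds), as.character, "")
  if (length(cds) < 2) stop("need at least 2 sequences")
  prs <- combn(length(cds), 2)
  res <- apply(prs, 2L, function(ij) {
    r <- ng86Pairwise(cds[ij[1L]], cds[ij[2L]])
    c(r$dN, r$dS)
  })
  dN <- mean(res[1L, ]); dS <- mean(res[2L, ])
  structure(list(dN = dN, dS = dS,
                 omega = if (dS > 0) dN / dS else NA_real_,
                 method = "ng86"), class = "dnds")
}

#' Summarize selection pressure by annotation category
#'
#' For each label: number of families with a defined omega, median omega,
#' interquartile range, and the purifying fraction (share of families with
#' omega < 1).  Labels with no contributing family are dropped with a
#' warning.
#'
#' @param omegas Named numeric, one (possibly NA) omega per family.
#' @param annotations data.frame with columns \code{family} and \code{label}.
#' @return data.frame: label, n, median_omega, iqr_omega, purifying_fraction.
#' @export
selectionByCategory <- function(omegas, annotations) {
  stopifnot(all(c("family", "label") %in% names(annotations)))
  labs <- unique(annotations$label)
  rows <- lapply(labs, function(lb) {
    fams <- annotations$family[annotations$label == lb]
    om <- omegas[intersect(fams, names(omegas))]
    om <- om[!is.na(om)]
    if (!length(om)) return(NULL)
    data.frame(label = lb, n = length(om), median_omega = median(om),
               iqr_omega = IQR(om), purifying_fraction = mean(om < 1),
               stringsAsFactors = FALSE)
  })
  dropped <- labs[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("label(s) with no scored family omitted: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
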