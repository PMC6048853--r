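# Codon-model machinery shared by the sequence simulator and the M0 fitter.
# State space = the 61 sense codons of the standard genetic code; uniform
# codon frequencies throughout (simulator and estimator stay self-consistent).

.codonCache <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (!is.null(.codonCache$tab)) return(.codonCache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)            # 61
  cm <- do.call(rbind, strsplit(codons, ""))
  # pairwise single-nucleotide neighbor structure
  diffcount <- matrix(0L, n, n)
  for (p in 1:3) diffcount <- diffcount + outer(cm[, p], cm[, p], "!=")
  nb <- diffcount == 1L
  # transition (A<->G, C<->T) vs transversion for single-difference pairs
  is_ts <- matrix(FALSE, n, n)
  purine <- c("A", "G")
  for (p in 1:3) {
    d <- outer(cm[, p], cm[, p], "!=")
    ts_p <- outer(cm[, p] %in% purine, cm[, p] %in% purine, "==")
    only_p <- d & (diffcount == 1L)
    is_ts[only_p & ts_p] <- TRUE
  }
  syn <- outer(aa, aa, "==")
  tab <- list(codons = codons, aa = aa, n = n, codon_mat = cm,
              neighbor = nb, is_ts = is_ts, synonymous = syn)
  .codonCache$tab <- tab
  tab
}

# Scaled GY94-style rate generator: uniform codon frequencies, rate
# kappa^[ts] * omega^[nonsyn] / 61 between single-nucleotide neighbors,
# normalized to one expected substitution per codon per unit branch length.
# With omega = 0 the chain still moves through synonymous changes only.
.codonRateMatrix <- function(omega, kappa) {
  if (omega < 0) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  tab <- .codonTable()
  Q <- matrix(0, tab$n, tab$n, dimnames = list(tab$codons, tab$codons))
  Q[tab$neighbor] <- 1
  Q[tab$neighbor & tab$is_ts] <- kappa
  Q[tab$neighbor & !tab$synonymous] <- Q[tab$neighbor & !tab$synonymous] * omega
  diag(Q) <- -rowSums(Q)
  rate <- -mean(diag(Q))                       # pi uniform
  if (rate <= 0) stop("degenerate rate matrix (omega = 0 with no synonymous moves?)")
  Q / rate
}

# Eigen-decomposition once per (omega, kappa); P(t) for many t cheaply.
# Q is symmetric under uniform frequencies so eigen(symmetric = TRUE) applies.
.codonEigen <- function(omega, kappa) {
  Q <- .codonRateMatrix(omega, kappa)
  e <- eigen(Q, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, Q = Q)
}

.codonProb <- function(eig, t) {
  P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Evolve a matrix of codon states (rows = independent units, cols = sites)
# across one branch with transition matrix P; vectorized by parent state.
.evolveStates <- function(states, P) {
  out <- states
  dim(out) <- dim(states)
  vec <- as.vector(states)
  n <- ncol(P)
  for (s in unique(vec)) {
    idx <- which(vec == s)
    out[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

.codonStatesToDna <- function(states) {
  tab <- .codonTable()
  paste(tab$codons[states], collapse = "")
}

.dnaToCodonStates <- function(seq) {
  tab <- .codonTable()
  if (nchar(seq) %% 3L != 0L) stop("CDS length must be a multiple of 3")
  cod <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  st <- match(cod, tab$codons)
  if (anyNA(st)) stop("internal stop codon or ambiguous codon in CDS")
  st
}

.translateStates <- function(states) {
  tab <- .codonTable()
  paste(tab$aa[states], collapse = "")
}
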