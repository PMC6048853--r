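# Pan-genome structure: presence/absence matrix, accumulation curves,
# Heaps'-law openness, partition summaries and annotation profiling.

#' Presence/absence matrix of families across genomes
#'
#' @param families A \linkS4class{FamilySet}.
#' @return Integer 0/1 matrix, rows = families, columns = genomes (all
#'   genomes of the set, including any without members in some family).
#' @export
buildPresenceAbsence <- function(families) {
  stopifnot(is(families, "FamilySet"))
  mem <- familyMembership(families)
  if (!nrow(mem)) stop("no families")
  fams <- names(familyCategories(families))
  gens <- genomeNames(families)
  m <- matrix(0L, length(fams), length(gens), dimnames = list(fams, gens))
  m[cbind(match(mem$family, fams), match(mem$genome, gens))] <- 1L
  m
}

#' Pan and core accumulation curves over genome permutations
#'
#' For each of \code{n_permutations} random genome orderings, pan(n) counts
#' the families present in at least one of the first n genomes and core(n)
#' those present in all of them; means and standard deviations across
#' permutations are returned.
#'
#' @param matrix 0/1 presence matrix from [buildPresenceAbsence()].
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return data.frame (n, pan_mean, pan_sd, core_mean, core_sd) with
#'   attributes \code{n_permutations} and \code{seed}.
#' @export
accumulationCurve <- function(matrix, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  N <- ncol(matrix)
  pan <- core <- base::matrix(0, n_permutations, N)
  .withSeed(seed, {
    for (p in seq_len(n_permutations)) {
      ordg <- sample.int(N)
      cum <- matrix[, ordg, drop = FALSE]
      seen <- t(apply(cum, 1L, cummax))          # present in >= 1 of first n
      allof <- t(apply(cum, 1L, cummin))         # present in all of first n
      pan[p, ] <- colSums(seen)
      core[p, ] <- colSums(allof)
    }
  })
  out <- data.frame(n = seq_len(N),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2L, sd),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2L, sd))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  out
}

#' Fit Heaps' law to a pan-genome accumulation curve
#'
#' Least-squares fit of \code{log(pan) = log(kappa) + gamma * log(n)}.  A
#' positive exponent gamma indicates an open pan-genome; the verdict uses a
#' threshold of gamma > 0.05 to leave room for sampling noise around a
#' genuinely closed (gamma = 0) pan-genome.
#'
#' @param curve data.frame from [accumulationCurve()] (needs columns n and
#'   pan_mean, at least 4 points).
#' @param open_threshold Gamma above which the pan-genome is called open.
#' @return list of class \code{heapsFit}: heaps_kappa, heaps_gamma,
#'   r_squared, open_verdict.
#' @export
fitHeaps <- function(curve, open_threshold = 0.05) {
  if (nrow(curve) < 4) stop("need at least 4 curve points")
  if (any(curve$pan_mean <= 0)) stop("pan_mean must be positive")
  fit <- lm(log(pan_mean) ~ log(n), data = curve)
  gamma <- unname(coef(fit)[2L])
  kappa <- exp(unname(coef(fit)[1L]))
  y <- log(curve$pan_mean)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(heaps_kappa = kappa, heaps_gamma = gamma, r_squared = r2,
                 open_verdict = gamma > open_threshold),
            class = "heapsFit")
}

#' @export
print.heapsFit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: pan(n) = %.3g * n^%.4f (r^2 = %.4f) -> %s\n",
              x$heaps_kappa, x$heaps_gamma, x$r_squared,
              if (x$open_verdict) "open" else "closed"))
  invisible(x)
}

#' Partition summary of a family set
#'
#' Counts the pan, core, accessory and strain-specific families, the
#' single-copy core families and per-genome specific-family counts, and the
#' integer-rounded core and variable percentages of the pan-genome.
#'
#' @param families A \linkS4class{FamilySet}.
#' @return list: pan, core, accessory, specific, single_copy,
#'   specific_by_genome (named integer), core_percent, variable_percent.
#' @export
partitionSummary <- function(families) {
  stopifnot(is(families, "FamilySet"))
  cat_ <- familyCategories(families)
  pan <- length(cat_)
  core <- sum(cat_ == "core")
  specific <- sum(cat_ == "specific")
  accessory <- pan - core - specific
  mem <- familyMembership(families)
  spec_fams <- names(cat_)[cat_ == "specific"]
  spec_gen <- mem$genome[match(spec_fams, mem$family)]
  by_gen <- table(factor(spec_gen, levels = genomeNames(families)))
  list(pan = pan, core = core, accessory = accessory, specific = specific,
       single_copy = sum(singleCopy(families)),
       specific_by_genome = setNames(as.integer(by_gen), names(by_gen)),
       core_percent = round(100 * core / pan),
       variable_percent = round(100 * (pan - core) / pan))
}

#' Partition arithmetic from published headline counts
#'
#' Given the pan, core and strain-specific family counts of a pan-genome
#' study, derives the accessory count and the integer core/variable shares,
#' the identities that tie the partition together.
#'
#' @param pan,core,specific Family counts.
#' @return list: accessory, core_percent, variable_percent.
#' @examples
#' partitionShares(13406, 1878, 5801)  # accessory 5727, 14% core, 86% variable
#' @export
partitionShares <- function(pan, core, specific) {
  if (core + specific > pan) stop("core + specific exceed pan")
  list(accessory = pan - core - specific,
       core_percent = round(100 * core / pan),
       variable_percent = round(100 * (pan - core) / pan))
}

#' Percentage share, to a fixed number of decimals
#'
#' @param count,total Numerator and denominator.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage.
#' @examples
#' percentShare(1805, 3594)  # 50.22
#' @export
percentShare <- function(count, total, digits = 2) {
  if (total <= 0) stop("total must be positive")
  round(100 * count / total, digits)
}

#' Aggregate annotation labels over partition categories
#'
#' A family carries a label when at least one member gene does (union rule);
#' families are counted once per distinct label.  Also tabulates labels of
#' strain-specific families per genome.
#'
#' @param families A \linkS4class{FamilySet}.
#' @param annotations data.frame with columns \code{gene} and \code{label}
#'   (one row per gene-label assignment; genes may carry several labels).
#' @param scheme Free-text name of the annotation scheme (cazyme, go_slim,
#'   cog, ...), recorded in the output.
#' @return list: \code{by_category} (data.frame category, label, families)
#'   and \code{specific_by_genome} (data.frame genome, label, families),
#'   plus attribute \code{scheme}.
#' @export
profileAnnotations <- function(families, annotations,
                               scheme = c("cazyme", "go_slim", "cog")) {
  scheme <- match.arg(scheme)
  stopifnot(is(families, "FamilySet"),
            all(c("gene", "label") %in% names(annotations)))
  mem <- familyMembership(families)
  unknown <- setdiff(annotations$gene, mem$gene)
  if (length(unknown)) {
    warning(length(unknown), " annotated gene id(s) not in any family; skipped")
    annotations <- annotations[!annotations$gene %in% unknown, , drop = FALSE]
  }
  ann <- merge(annotations, mem, by = "gene")
  fam_lab <- unique(ann[, c("family", "label")])
  fam_lab$category <- familyCategories(families)[fam_lab$family]
  by_cat <- as.data.frame(table(category = fam_lab$category,
                                label = fam_lab$label),
                          responseName = "families",
                          stringsAsFactors = FALSE)
  by_cat <- by_cat[by_cat$families > 0, , drop = FALSE]
  spec <- fam_lab[fam_lab$category == "specific", , drop = FALSE]
  spec$genome <- mem$genome[match(spec$family, mem$family)]
  by_gen <- as.data.frame(table(genome = spec$genome, label = spec$label),
                          responseName = "families",
                          stringsAsFactors = FALSE)
  by_gen <- by_gen[by_gen$families > 0, , drop = FALSE]
  out <- list(by_category = by_cat, specific_by_genome = by_gen)
  attr(out, "scheme") <- scheme
  out
}
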