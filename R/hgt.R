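# Best-hit-profile detection of horizontally transferred genes: per-gene
# self/close/distal scores from taxon-labelled hit tables, data-driven
# cutoffs from the score distributions, calls with donor assignment.

#' Configuration for transfer detection
#'
#' @param min_identity Percent-identity floor for hit retention (default 50).
#' @param strict_identity Stricter floor applied when \code{strict = TRUE}
#'   in [scoreGenes()] (default 90).
#' @param evalue_cutoff Maximum E-value retained (default 1e-5).
#' @param max_hits Top-scoring hits kept per gene (default 500).
#' @param cutoff_method \code{"kde_valley"} (Gaussian KDE, Silverman
#'   bandwidth, first minimum between the two largest modes) or
#'   \code{"quantile"}.
#' @param quantile_prob Quantile used by the fallback (default 0.25).
#' @return list of class \code{hgtConfig}.
#' @export
hgtConfig <- function(min_identity = 50, strict_identity = 90,
                      evalue_cutoff = 1e-5, max_hits = 500,
                      cutoff_method = c("kde_valley", "quantile"),
                      quantile_prob = 0.25) {
  if (max_hits < 1) stop("max_hits must be >= 1")
  structure(list(min_identity = min_identity,
                 strict_identity = strict_identity,
                 evalue_cutoff = evalue_cutoff, max_hits = max_hits,
                 cutoff_method = match.arg(cutoff_method),
                 quantile_prob = quantile_prob),
            class = "hgtConfig")
}

#' Per-gene self/close/distal scores from a taxon-labelled hit table
#'
#' Hits are deduplicated by query-subject pair (best bit score kept),
#' filtered by percent identity and E-value, truncated to the top
#' \code{max_hits} by bit score, partitioned into self/close/distal by the
#' taxon map, normalized by the gene's best retained bit score, and summed
#' per group.
#'
#' @param hits 12-column m8 data.frame (query, subject, pident, ...,
#'   evalue, bitscore).
#' @param taxon_map data.frame with columns \code{subject}, \code{taxon},
#'   \code{group} (group in self/close/distal).
#' @param config An [hgtConfig()].
#' @param strict Apply the stricter identity floor instead of the default.
#' @return data.frame: gene, self_score, close_score, distal_score,
#'   top_distal_taxon, n_hits.  Genes with no surviving hits are excluded
#'   with a warning.
#' @export
scoreGenes <- function(hits, taxon_map, config = hgtConfig(),
                       strict = FALSE) {
  stopifnot(all(c("query", "subject", "pident", "evalue", "bitscore")
                %in% names(hits)))
  floor_id <- if (strict) config$strict_identity else config$min_identity
  h <- hits[hits$pident >= floor_id & hits$evalue <= config$evalue_cutoff, ,
            drop = FALSE]
  # deduplicate query-subject pairs, keeping the best bit score
  h <- h[order(h$query, h$subject, -h$bitscore), , drop = FALSE]
  h <- h[!duplicated(h[, c("query", "subject")]), , drop = FALSE]
  grp <- taxon_map$group[match(h$subject, taxon_map$subject)]
  tax <- taxon_map$taxon[match(h$subject, taxon_map$subject)]
  if (anyNA(grp)) stop("hit subject(s) missing from the taxon map")
  h$group <- grp; h$taxon <- tax
  all_genes <- unique(hits$query)
  out <- lapply(split(h, h$query), function(g) {
    g <- g[order(-g$bitscore), , drop = FALSE]
    g <- head(g, config$max_hits)
    best <- max(g$bitscore)
    norm <- g$bitscore / best
    dist_idx <- which(g$group == "distal")
    data.frame(
      gene = g$query[1L],
      self_score = sum(norm[g$group == "self"]),
      close_score = sum(norm[g$group == "close"]),
      distal_score = sum(norm[g$group == "distal"]),
      top_distal_taxon = if (length(dist_idx)) g$taxon[dist_idx[1L]]
      else NA_character_,
      n_hits = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  dropped <- setdiff(all_genes, out$gene)
  if (length(dropped))
    warning(length(dropped), " gene(s) with no surviving hits excluded")
  out
}

# First local KDE minimum between the two largest modes; NULL when the
# distribution is effectively unimodal (fewer than two modes, or no valley
# dipping below half the smaller mode's density -- wiggles of a single mode
# must not produce a cutoff in the middle of the distribution).
.kdeValley <- function(x) {
  if (length(unique(x)) < 3) return(NULL)
  d <- density(x, bw = "nrd0")
  y <- d$y
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(locmax) < 2L) return(NULL)
  top2 <- locmax[order(y[locmax], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  seg <- y[lo:hi]
  mins <- which(diff(sign(diff(seg))) > 0) + 1L
  if (!length(mins)) mins <- which.min(seg)
  valley <- lo + mins[1L] - 1L
  if (y[valley] > 0.5 * min(y[top2])) return(NULL)
  d$x[valley]
}

#' Data-driven close and distal score cutoffs
#'
#' Under \code{kde_valley}, each cutoff is the first local minimum of a
#' Gaussian kernel density (Silverman bandwidth) of the scores between the
#' two largest well-separated modes.  A distribution without a genuine low
#' (close) or high (distal) secondary mode carries no transfer signal: the
#' kde_valley method then returns conservative cutoffs that flag nothing
#' (close_cutoff 0, distal_cutoff Inf) with a warning.  The explicit
#' \code{quantile} method uses the configured quantile of the close scores
#' and its mirror (upper quantile) for the distal scores.
#'
#' @param scores data.frame from [scoreGenes()] (>= 50 genes).
#' @param config An [hgtConfig()].
#' @return list: close_cutoff, distal_cutoff, method_used (per cutoff).
#' @export
estimateCutoffs <- function(scores, config = hgtConfig()) {
  if (nrow(scores) < 50) stop("need at least 50 genes to estimate cutoffs")
  one <- function(x, nm, none_cut) {
    if (config$cutoff_method == "kde_valley") {
      v <- .kdeValley(x)
      if (!is.null(v)) return(list(cut = v, method = "kde_valley"))
      warning("no separated secondary mode in ", nm,
              " scores; conservative cutoff (no calls on this margin)")
      return(list(cut = none_cut, method = "no_valley"))
    }
    p <- if (nm == "close") config$quantile_prob else 1 - config$quantile_prob
    list(cut = unname(quantile(x, p)), method = "quantile")
  }
  cl <- one(scores$close_score, "close", 0)
  di <- one(scores$distal_score, "distal", Inf)
  list(close_cutoff = cl$cut, distal_cutoff = di$cut,
       method_used = c(close = cl$method, distal = di$method))
}

#' Call horizontally transferred genes
#'
#' A gene is flagged when its close score falls below the close cutoff
#' (poor support in the sister taxa) while its distal score reaches the
#' distal cutoff (strong support far away); the donor is the taxon of its
#' best distal hit.
#'
#' @param scores data.frame from [scoreGenes()].
#' @param cutoffs list from [estimateCutoffs()] (close_cutoff,
#'   distal_cutoff).
#' @param gene_genomes Optional named character (genome per gene) enabling
#'   per-strain counts.
#' @return list: \code{calls} (data.frame gene, flagged, donor, scores),
#'   \code{by_donor} (named counts over flagged genes), and, when genomes
#'   are supplied, \code{by_strain}.
#' @export
callHgt <- function(scores, cutoffs, gene_genomes = NULL) {
  flagged <- scores$close_score < cutoffs$close_cutoff &
    scores$distal_score >= cutoffs$distal_cutoff &
    scores$distal_score > 0
  calls <- data.frame(gene = scores$gene, flagged = flagged,
                      donor = ifelse(flagged, scores$top_distal_taxon,
                                     NA_character_),
                      close_score = scores$close_score,
                      distal_score = scores$distal_score,
                      stringsAsFactors = FALSE)
  out <- list(calls = calls,
              by_donor = table(calls$donor[calls$flagged]))
  if (!is.null(gene_genomes)) {
    gg <- gene_genomes[calls$gene]
    out$by_strain <- table(gg[calls$flagged])
  }
  out
}
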