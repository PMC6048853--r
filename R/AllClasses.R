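#' @import methods
#' @importFrom stats density dist as.dist optim optimize quantile runif rpois
#'   rbinom sd median IQR lm coef setNames ave
#' @importFrom utils read.delim write.table combn head
NULL

#' Simulation configuration for the synthetic pan-genome generator
#'
#' Holds every knob of the synthetic-data generator: the number of genomes and
#' the pure-birth rate of the species tree, the planted gene-content history
#' (core families, root accessory families, Poisson gain/loss rates per unit
#' branch length), the selection regime used to evolve codon sequences (one
#' dN/dS ratio per family class, a shared transition/transversion ratio), the
#' horizontal-transfer implant rate, and the master seed.  Identical
#' configuration plus seed yields byte-identical output everywhere.
#'
#' @slot n_genomes Number of genomes (tree leaves), at least 2.
#' @slot birth_rate Pure-birth (Yule) speciation rate per unit time.
#' @slot n_core_families Number of planted core families (present in every
#'   genome, exempt from loss).
#' @slot n_root_accessory Number of accessory families present at the root and
#'   subject to loss.
#' @slot gain_rate,loss_rate Family gain/loss events per family per unit
#'   branch length.
#' @slot hgt_rate Expected implanted transfer genes per genome.
#' @slot omega_by_class Named numeric, dN/dS ratio per family class; must
#'   contain entries \code{core} and \code{accessory} (gained/specific
#'   families inherit the accessory value).
#' @slot kappa_tstv Transition/transversion rate ratio (> 0).
#' @slot gene_length_codons Codons per gene (>= 10); CDS length is three times
#'   this.
#' @slot divergence_scale Multiplier applied to species-tree branch lengths
#'   before sequence evolution; controls sequence divergence independently of
#'   tree shape.
#' @slot seed Master RNG seed (integer).
#' @export
setClass("PanSimConfig", representation(
  n_genomes = "integer",
  birth_rate = "numeric",
  n_core_families = "integer",
  n_root_accessory = "integer",
  gain_rate = "numeric",
  loss_rate = "numeric",
  hgt_rate = "numeric",
  omega_by_class = "numeric",
  kappa_tstv = "numeric",
  gene_length_codons = "integer",
  divergence_scale = "numeric",
  seed = "integer"
))

setValidity("PanSimConfig", function(object) {
  msg <- character()
  if (object@n_genomes < 2L) msg <- c(msg, "n_genomes must be >= 2")
  if (object@birth_rate <= 0) msg <- c(msg, "birth_rate must be > 0")
  if (object@n_core_families < 1L) msg <- c(msg, "n_core_families must be >= 1")
  if (object@n_root_accessory < 0L) msg <- c(msg, "n_root_accessory must be >= 0")
  rates <- c(gain_rate = object@gain_rate, loss_rate = object@loss_rate,
             hgt_rate = object@hgt_rate)
  if (any(rates < 0)) msg <- c(msg, "gain_rate, loss_rate and hgt_rate must be >= 0")
  if (any(object@omega_by_class < 0)) msg <- c(msg, "omega values must be >= 0")
  if (!all(c("core", "accessory") %in% names(object@omega_by_class)))
    msg <- c(msg, "omega_by_class must name 'core' and 'accessory' classes")
  if (object@kappa_tstv <= 0) msg <- c(msg, "kappa_tstv must be > 0")
  if (object@gene_length_codons < 10L) msg <- c(msg, "gene_length_codons must be >= 10")
  if (object@divergence_scale <= 0) msg <- c(msg, "divergence_scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param n_genomes,birth_rate,n_core_families,n_root_accessory Tree and
#'   content sizes; see the class documentation.
#' @param gain_rate,loss_rate,hgt_rate Event rates (>= 0).
#' @param omega_by_class Named dN/dS per family class (\code{core},
#'   \code{accessory}).
#' @param kappa_tstv Transition/transversion ratio.
#' @param gene_length_codons Codons per gene.
#' @param divergence_scale Branch-length multiplier for sequence evolution.
#' @param seed Master seed.
#' @return A validated \linkS4class{PanSimConfig}.
#' @examples
#' cfg <- PanSimConfig(n_genomes = 6, n_core_families = 20,
#'                     n_root_accessory = 10, seed = 1)
#' cfg
#' @export
PanSimConfig <- function(n_genomes = 24, birth_rate = 1,
                         n_core_families = 200, n_root_accessory = 300,
                         gain_rate = 0.5, loss_rate = 0.5, hgt_rate = 0,
                         omega_by_class = c(core = 0.2, accessory = 0.5),
                         kappa_tstv = 2, gene_length_codons = 100,
                         divergence_scale = 0.1, seed = 1) {
  new("PanSimConfig",
      n_genomes = as.integer(n_genomes), birth_rate = as.numeric(birth_rate),
      n_core_families = as.integer(n_core_families),
      n_root_accessory = as.integer(n_root_accessory),
      gain_rate = as.numeric(gain_rate), loss_rate = as.numeric(loss_rate),
      hgt_rate = as.numeric(hgt_rate),
      omega_by_class = omega_by_class, kappa_tstv = as.numeric(kappa_tstv),
      gene_length_codons = as.integer(gene_length_codons),
      divergence_scale = as.numeric(divergence_scale),
      seed = as.integer(seed))
}

setMethod("show", "PanSimConfig", function(object) {
  cat("PanSimConfig:", object@n_genomes, "genomes,",
      object@n_core_families, "core +", object@n_root_accessory,
      "root-accessory families\n")
  cat("  gain/loss/hgt rates:", object@gain_rate, "/", object@loss_rate, "/",
      object@hgt_rate, "\n")
  cat("  omega:", paste(names(object@omega_by_class),
                        object@omega_by_class, sep = "=", collapse = ", "),
      " kappa:", object@kappa_tstv, "\n")
  cat("  gene length:", object@gene_length_codons, "codons;",
      "divergence scale:", object@divergence_scale, "; seed:", object@seed, "\n")
})

#' Ground-truth tables of a simulated dataset
#'
#' Records everything the generator knows: which gene belongs to which
#' family in which genome, the gain/loss/transfer events placed on each
#' branch, the donor taxon of every implanted transfer gene, and the true
#' dN/dS ratio each family was evolved under.
#'
#' @slot familyMembership data.frame with columns \code{family},
#'   \code{genome}, \code{gene}; every simulated gene appears exactly once.
#' @slot eventLog data.frame with columns \code{branch} (child node label of
#'   the branch), \code{family}, \code{event} (\code{gain}, \code{loss},
#'   \code{duplication} or \code{hgt}).
#' @slot hgtDonors Named character; donor taxon per transfer-implanted gene.
#' @slot omegaTruth Named numeric; true dN/dS per family.
#' @export
setClass("PanTruth", representation(
  familyMembership = "data.frame",
  eventLog = "data.frame",
  hgtDonors = "character",
  omegaTruth = "numeric"
))

setValidity("PanTruth", function(object) {
  msg <- character()
  fm <- object@familyMembership
  if (!all(c("family", "genome", "gene") %in% names(fm)))
    msg <- c(msg, "familyMembership needs columns family, genome, gene")
  if (anyDuplicated(fm$gene))
    msg <- c(msg, "each gene must belong to exactly one family")
  hg <- names(object@hgtDonors)
  if (length(hg) && !all(hg %in% fm$gene))
    msg <- c(msg, "every transfer-flagged gene must be a simulated gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PanTruth", function(object) {
  cat("PanTruth:", length(unique(object@familyMembership$family)), "families,",
      nrow(object@familyMembership), "genes,",
      nrow(object@eventLog), "events,",
      length(object@hgtDonors), "transfer genes\n")
})

#' A collection of simulated genes with sequences and coordinates
#'
#' One row of \code{geneInfo} per gene: genome, gene id, contig, 0-based
#' half-open coordinates and strand; CDS and protein sequences are stored as
#' \code{DNAStringSet}/\code{AAStringSet} keyed by gene id.
#'
#' @slot geneInfo data.frame (genome, gene, contig, start, end, strand).
#' @slot cds \code{DNAStringSet} of coding sequences, names = gene ids.
#' @slot protein \code{AAStringSet} of translations, names = gene ids.
#' @export
setClass("GeneSet", representation(
  geneInfo = "data.frame",
  cds = "DNAStringSet",
  protein = "AAStringSet"
))

setValidity("GeneSet", function(object) {
  msg <- character()
  gi <- object@geneInfo
  need <- c("genome", "gene", "contig", "start", "end", "strand")
  if (!all(need %in% names(gi)))
    msg <- c(msg, paste("geneInfo needs columns", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(gi$gene)) msg <- c(msg, "gene ids must be unique")
    if (!all(gi$strand %in% c("+", "-"))) msg <- c(msg, "strand must be + or -")
    if (any(gi$end <= gi$start)) msg <- c(msg, "end must exceed start (0-based half-open)")
    if (!identical(sort(names(object@cds)), sort(gi$gene)) ||
        !identical(sort(names(object@protein)), sort(gi$gene)))
      msg <- c(msg, "cds and protein names must match gene ids")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet:", nrow(object@geneInfo), "genes across",
      length(unique(object@geneInfo$genome)), "genomes\n")
})

#' Orthologous gene families with partition categories
#'
#' The central container downstream of clustering: family membership (one row
#' per gene), the core/accessory/specific category of each family, the
#' single-copy flag, and the full genome set (so that genomes contributing no
#' clustered gene still count in the core definition).
#'
#' @slot membership data.frame with columns \code{family}, \code{genome},
#'   \code{gene}.
#' @slot category Named character (\code{core}, \code{accessory} or
#'   \code{specific}) per family.
#' @slot singleCopy Named logical per family; TRUE iff the family spans all
#'   genomes with exactly one gene each.
#' @slot genomes Character vector of all genome ids.
#' @export
setClass("FamilySet", representation(
  membership = "data.frame",
  category = "character",
  singleCopy = "logical",
  genomes = "character"
))

setValidity("FamilySet", function(object) {
  msg <- character()
  mb <- object@membership
  if (!all(c("family", "genome", "gene") %in% names(mb)))
    msg <- c(msg, "membership needs columns family, genome, gene")
  fams <- unique(mb$family)
  if (!setequal(fams, names(object@category)))
    msg <- c(msg, "category must name every family exactly")
  if (!all(object@category %in% c("core", "accessory", "specific")))
    msg <- c(msg, "categories must be core/accessory/specific")
  if (!setequal(fams, names(object@singleCopy)))
    msg <- c(msg, "singleCopy must name every family exactly")
  if (nrow(mb) && !all(mb$genome %in% object@genomes))
    msg <- c(msg, "membership genomes must be listed in genomes")
  if (anyDuplicated(mb$gene))
    msg <- c(msg, "families must partition genes (no gene in two families)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FamilySet", function(object) {
  tab <- table(factor(object@category, c("core", "accessory", "specific")))
  cat("FamilySet:", length(object@category), "families over",
      length(object@genomes), "genomes\n")
  cat("  core:", tab[["core"]], " accessory:", tab[["accessory"]],
      " specific:", tab[["specific"]],
      " single-copy:", sum(object@singleCopy), "\n")
})
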