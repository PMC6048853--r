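#' Accessors for panforge containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x A panforge object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))
#' @rdname accessors
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))
#' @rdname accessors
#' @export
setGeneric("genomeNames", function(x) standardGeneric("genomeNames"))
#' @rdname accessors
#' @export
setGeneric("familyMembership", function(x) standardGeneric("familyMembership"))
#' @rdname accessors
#' @export
setGeneric("familyCategories", function(x) standardGeneric("familyCategories"))
#' @rdname accessors
#' @export
setGeneric("singleCopy", function(x) standardGeneric("singleCopy"))
#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setGeneric("hgtDonors", function(x) standardGeneric("hgtDonors"))
#' @rdname accessors
#' @export
setGeneric("omegaTruth", function(x) standardGeneric("omegaTruth"))

#' @rdname accessors
#' @export
setMethod("geneInfo", "GeneSet", function(x) x@geneInfo)
#' @rdname accessors
#' @export
setMethod("cdsSeqs", "GeneSet", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("proteinSeqs", "GeneSet", function(x) x@protein)
#' @rdname accessors
#' @export
setMethod("genomeNames", "GeneSet", function(x) sort(unique(x@geneInfo$genome)))
#' @rdname accessors
#' @export
setMethod("genomeNames", "FamilySet", function(x) x@genomes)
#' @rdname accessors
#' @export
setMethod("familyMembership", "FamilySet", function(x) x@membership)
#' @rdname accessors
#' @export
setMethod("familyMembership", "PanTruth", function(x) x@familyMembership)
#' @rdname accessors
#' @export
setMethod("familyCategories", "FamilySet", function(x) x@category)
#' @rdname accessors
#' @export
setMethod("singleCopy", "FamilySet", function(x) x@singleCopy)
#' @rdname accessors
#' @export
setMethod("eventLog", "PanTruth", function(x) x@eventLog)
#' @rdname accessors
#' @export
setMethod("hgtDonors", "PanTruth", function(x) x@hgtDonors)
#' @rdname accessors
#' @export
setMethod("omegaTruth", "PanTruth", function(x) x@omegaTruth)
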