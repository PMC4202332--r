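#' @import methods
#' @importFrom stats rbinom rlnorm rnorm rnbinom runif median cor.test setNames
#' @importFrom utils read.delim write.table
NULL

#' Accessor generics
#'
#' Accessors for the central S4 containers: the underlying \code{ape}
#' \code{phylo} object, the tagged WGD node, species and locus bookkeeping,
#' state grids and event tables.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot contents; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("treePhylo", function(x, ...) standardGeneric("treePhylo"))

#' @rdname accessors
#' @export
setGeneric("wgdNode", function(x, ...) standardGeneric("wgdNode"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x, ...) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("postWgdSpecies", function(x, ...) standardGeneric("postWgdSpecies"))

#' @rdname accessors
#' @export
setGeneric("branchMap", function(x, ...) standardGeneric("branchMap"))

#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x, ...) standardGeneric("alignmentRows"))

#' @rdname accessors
#' @export
setGeneric("alignmentFeatures", function(x, ...) standardGeneric("alignmentFeatures"))

#' @rdname accessors
#' @export
setGeneric("states", function(x, ...) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("codonIndels", function(x, ...) standardGeneric("codonIndels"))

#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x, ...) standardGeneric("siteInfo"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x, ...) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("branchTotals", function(x, ...) standardGeneric("branchTotals"))

#' @rdname accessors
#' @export
setGeneric("pillarEntries", function(x, ...) standardGeneric("pillarEntries"))
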