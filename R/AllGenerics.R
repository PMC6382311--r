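#' @rdname MutationMatrix-class
#' @param x,object an object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname MutationMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MutationMatrix-class
#' @param genes optional character vector restricting the result.
#' @export
setGeneric("mutatedSamples", function(x, genes = NULL) standardGeneric("mutatedSamples"))

#' @rdname MutationMatrix-class
#' @export
setGeneric("mutationCounts", function(x, genes = NULL) standardGeneric("mutationCounts"))

#' @rdname InfluenceNetwork-class
#' @param x an object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InfluenceNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname InfluenceNetwork-class
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname GeneModule-class
#' @param x an object.
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname GeneModule-class
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' @rdname ModuleScore-class
#' @param x an object.
#' @export
setGeneric("compositeScore", function(x) standardGeneric("compositeScore"))

#' @rdname ModuleCatalog-class
#' @param x an object.
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname ModuleCatalog-class
#' @export
setGeneric("catalogModules", function(x) standardGeneric("catalogModules"))

#' @rdname CoverSolution-class
#' @param x an object.
#' @export
setGeneric("chosenModules", function(x) standardGeneric("chosenModules"))

#' @rdname CoverSolution-class
#' @export
setGeneric("sampleAssignment", function(x) standardGeneric("sampleAssignment"))

#' @rdname CoverSolution-class
#' @export
setGeneric("uncoveredSamples", function(x) standardGeneric("uncoveredSamples"))

#' @rdname PlantedCohort-class
#' @param x an object.
#' @export
setGeneric("truthModules", function(x) standardGeneric("truthModules"))
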