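#' @import methods
NULL

#' @rdname FeatureTable-class
#' @param x an object
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname FeatureTable-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("plsdaScores", function(x) standardGeneric("plsdaScores"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("plsdaWeights", function(x) standardGeneric("plsdaWeights"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("plsdaLoadings", function(x) standardGeneric("plsdaLoadings"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("plsdaYLoadings", function(x) standardGeneric("plsdaYLoadings"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("explainedYSS", function(x) standardGeneric("explainedYSS"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))

#' @rdname PlsdaModel-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))

#' @rdname PathwayGraph-class
#' @param value replacement value
#' @export
setGeneric("nodeWeights<-", function(x, value) standardGeneric("nodeWeights<-"))

#' @rdname MetaboliteSetCollection-class
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname MetaboliteSetCollection-class
#' @export
setGeneric("setMembers", function(x) standardGeneric("setMembers"))

#' @rdname MetaboliteSetCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname MappingTable-class
#' @export
setGeneric("mappedGenes", function(x) standardGeneric("mappedGenes"))
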