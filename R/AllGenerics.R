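#' Accessors for nuegrn S4 containers
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setMethod("edges", "GRNEdgeList", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edges", "PruneResult", function(x) x@edges@edges)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("moduleLabels", "SyntheticDataset", function(x) x@trueModuleLabels)

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

#' @rdname accessors
#' @export
setMethod("mergeLog", "ModuleSet", function(x) x@mergeLog)

#' @rdname accessors
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))

#' @rdname accessors
#' @export
setMethod("expressionData", "SyntheticDataset", function(x) x@expression)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setMethod("phenotypes", "SyntheticDataset", function(x) x@phenotypes)

#' @rdname accessors
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname accessors
#' @export
setMethod("trueEdges", "SyntheticDataset", function(x) x@trueEdges)

#' @rdname accessors
#' @export
setGeneric("tfList", function(x) standardGeneric("tfList"))

#' @rdname accessors
#' @export
setMethod("tfList", "SyntheticDataset", function(x) x@tfList)

#' @rdname accessors
#' @export
setGeneric("deClasses", function(x) standardGeneric("deClasses"))

#' @rdname accessors
#' @export
setMethod("deClasses", "SyntheticDataset", function(x) x@trueDeClasses)

#' @rdname accessors
#' @export
setGeneric("validatedEdges", function(x) standardGeneric("validatedEdges"))

#' @rdname accessors
#' @export
setMethod("validatedEdges", "GoldStandard", function(x) x@validatedEdges)

#' @rdname accessors
#' @export
setGeneric("assayedTfs", function(x) standardGeneric("assayedTfs"))

#' @rdname accessors
#' @export
setMethod("assayedTfs", "GoldStandard", function(x) x@assayedTfs)

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname accessors
#' @export
setMethod("curvePoints", "PRCurve", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("weightThreshold", function(x) standardGeneric("weightThreshold"))

#' @rdname accessors
#' @export
setMethod("weightThreshold", "PruneResult", function(x) x@weightThreshold)

#' @rdname accessors
#' @export
setGeneric("moduleTraitCor", function(x) standardGeneric("moduleTraitCor"))

#' @rdname accessors
#' @export
setMethod("moduleTraitCor", "CorrelationStats", function(x) x@moduleTraitCor)

#' @rdname accessors
#' @export
setGeneric("moduleTraitP", function(x) standardGeneric("moduleTraitP"))

#' @rdname accessors
#' @export
setMethod("moduleTraitP", "CorrelationStats", function(x) x@moduleTraitP)

#' @rdname accessors
#' @export
setGeneric("geneSignificance", function(x) standardGeneric("geneSignificance"))

#' @rdname accessors
#' @export
setMethod("geneSignificance", "CorrelationStats", function(x) x@gs)

#' @rdname accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' @rdname accessors
#' @export
setMethod("moduleMembership", "CorrelationStats", function(x) x@mm)
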