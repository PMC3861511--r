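#' @rdname ExpressionTable-class
#' @param x an object.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("housekeepingGenes", function(x) standardGeneric("housekeepingGenes"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @rdname FoldChangeMatrix-class
#' @param x an object.
#' @export
setGeneric("fcScale", function(x) standardGeneric("fcScale"))

#' @rdname ddctNormalize
#' @export
setGeneric("ddctNormalize", function(x, ...) standardGeneric("ddctNormalize"))

#' @rdname toLog2FoldChange
#' @export
setGeneric("toLog2FoldChange", function(x, ...) standardGeneric("toLog2FoldChange"))

#' @rdname toLog2FoldChange
#' @export
setGeneric("asFoldChangeMatrix", function(x, ...) standardGeneric("asFoldChangeMatrix"))

#' @rdname pairwiseRD
#' @export
setGeneric("pairwiseRD", function(x, ...) standardGeneric("pairwiseRD"))

#' @rdname screenGenes
#' @export
setGeneric("screenGenes", function(x, ...) standardGeneric("screenGenes"))

#' @rdname overallMeanRD
#' @export
setGeneric("overallMeanRD", function(x, ...) standardGeneric("overallMeanRD"))

#' @rdname searchGeneSets
#' @export
setGeneric("searchGeneSets", function(x, ...) standardGeneric("searchGeneSets"))

#' @rdname averageLinkageCluster
#' @export
setGeneric("averageLinkageCluster", function(x, ...) standardGeneric("averageLinkageCluster"))
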