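#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))

#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))

#' @export
setGeneric("canonicalKey", function(x) standardGeneric("canonicalKey"))

#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @export
setGeneric("subnetworkCounts", function(x) standardGeneric("subnetworkCounts"))

#' @export
setGeneric("realizations", function(x) standardGeneric("realizations"))

#' @export
setGeneric("motifResults", function(x) standardGeneric("motifResults"))

#' @export
setGeneric("runMetadata", function(x) standardGeneric("runMetadata"))

#' @export
setGeneric("significantMotifs", function(x) standardGeneric("significantMotifs"))
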