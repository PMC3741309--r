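# The NetworkSample container.

#' Construct a sample of labeled networks
#'
#' @param networks list of [LabeledNetwork-class] objects, all sharing the
#'   identical ordered vertex label set.
#' @param name sample name used in reports.
#' @return a [NetworkSample-class].
#' @export
NetworkSample <- function(networks, name = "sample") {
  if (length(networks) < 1L) stop("empty sample: at least one network is required")
  new("NetworkSample",
      labels = networks[[1L]]@labels,
      networks = networks,
      name = as.character(name))
}

#' @describeIn NetworkSample shared vertex label set
#' @param x a NetworkSample.
#' @export
setMethod("vertexLabels", "NetworkSample", function(x) x@labels)

#' @describeIn NetworkSample sample name
#' @export
setMethod("sampleName", "NetworkSample", function(x) x@name)

#' @describeIn NetworkSample number of element networks
#' @export
setMethod("sampleSize", "NetworkSample", function(x) length(x@networks))

#' @export
setMethod("length", "NetworkSample", function(x) length(x@networks))

#' @export
setMethod("[[", "NetworkSample", function(x, i) x@networks[[i]])

setMethod("show", "NetworkSample", function(object) {
  m <- vapply(object@networks, edgeCount, integer(1))
  cat(sprintf("NetworkSample \"%s\": %d networks on %d vertices\n",
              object@name, length(object@networks), length(object@labels)))
  cat(sprintf("  edges per network: %d-%d (median %g)\n",
              min(m), max(m), stats::median(m)))
})
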