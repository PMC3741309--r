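#' LabeledNetwork: a simple directed network over a fixed ordered label set
#'
#' The unit of analysis. Vertices are identified by pairwise-different,
#' case-sensitive character labels whose order is fixed (it defines row and
#' column order of any adjacency serialization and is shared by a whole
#' sample). Edges are an unordered set of ordered (tail, head) label pairs;
#' loops and multi-edges are invalid.
#'
#' @slot labels character vector of pairwise-different vertex labels (n >= 2).
#' @slot edges integer matrix with m rows and columns tail, head holding
#'   1-based indices into `labels`.
#' @exportClass LabeledNetwork
setClass("LabeledNetwork",
  representation(labels = "character", edges = "matrix"))

setValidity("LabeledNetwork", function(object) {
  msgs <- .validateRaw(object@labels, object@edges)
  if (length(msgs)) msgs else TRUE
})

#' NetworkSample: an ordered collection of networks sharing one label set
#'
#' All element networks must carry the identical ordered vertex label set;
#' the sample is the input of motif detection.
#'
#' @slot labels shared ordered vertex label set.
#' @slot networks list of [LabeledNetwork-class] objects.
#' @slot name sample name used in reports.
#' @exportClass NetworkSample
setClass("NetworkSample",
  representation(labels = "character", networks = "list", name = "character"))

setValidity("NetworkSample", function(object) {
  msgs <- character()
  if (length(object@networks) < 1L)
    msgs <- c(msgs, "empty sample: at least one network is required")
  for (i in seq_along(object@networks)) {
    net <- object@networks[[i]]
    if (!is(net, "LabeledNetwork")) {
      msgs <- c(msgs, sprintf("element %d is not a LabeledNetwork", i))
    } else if (!identical(net@labels, object@labels)) {
      msgs <- c(msgs, sprintf("element %d has a different vertex label set", i))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LabeledSubnetwork: an induced connected labeled subnetwork
#'
#' Canonical representation of an induced, weakly connected subnetwork on k
#' labeled vertices. Identity is the edge set: two subnetworks are equal iff
#' their canonical keys are equal.
#'
#' @slot vertices the k vertex labels (sorted).
#' @slot edges character matrix (tail, head) of labeled edges.
#' @slot key canonical string key: lexicographically sorted "tail>head"
#'   tokens joined by "|".
#' @exportClass LabeledSubnetwork
setClass("LabeledSubnetwork",
  representation(vertices = "character", edges = "matrix", key = "character"))

setValidity("LabeledSubnetwork", function(object) {
  msgs <- character()
  if (length(object@vertices) < 2L)
    msgs <- c(msgs, "a subnetwork needs at least 2 vertices")
  if (nrow(object@edges) < 1L)
    msgs <- c(msgs, "a subnetwork needs a nonempty edge set")
  if (!all(object@edges %in% object@vertices))
    msgs <- c(msgs, "edge endpoints outside the vertex set")
  if (!isWeaklyConnected(object@vertices, object@edges))
    msgs <- c(msgs, "subnetwork is not weakly connected")
  if (length(msgs)) msgs else TRUE
})

#' SubnetworkCounts: counts of induced k-subnetworks over a sample
#'
#' Map from canonical subnetwork key to the number of sample element
#' networks whose enumeration contains it. Because vertex labels are pairwise
#' different, each subnetwork occurs at most once per network, so every count
#' lies in 1..sampleSize; keys with count zero are never materialized.
#'
#' @slot sampleName name of the counted sample.
#' @slot k subnetwork size.
#' @slot counts named integer vector (names = canonical keys).
#' @slot sampleSize number of element networks.
#' @exportClass SubnetworkCounts
setClass("SubnetworkCounts",
  representation(sampleName = "character", k = "integer",
                 counts = "integer", sampleSize = "integer"))

setValidity("SubnetworkCounts", function(object) {
  msgs <- character()
  if (length(object@counts) &&
      (any(object@counts < 0L) || any(object@counts > object@sampleSize)))
    msgs <- c(msgs, "counts must lie in 0..sampleSize")
  if (length(object@counts) && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by canonical keys")
  if (length(msgs)) msgs else TRUE
})

#' NullEnsemble: degree-preserving random realizations of one network
#'
#' M realizations of one sample element's in/out degree sequence, produced by
#' independent edge-switching chains restarted from the source network.
#'
#' @slot sourceIndex index of the source element in its sample.
#' @slot Q mixing parameter (switch attempts per edge; total attempts
#'   round(Q*m), rejected attempts included).
#' @slot realizations list of [LabeledNetwork-class] objects.
#' @slot seed integer seed the ensemble was generated from.
#' @exportClass NullEnsemble
setClass("NullEnsemble",
  representation(sourceIndex = "integer", Q = "numeric",
                 realizations = "list", seed = "integer"))

#' MotifAnalysis: result of a motif detection run
#'
#' Candidate subnetworks with observed sample counts, estimated null
#' occurrence probabilities, raw and Holm-adjusted p-values and significance
#' flags, plus the fully resolved run configuration.
#'
#' @slot results data.frame with one row per candidate key.
#' @slot metadata list with the resolved configuration (k, minCount, alpha,
#'   Q, M, seed, sample name, package version, calibration reports).
#' @exportClass MotifAnalysis
setClass("MotifAnalysis",
  representation(results = "data.frame", metadata = "list"))
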