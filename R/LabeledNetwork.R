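# Construction, validation and elementary operations on labeled networks.

# raw-ingredient validation shared by validateNetwork() and the S4 validity;
# `edges` is an integer index matrix (m x 2)
.validateRaw <- function(labels, edges) {
  msgs <- character()
  if (length(labels) < 2L)
    msgs <- c(msgs, "label set must contain at least 2 labels")
  if (anyDuplicated(labels))
    msgs <- c(msgs, sprintf("duplicate labels: %s",
                            paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  if (!is.matrix(edges) || ncol(edges) != 2L)
    return(c(msgs, "edges must be a 2-column matrix"))
  if (nrow(edges)) {
    if (!is.numeric(edges))
      return(c(msgs, "edge matrix must hold vertex indices"))
    n <- length(labels)
    bad <- edges < 1L | edges > n
    if (any(bad))
      msgs <- c(msgs, "edge endpoint outside the label set")
    else {
      loops <- edges[, 1L] == edges[, 2L]
      if (any(loops))
        msgs <- c(msgs, sprintf("loop at vertex %s",
                                paste(unique(labels[edges[loops, 1L]]), collapse = ", ")))
      if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
        msgs <- c(msgs, "duplicate edges (multi-edges are not allowed)")
    }
  }
  msgs
}

# accept edges as character matrix/data.frame of label pairs or integer index
# matrix; return integer index matrix with colnames tail/head
.edgesToIndex <- function(labels, edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    out <- matrix(integer(), ncol = 2L)
  } else if (is.character(edges)) {
    if (!is.matrix(edges) || ncol(edges) != 2L)
      stop("character edges must form a 2-column (tail, head) matrix")
    idx <- match(edges, labels)
    unknown <- is.na(idx)
    if (any(unknown))
      stop("unknown label(s) in edges: ",
           paste(unique(edges[unknown]), collapse = ", "))
    out <- matrix(as.integer(idx), ncol = 2L)
  } else {
    out <- matrix(as.integer(edges), ncol = 2L)
  }
  colnames(out) <- c("tail", "head")
  out
}

#' Construct a labeled directed network
#'
#' @param labels ordered character vector of pairwise-different vertex labels.
#' @param edges edge set, either a 2-column character matrix / data.frame of
#'   (tail, head) label pairs or a 2-column integer matrix of label indices.
#'   May be empty. Duplicate edges are collapsed with a warning (the method
#'   operates on simple graphs); loops are an error.
#' @return a [LabeledNetwork-class] object.
#' @examples
#' net <- LabeledNetwork(c("F3", "Fz", "F4"),
#'                       rbind(c("F3", "Fz"), c("Fz", "F4")))
#' edgeCount(net)
#' @export
LabeledNetwork <- function(labels, edges = NULL) {
  labels <- as.character(labels)
  idx <- .edgesToIndex(labels, edges)
  dup <- duplicated(paste(idx[, 1L], idx[, 2L]))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    idx <- idx[!dup, , drop = FALSE]
  }
  new("LabeledNetwork", labels = labels, edges = idx)
}

#' Validate network ingredients without constructing an object
#'
#' Returns a report instead of failing, listing every violation of the
#' simple-directed-network invariants: loops, endpoints outside the label
#' set, duplicate (multi-) edges, duplicate labels.
#'
#' @inheritParams LabeledNetwork
#' @return list with elements `valid` (logical) and `violations` (character).
#' @export
validateNetwork <- function(labels, edges = NULL) {
  labels <- as.character(labels)
  idx <- tryCatch(.edgesToIndex(labels, edges),
                  error = function(e) conditionMessage(e))
  if (is.character(idx) && !is.matrix(idx))
    return(list(valid = FALSE, violations = idx))
  msgs <- .validateRaw(labels, idx)
  list(valid = length(msgs) == 0L, violations = msgs)
}

#' @describeIn LabeledNetwork vertex labels
#' @param x a LabeledNetwork.
#' @export
setMethod("vertexLabels", "LabeledNetwork", function(x) x@labels)

#' @describeIn LabeledNetwork edges as a character (tail, head) matrix
#' @export
setMethod("edgeLabels", "LabeledNetwork", function(x) {
  out <- matrix(x@labels[x@edges], ncol = 2L)
  colnames(out) <- c("tail", "head")
  out
})

#' @describeIn LabeledNetwork number of edges
#' @export
setMethod("edgeCount", "LabeledNetwork", function(x) nrow(x@edges))

#' @describeIn LabeledNetwork logical adjacency matrix in label order
#' @export
setMethod("adjacencyMatrix", "LabeledNetwork", function(x) {
  n <- length(x@labels)
  adj <- matrix(FALSE, n, n, dimnames = list(x@labels, x@labels))
  if (nrow(x@edges)) adj[x@edges] <- TRUE
  adj
})

setMethod("show", "LabeledNetwork", function(object) {
  cat(sprintf("LabeledNetwork: %d vertices, %d directed edges\n",
              length(object@labels), nrow(object@edges)))
  cat("  labels:", paste(object@labels, collapse = " "), "\n")
  if (nrow(object@edges)) {
    toks <- .edgeTokens(edgeLabels(object))
    cat("  edges: ", paste(utils::head(sort(toks, method = "radix"), 12L),
                           collapse = " "),
        if (nrow(object@edges) > 12L) "..." else "", "\n")
  }
})

#' In- and out-degree sequence of a network
#'
#' Per-label in- and out-degrees; both sum to the edge count, the invariant
#' preserved by the edge-switching null model.
#'
#' @param x a [LabeledNetwork-class].
#' @return list with named integer vectors `in_deg` and `out_deg`.
#' @export
setMethod("degreeSequence", "LabeledNetwork", function(x) {
  n <- length(x@labels)
  out_deg <- tabulate(x@edges[, 1L], nbins = n)
  in_deg <- tabulate(x@edges[, 2L], nbins = n)
  list(in_deg = setNames(as.integer(in_deg), x@labels),
       out_deg = setNames(as.integer(out_deg), x@labels))
})

# ---- canonical keys ------------------------------------------------------

.edgeTokens <- function(edgeChar) {
  if (nrow(edgeChar) == 0L) return(character())
  paste0(edgeChar[, 1L], ">", edgeChar[, 2L])
}

# deterministic, locale-independent key: radix-sorted tokens joined by "|"
.keyFromTokens <- function(tokens) {
  paste(sort(tokens, method = "radix"), collapse = "|")
}

#' Canonical key of an edge set
#'
#' Identity of a labeled subnetwork is its edge set; the canonical key is the
#' lexicographically sorted sequence of "tail>head" tokens joined by "|". It
#' is order-independent and injective on edge sets: two subnetworks are equal
#' iff their keys are equal. Applied to a whole network it serves as the
#' distinct-network key used by the null-model calibration.
#'
#' @param x a [LabeledSubnetwork-class], a [LabeledNetwork-class], or a
#'   2-column character matrix of (tail, head) label pairs.
#' @return a character key ("" for an empty edge set of a whole network).
#' @examples
#' canonicalKey(rbind(c("Fz", "F4"), c("F3", "Fz")))  # "F3>Fz|Fz>F4"
#' @export
setMethod("canonicalKey", "matrix", function(x) {
  stopifnot(is.character(x), ncol(x) == 2L)
  .keyFromTokens(.edgeTokens(x))
})

#' @rdname canonicalKey
#' @export
setMethod("canonicalKey", "LabeledNetwork", function(x) {
  .keyFromTokens(.edgeTokens(edgeLabels(x)))
})

#' @rdname canonicalKey
#' @export
setMethod("canonicalKey", "LabeledSubnetwork", function(x) x@key)

# parse a canonical key back into a character edge matrix
.keyToEdges <- function(key) {
  toks <- strsplit(key, "|", fixed = TRUE)[[1L]]
  parts <- strsplit(toks, ">", fixed = TRUE)
  out <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(out) <- c("tail", "head")
  out
}

.keyVertices <- function(key) {
  sort(unique(as.vector(.keyToEdges(key))), method = "radix")
}

# ---- connectivity and induced subnetworks --------------------------------

#' Weak connectivity of a vertex set under an edge set
#'
#' TRUE iff every vertex is reachable from every other when edge directions
#' are ignored. This is the connectivity notion used throughout: the
#' motif-detection convention for "connected subnetwork".
#'
#' @param vertices character vector of vertex labels.
#' @param edges 2-column character matrix of (tail, head) pairs, all
#'   endpoints in `vertices`.
#' @return logical.
#' @export
isWeaklyConnected <- function(vertices, edges) {
  k <- length(vertices)
  if (k <= 1L) return(TRUE)
  if (is.null(edges) || nrow(edges) == 0L) return(FALSE)
  ti <- match(edges[, 1L], vertices)
  hi <- match(edges[, 2L], vertices)
  if (anyNA(ti) || anyNA(hi)) stop("edge endpoint outside the vertex set")
  reach <- logical(k)
  reach[1L] <- TRUE
  repeat {
    grow <- (reach[ti] & !reach[hi]) | (reach[hi] & !reach[ti])
    if (!any(grow)) break
    reach[ti[grow]] <- TRUE
    reach[hi[grow]] <- TRUE
  }
  all(reach)
}

# fast internal variant on a logical adjacency submatrix (k x k)
.wconnAdj <- function(sub) {
  k <- nrow(sub)
  und <- sub | t(sub)
  reach <- logical(k)
  reach[1L] <- TRUE
  repeat {
    newreach <- reach | (colSums(und[reach, , drop = FALSE]) > 0L)
    if (all(newreach == reach)) break
    reach <- newreach
  }
  all(reach)
}

#' Induced subnetwork on a vertex subset
#'
#' Extracts the subnetwork containing exactly the edges of `x` with both
#' endpoints in `vertices`. Following the induced-subgraph semantics of the
#' enumeration, the result is returned only when it is weakly connected;
#' otherwise `NULL`.
#'
#' @param x a [LabeledNetwork-class].
#' @param vertices k >= 2 distinct labels, all present in the network.
#' @return a [LabeledSubnetwork-class] or `NULL` if not weakly connected.
#' @export
inducedSubnetwork <- function(x, vertices) {
  stopifnot(is(x, "LabeledNetwork"))
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate labels in vertex subset")
  if (!all(vertices %in% x@labels)) stop("unknown label(s) in vertex subset")
  if (length(vertices) < 2L) stop("a subnetwork needs at least 2 vertices")
  el <- edgeLabels(x)
  keep <- el[, 1L] %in% vertices & el[, 2L] %in% vertices
  sub <- el[keep, , drop = FALSE]
  if (!isWeaklyConnected(vertices, sub)) return(NULL)
  new("LabeledSubnetwork",
      vertices = sort(vertices, method = "radix"),
      edges = sub,
      key = .keyFromTokens(.edgeTokens(sub)))
}

setMethod("show", "LabeledSubnetwork", function(object) {
  cat(sprintf("LabeledSubnetwork: k = %d, %d edges\n  key: %s\n",
              length(object@vertices), nrow(object@edges), object@key))
})
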