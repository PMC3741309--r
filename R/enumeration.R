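# Exhaustive enumeration of induced connected labeled k-subnetworks.
#
# Because all vertices carry pairwise-different labels, subnetwork identity
# is edge-set identity: no isomorphism classes, and each subnetwork occurs at
# most once per network. Enumeration scans all choose(n, k) vertex
# combinations — for the dense, small networks this method targets (EEG-scale,
# n around 9-20, k in 2..5) the combination scan beats recursive schemes.

#' Enumerate induced weakly connected k-subnetworks of one network
#'
#' Scans all choose(n, k) vertex combinations and returns the canonical key
#' of each combination whose induced subnetwork is weakly connected.
#'
#' @param x a [LabeledNetwork-class].
#' @param k subnetwork size, 2 <= k <= n.
#' @return character vector of canonical keys (sorted, no duplicates).
#' @export
enumerateSubnetworks <- function(x, k) {
  stopifnot(is(x, "LabeledNetwork"))
  n <- length(x@labels)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop(sprintf("k must lie in 2..%d (got %d)", n, k))
  if (nrow(x@edges) == 0L) return(character())
  adj <- matrix(FALSE, n, n)
  adj[x@edges] <- TRUE
  combs <- combn(n, k)
  labels <- x@labels
  keys <- character(ncol(combs))
  nk <- 0L
  for (ci in seq_len(ncol(combs))) {
    v <- combs[, ci]
    sub <- adj[v, v, drop = FALSE]
    if (!any(sub)) next
    if (!.wconnAdj(sub)) next
    w <- which(sub)
    ti <- v[(w - 1L) %% k + 1L]
    hi <- v[(w - 1L) %/% k + 1L]
    nk <- nk + 1L
    keys[nk] <- .keyFromTokens(paste0(labels[ti], ">", labels[hi]))
  }
  sort(keys[seq_len(nk)], method = "radix")
}

#' Count induced k-subnetworks over a sample
#'
#' For every canonical key, the count is the number of sample element
#' networks whose k-enumeration contains it (at most once per network, so
#' counts lie in 1..sampleSize). Keys never observed are not materialized.
#'
#' @param sample a [NetworkSample-class].
#' @param k subnetwork size.
#' @return a [SubnetworkCounts-class].
#' @export
countOverSample <- function(sample, k) {
  stopifnot(is(sample, "NetworkSample"))
  keys <- unlist(lapply(sample@networks, enumerateSubnetworks, k = k))
  counts <- if (length(keys)) table(keys) else integer()
  counts <- setNames(as.integer(counts), names(counts))
  new("SubnetworkCounts", sampleName = sample@name, k = as.integer(k),
      counts = counts, sampleSize = length(sample@networks))
}

#' @describeIn countOverSample named count vector of a SubnetworkCounts
#' @param x a SubnetworkCounts.
#' @export
setMethod("subnetworkCounts", "SubnetworkCounts", function(x) x@counts)

#' @export
setMethod("sampleName", "SubnetworkCounts", function(x) x@sampleName)

#' @export
setMethod("sampleSize", "SubnetworkCounts", function(x) x@sampleSize)

setMethod("show", "SubnetworkCounts", function(object) {
  cat(sprintf("SubnetworkCounts \"%s\": %d distinct %d-subnetworks over %d networks\n",
              object@sampleName, length(object@counts), object@k,
              object@sampleSize))
})

#' Filter candidate subnetworks by a minimum sample count
#'
#' Keeps the keys that reach `minCount` in at least one of the supplied
#' count tables (union across samples). This is the candidate prefilter that
#' restricts significance testing to the most promising subnetworks; with
#' `minCount = 1` every observed key is kept.
#'
#' @param tables list of [SubnetworkCounts-class] sharing the same k.
#' @param minCount integer >= 1.
#' @return character vector of candidate keys (sorted).
#' @export
filterCandidates <- function(tables, minCount) {
  if (is(tables, "SubnetworkCounts")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, minCount >= 1L)
  ks <- vapply(tables, function(t) t@k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("count tables have inconsistent subnetwork sizes k: ",
         paste(unique(ks), collapse = ", "))
  hits <- lapply(tables, function(t) names(t@counts)[t@counts >= minCount])
  sort(unique(as.character(unlist(hits))), method = "radix")
}

#' Number of weakly connected labeled digraph topologies
#'
#' Counts the weakly connected simple digraphs on k distinctly labeled
#' vertices by exhaustive generation over all 2^(k(k-1)) arc subsets. On the
#' 9-electrode geometry each of the choose(9, 3) vertex triples can realize
#' any of the 54 connected labeled 3-topologies.
#'
#' @param k 2 <= k <= 5 (the exhaustive scan is capped to bound memory and
#'   time; the method itself uses k in 2..3).
#' @return the count (3 for k = 2, 54 for k = 3, 3834 for k = 4).
#' @export
countConnectedTopologies <- function(k) {
  k <- as.integer(k)
  if (k < 2L || k > 5L) stop("k must lie in 2..5")
  cpp_count_connected_digraphs(k)
}
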